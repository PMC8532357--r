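yeastlike_fixture <- function() {
  metabolic_model(
    "yeastlike",
    tibble::tibble(
      id = c("o2", "erg", "pyr", "hemeA", "biomass"),
      name = c("oxygen", "ergosterol", "pyruvate", "heme A", "biomass"),
      compartment = "c"),
    tibble::tibble(
      id = c("r_1992", "r_1757", "r_0713", "GROW", "EX_pyr",
             "EX_biomass"),
      name = c("oxygen exchange", "ergosterol exchange", "shuttle",
               "biomass pseudo-reaction", "pyruvate exchange",
               "biomass sink"),
      lower_bound = c(-1000, 0, -1000, 0, -1000, 0),
      upper_bound = c(0, 0, 1000, 1000, 1000, 1000),
      gene_association = "", subsystem = "",
      stoichiometry = list(
        c(o2 = -1), c(erg = -1), c(pyr = -1, erg = 1),
        c(pyr = -1, hemeA = -1e-5, biomass = 1), c(pyr = -1),
        c(biomass = -1))
    ),
    biomass_reaction_id = "GROW"
  )
}

test_that("anaerobic modifications apply the full recipe", {
  m <- yeastlike_fixture()
  rec <- anaerobic_recipe(
    oxygen_exchange_id = "r_1992",
    unrestricted_uptake_ids = "r_1757",
    blocked_reaction_ids = "r_0713",
    biomass_removals = "hemeA")
  m2 <- apply_anaerobic_modifications(m, rec)

  i <- match(c("r_1992", "r_1757", "r_0713"), m2$reactions$id)
  # oxygen exchange closed both ways
  expect_equal(unname(m2$reactions$lower_bound[i[1]]), 0)
  expect_equal(unname(m2$reactions$upper_bound[i[1]]), 0)
  # sterol uptake opened to the reversible default, upper bound unchanged
  expect_equal(unname(m2$reactions$lower_bound[i[2]]), -1000)
  expect_equal(unname(m2$reactions$upper_bound[i[2]]), 0)
  # shuttle blocked
  expect_equal(unname(m2$reactions$lower_bound[i[3]]), 0)
  expect_equal(unname(m2$reactions$upper_bound[i[3]]), 0)
  # heme A deleted from biomass, other coefficients identical
  bio <- m2$reactions$stoichiometry[[match("GROW", m2$reactions$id)]]
  expect_false("hemeA" %in% names(bio))
  expect_equal(bio, c(pyr = -1, biomass = 1))
  # reaction/metabolite counts unchanged
  expect_equal(nrow(m2$reactions), nrow(m$reactions))
  expect_equal(nrow(m2$metabolites), nrow(m$metabolites))
})

test_that("anaerobic modifications are idempotent", {
  m <- build_toy_wine_network()
  rec <- toy_anaerobic_recipe()
  once <- apply_anaerobic_modifications(m, rec)
  twice <- apply_anaerobic_modifications(once, rec)
  expect_equal(twice, once)
})

test_that("unresolved recipe ids are reported together", {
  m <- build_toy_wine_network()
  rec <- anaerobic_recipe(oxygen_exchange_id = "EX_o2",
                          unrestricted_uptake_ids = "r_9999",
                          blocked_reaction_ids = "r_8888",
                          biomass_removals = "hemeA")
  expect_error(apply_anaerobic_modifications(m, rec), "r_9999")
  expect_error(apply_anaerobic_modifications(m, rec), "r_8888")
})

test_that("recipe YAML round-trips", {
  rec <- toy_anaerobic_recipe()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_recipe_yaml(rec, path)
  rec2 <- read_recipe_yaml(path)
  expect_equal(rec2, rec)
})

test_that("fixing exchange fluxes sets the LB=UB box with optional band", {
  m <- chain_model()
  cons <- tibble::tibble(reaction_id = "EX_A", flux = -2.5)
  m2 <- fix_exchange_fluxes(m, cons, 0)
  i <- match("EX_A", m2$reactions$id)
  expect_equal(m2$reactions$lower_bound[i], -2.5)
  expect_equal(m2$reactions$upper_bound[i], -2.5)

  m3 <- fix_exchange_fluxes(m, tibble::tibble(reaction_id = "EX_B",
                                              flux = 10), 0.05)
  i <- match("EX_B", m3$reactions$id)
  expect_equal(m3$reactions$lower_bound[i], 9.5)
  expect_equal(m3$reactions$upper_bound[i], 10.5)

  # growth rate fixed the same way on the biomass reaction
  toy <- build_toy_wine_network()
  m4 <- fix_exchange_fluxes(toy, tibble::tibble(reaction_id = "BIOMASS",
                                                flux = 0.05), 0)
  i <- match("BIOMASS", m4$reactions$id)
  expect_equal(m4$reactions$lower_bound[i], 0.05)
  expect_equal(m4$reactions$upper_bound[i], 0.05)

  # only exchange/biomass reactions may be constrained
  expect_error(
    fix_exchange_fluxes(toy, tibble::tibble(reaction_id = "PGK",
                                            flux = 1), 0),
    "exchange or biomass")
  expect_error(
    fix_exchange_fluxes(toy, tibble::tibble(reaction_id = "EX_glc",
                                            flux = NaN), 0),
    "non-finite")
})

test_that("feasibility check returns witnesses and detects contradictions", {
  m <- chain_model()
  # consistent fixed exchanges
  m2 <- fix_exchange_fluxes(m, tibble::tibble(
    reaction_id = c("EX_A", "EX_B"), flux = c(-5, 5)), 0)
  f <- check_feasibility(m2)
  expect_true(f$feasible)
  sys <- build_stoichiometric_system(m2)
  expect_lt(max(abs(sys$S %*% f$certificate)), 1e-9)

  # mass-balance contradiction: uptake 5 cannot yield secretion 7
  m3 <- m
  m3$reactions$lower_bound <- c(-5, 0, 7)
  m3$reactions$upper_bound <- c(-5, 10, 7)
  expect_false(check_feasibility(m3)$feasible)

  # unconstrained toy network admits v = 0
  f0 <- check_feasibility(build_toy_wine_network())
  expect_true(f0$feasible)
})

test_that("reconciliation projects noisy fluxes onto a feasible vector", {
  m <- apply_anaerobic_modifications(build_toy_wine_network(),
                                     toy_anaerobic_recipe())
  # a consistent vector, then perturbed so LB=UB fixing is infeasible
  truth <- tibble::tibble(
    reaction_id = c("EX_glc", "EX_etoh", "EX_glyc", "EX_aa_1",
                    "EX_fusol_1", "EX_ester", "BIOMASS"),
    flux = c(-2, 3.74, 0.2, -0.1, 0.075, 0.02, 0.05))
  noisy <- truth
  noisy$flux <- noisy$flux * (1 + c(0.1, -0.08, 0.12, 0.05, -0.1, 0.1,
                                    0.04))
  expect_false(
    check_feasibility(fix_exchange_fluxes(m, noisy, 0))$feasible)
  rec <- reconcile_constraints(m, noisy)
  m2 <- fix_exchange_fluxes(m, rec, 0)
  expect_true(check_feasibility(m2)$feasible)
  # reconciled values stay close to the measurements (relative)
  expect_true(all(abs(rec$flux - rec$flux_measured) <
                    0.35 * pmax(abs(rec$flux_measured), 0.1)))
})
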