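linear_series <- function() {
  fermentation_series(
    "s", c(0, 24, 48), c(2, 2, 2),
    list(glucose = c(200, 150, 100), acetate = c(5, 5, 5)))
}

test_that("midpoint flux estimate is exact on the linear glucose profile", {
  s <- linear_series()
  # (100 - 200) / 48 / 2
  expect_equal(estimate_specific_flux(s, "glucose", 24), -100 / 48 / 2)
  expect_equal(estimate_specific_flux(s, "acetate", 24), 0)
  # endpoints fall back to one-sided differences
  expect_equal(estimate_specific_flux(s, "glucose", 0), -50 / 24 / 2)
  expect_equal(estimate_specific_flux(s, "glucose", 48), -50 / 24 / 2)
})

test_that("central difference is exact on quadratic profiles (interior)", {
  times <- seq(0, 20, by = 2)
  a <- 3; b <- -1.5; cc <- 0.25
  conc <- a + b * times + cc * times^2
  s <- fermentation_series("s", times, rep(1, length(times)),
                           list(comp = conc))
  for (tp in times[2:(length(times) - 1)]) {
    expect_equal(estimate_specific_flux(s, "comp", tp), b + 2 * cc * tp,
                 tolerance = 1e-12)
  }
})

test_that("estimator recovers a planted constant production rate", {
  # forward-simulate C(t) = C0 + q X t at constant biomass X = 1
  q <- 0.3
  times <- 0:10
  s <- fermentation_series("s", times, rep(1, 11),
                           list(voc = 1 + q * times))
  for (tp in 1:9) {
    expect_equal(estimate_specific_flux(s, "voc", tp), q,
                 tolerance = 1e-9)
  }
})

test_that("estimator is linear in the concentrations", {
  times <- seq(0, 12, 2)
  set.seed(1)
  c1 <- cumsum(runif(7)); c2 <- cumsum(rnorm(7))
  X <- runif(7, 1, 3)
  mk <- function(conc) fermentation_series("s", times, X,
                                           list(z = conc))
  for (tp in times[2:6]) {
    lhs <- estimate_specific_flux(mk(2 * c1 - 3 * c2), "z", tp)
    rhs <- 2 * estimate_specific_flux(mk(c1), "z", tp) -
      3 * estimate_specific_flux(mk(c2), "z", tp)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("flux sign follows local monotonicity", {
  times <- seq(0, 20, 2)
  down <- sort(runif(11, 10, 100), decreasing = TRUE)
  up <- sort(runif(11, 0, 50))
  s <- fermentation_series("s", times, runif(11, 1, 2),
                           list(eaten = down, made = up))
  for (tp in times[2:10]) {
    expect_lte(estimate_specific_flux(s, "eaten", tp), 0)
    expect_gte(estimate_specific_flux(s, "made", tp), 0)
  }
})

test_that("growth rate estimation matches analytic cases", {
  s <- fermentation_series("s", c(0, 24, 48), c(1, 1, 1),
                           list(x = c(0, 0, 0)))
  expect_equal(estimate_growth_rate(s, 24), 0)

  s2 <- fermentation_series("s", c(0, 24, 48), c(1, 2, 3),
                            list(x = c(0, 0, 0)))
  expect_equal(estimate_growth_rate(s2, 24), (3 - 1) / 48 / 2)

  # true exponential sampled finely: relative error O((mu dt)^2)
  times <- seq(0, 10, 0.5)
  s3 <- fermentation_series("s", times, 0.5 * exp(0.1 * times),
                            list(x = times * 0))
  for (tp in times[3:18]) {
    expect_equal(estimate_growth_rate(s3, tp), 0.1, tolerance = 0.01)
  }
})

test_that("estimators reject bad lookups and degenerate series", {
  s <- linear_series()
  expect_error(estimate_specific_flux(s, "glucose", 12),
               "not a measured time point")
  expect_error(estimate_specific_flux(s, "ethanol", 24), "not measured")
  expect_error(fermentation_series("s", c(0, 24), c(1, 1),
                                   list(g = c(1, 2))),
               "at least 3")
  expect_error(fermentation_series("s", c(0, 24, 12), c(1, 1, 1),
                                   list(g = 1:3)),
               "strictly increasing")
  expect_error(fermentation_series("s", c(0, 12, 24), c(1, 0, 1),
                                   list(g = 1:3)),
               "positive")
})

test_that("flux table assembles one constraint set per strain and time", {
  mapping <- c(glucose = "EX_glc", acetate = "EX_ac")
  mk <- function(nm) fermentation_series(
    nm, c(0, 24, 58, 144), rep(2, 4),
    list(glucose = c(200, 150, 90, 60), acetate = c(0, 1, 3, 4)))
  strains <- lapply(paste0("s", 1:4), mk)

  ft <- build_flux_table(strains, c(24, 58, 144), mapping,
                         biomass_reaction_id = "GROW")
  expect_equal(nrow(dplyr::distinct(ft, strain, time_h)), 12)
  # each constraint set: 2 compounds + growth rate
  expect_equal(nrow(ft), 12 * 3)
  expect_true(all(c("EX_glc", "EX_ac", "GROW") %in% ft$reaction_id))

  single <- build_flux_table(strains[1], 24, mapping,
                             biomass_reaction_id = "GROW")
  expect_equal(nrow(dplyr::distinct(single, strain, time_h)), 1)

  # unmapped compounds warn and are excluded; missing times error
  expect_warning(
    build_flux_table(strains[1], 24, mapping["glucose"],
                     biomass_reaction_id = "GROW"),
    "unmapped")
  expect_error(
    build_flux_table(strains[1], 30, mapping,
                     biomass_reaction_id = "GROW"),
    "not in series")
})

test_that("flux table CSV round-trips", {
  mapping <- c(glucose = "EX_glc")
  s <- fermentation_series("s1", c(0, 24, 48), c(1, 2, 4),
                           list(glucose = c(100, 80, 50)))
  ft <- build_flux_table(list(s), 24, mapping,
                         biomass_reaction_id = "GROW")
  path <- withr::local_tempfile(fileext = ".csv")
  write_flux_table_csv(ft, path)
  ft2 <- read_flux_table_csv(path)
  expect_equal(tibble::as_tibble(ft2), tibble::as_tibble(ft),
               ignore_attr = TRUE)
})
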