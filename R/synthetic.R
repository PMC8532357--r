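#' Build the toy wine-fermentation metabolic network
#'
#' A small, fully mass-balanced stand-in for a yeast genome-scale model at
#' desk scale: glucose uptake feeding a hexokinase/glycolysis chain to
#' pyruvate, an ethanol branch (pyruvate decarboxylase + alcohol
#' dehydrogenase, each with a parallel isoenzyme reaction so the
#' constrained polytope keeps sampling volume), a glycerol branch, an
#' Ehrlich-like branch per amino acid (transaminase with a parallel
#' isoform, alpha-keto-acid decarboxylase, fusel-aldehyde dehydrogenase,
#' fusel-alcohol exchange), an acetyl-transfer ester branch, an
#' oxygen-requiring heme A synthesis feeding the biomass pseudo-reaction,
#' and exchanges for every boundary metabolite. Each reaction carries a
#' toy single-gene GPR and a subsystem label.
#'
#' @param n_branch_vocs Number of Ehrlich branches (>= 1), each producing
#'   its own fusel alcohol from its own amino acid.
#' @param include_ehrlich Include the Ehrlich/ester branches at all.
#' @param default_bound Magnitude of the default flux bounds.
#' @param seed Kept for interface symmetry; construction is deterministic.
#' @return A `metabolic_model`.
#' @export
build_toy_wine_network <- function(n_branch_vocs = 1,
                                   include_ehrlich = TRUE,
                                   default_bound = 1000, seed = 1) {
  stopifnot(n_branch_vocs >= 1)
  b <- default_bound
  V <- if (include_ehrlich) n_branch_vocs else 0

  met <- function(id, name) tibble::tibble(id = id, name = name,
                                           compartment = "c")
  mets <- dplyr::bind_rows(
    met("glc", "D-glucose"), met("g6p", "glucose 6-phosphate"),
    met("pyr", "pyruvate"), met("acald", "acetaldehyde"),
    met("etoh", "ethanol"), met("glyc", "glycerol"),
    met("acoa", "acetyl-CoA"), met("co2", "carbon dioxide"),
    met("o2", "oxygen"), met("hemeA", "heme A"),
    met("biomass", "biomass")
  )
  if (V > 0) {
    for (v in seq_len(V)) {
      mets <- dplyr::bind_rows(
        mets,
        met(paste0("aa_", v), paste0("amino acid ", v)),
        met(paste0("kacid_", v), paste0("2-oxo acid ", v)),
        met(paste0("fald_", v), paste0("fusel aldehyde ", v)),
        met(paste0("fusol_", v), paste0("fusel alcohol ", v))
      )
    }
    mets <- dplyr::bind_rows(mets, met("ester", "acetate ester"))
  }

  rxn <- function(id, name, st, lb, ub, gene, subsystem) {
    tibble::tibble(id = id, name = name, lower_bound = lb,
                   upper_bound = ub, gene_association = gene,
                   subsystem = subsystem, stoichiometry = list(st))
  }
  ehrlich <- "Biosynthesis of secondary metabolites (Ehrlich pathway)"

  bio_st <- c(g6p = -0.3, pyr = -0.2, hemeA = -1e-5, biomass = 1)
  if (V > 0) bio_st <- c(bio_st[1:2], aa_1 = -0.1, bio_st[3:4])

  rxns <- dplyr::bind_rows(
    rxn("HXK", "hexokinase (D-glucose:ATP)", c(glc = -1, g6p = 1),
        0, b, "TOY_HXK1", "Glycolysis"),
    rxn("PGK", "lumped lower glycolysis", c(g6p = -1, pyr = 2),
        0, b, "TOY_PGK1", "Glycolysis, Carbon metabolism"),
    rxn("GPD", "glycerol-3-phosphate dehydrogenase (lumped)",
        c(g6p = -1, glyc = 2), 0, b, "TOY_GPD1",
        "Glycerophospholipid metabolism"),
    rxn("PDC", "pyruvate decarboxylase", c(pyr = -1, acald = 1, co2 = 1),
        0, b, "TOY_PDC1", paste0("Pyruvate metabolism, ", ehrlich)),
    rxn("PDC2", "pyruvate decarboxylase (isoform 2)",
        c(pyr = -1, acald = 1, co2 = 1), 0, b, "TOY_PDC5",
        paste0("Pyruvate metabolism, ", ehrlich)),
    rxn("ADH", "alcohol dehydrogenase (acetaldehyde to ethanol)",
        c(acald = -1, etoh = 1), 0, b, "TOY_ADH1",
        "Glycolysis, Fermentation"),
    rxn("ADH2", "alcohol dehydrogenase (isoform 5)",
        c(acald = -1, etoh = 1), 0, b, "TOY_ADH5",
        "Glycolysis, Fermentation"),
    rxn("ACS", "acetyl-CoA synthesis (lumped)", c(acald = -1, acoa = 1),
        0, b, "TOY_ACS1", "Pyruvate metabolism"),
    rxn("HEM", "heme A synthesis (oxygen-requiring)",
        c(pyr = -2, o2 = -1, hemeA = 1), 0, b, "TOY_HEM1",
        "Heme biosynthesis"),
    rxn("BIOMASS", "biomass pseudo-reaction", bio_st, 0, b, "",
        "Growth")
  )
  if (V > 0) {
    for (v in seq_len(V)) {
      aa <- paste0("aa_", v); ka <- paste0("kacid_", v)
      fa <- paste0("fald_", v); fu <- paste0("fusol_", v)
      rxns <- dplyr::bind_rows(
        rxns,
        rxn(paste0("TA_", v), paste0("transaminase ", v),
            stats::setNames(c(-1, 1), c(aa, ka)), 0, b,
            paste0("TOY_BAT", v), paste0("Amino acid metabolism, ",
                                         ehrlich)),
        rxn(paste0("TA", v, "b"),
            paste0("transaminase ", v, " (isoform)"),
            stats::setNames(c(-1, 1), c(aa, ka)), 0, b,
            paste0("TOY_ARO", 8 + v), paste0("Amino acid metabolism, ",
                                             ehrlich)),
        rxn(paste0("KDC_", v),
            paste0("2-oxo acid decarboxylase ", v),
            stats::setNames(c(-1, 1, 1), c(ka, fa, "co2")), 0, b,
            paste0("TOY_ARO10_", v), ehrlich),
        rxn(paste0("ADHF_", v),
            paste0("fusel aldehyde dehydrogenase ", v),
            stats::setNames(c(-1, 1), c(fa, fu)), 0, b,
            paste0("TOY_SFA", v), ehrlich)
      )
    }
    rxns <- dplyr::bind_rows(
      rxns,
      rxn("ATF", "alcohol acetyltransferase (ester synthesis)",
          c(fusol_1 = -1, acoa = -1, ester = 1), 0, b, "TOY_ATF1",
          "Ester biosynthesis")
    )
  }

  ex <- function(met_id, name) {
    rxn(paste0("EX_", met_id), paste0(name, " exchange"),
        stats::setNames(-1, met_id), -b, b, "", "Exchange")
  }
  rxns <- dplyr::bind_rows(
    rxns,
    ex("glc", "D-glucose"), ex("o2", "oxygen"), ex("etoh", "ethanol"),
    ex("glyc", "glycerol"), ex("co2", "carbon dioxide")
  )
  if (V > 0) {
    for (v in seq_len(V)) {
      rxns <- dplyr::bind_rows(rxns, ex(paste0("aa_", v),
                                        paste0("amino acid ", v)),
                               ex(paste0("fusol_", v),
                                  paste0("fusel alcohol ", v)))
    }
    rxns <- dplyr::bind_rows(rxns, ex("ester", "acetate ester"))
  }
  rxns <- dplyr::bind_rows(
    rxns,
    rxn("EX_biomass", "biomass sink", c(biomass = -1), 0, b, "",
        "Exchange")
  )

  metabolic_model("toy_wine_network", mets, rxns,
                  biomass_reaction_id = "BIOMASS")
}

#' Define a multi-strain fermentation scenario
#'
#' A scenario specifies, per strain and growth phase (exponential /
#' deceleration / stationary, with boundaries at 36 h and 58 h), the
#' specific pathway rates from which both the synthetic time courses and
#' the ground-truth exchange fluxes are derived: glucose uptake `v_glc`,
#' the fraction of hexose routed to glycerol `f_glyc`, per-branch amino
#' acid uptakes `v_aa` (list of numeric vectors, one value per branch),
#' ester synthesis rate `v_ester`, and growth rate `mu`. All rates in
#' mmol gDW^-1 h^-1 except `mu` (h^-1).
#'
#' @param strains Strain names.
#' @param params Tibble with columns `strain`, `phase` (one of
#'   `"exponential"`, `"deceleration"`, `"stationary"`), `v_glc`,
#'   `f_glyc`, `v_ester`, `mu`, and `v_aa` (list-column).
#' @param noise_cv Multiplicative measurement noise coefficient of
#'   variation applied to every reading (truncated at +/- 3 CV).
#' @param seed RNG seed for the noise.
#' @param x0 Inoculum biomass (gDW/L).
#' @param c0 Named initial concentrations (mmol/L); compounds absent from
#'   `c0` start at 0.
#' @param dt Time-grid spacing (h).
#' @param horizon Fermentation length (h).
#' @param phase_bounds Phase boundaries (h), exponential ends at the
#'   first, deceleration at the second.
#' @param ground_truth Free-form list recording planted differences.
#' @return An object of class `strain_scenario`.
#' @export
strain_scenario <- function(strains, params, noise_cv = 0.001, seed = 1,
                            x0 = 0.2,
                            c0 = c(glucose = 1100, amino_acid_1 = 80,
                                   amino_acid_2 = 30),
                            dt = 2, horizon = 144,
                            phase_bounds = c(36, 58),
                            ground_truth = list()) {
  params <- tibble::as_tibble(params)
  stopifnot(all(c("strain", "phase", "v_glc", "f_glyc", "v_ester", "mu",
                  "v_aa") %in% names(params)),
            all(strains %in% params$strain))
  structure(
    list(strains = strains, params = params, noise_cv = noise_cv,
         seed = as.integer(seed), x0 = x0, c0 = c0, dt = dt,
         horizon = horizon, phase_bounds = phase_bounds,
         ground_truth = ground_truth),
    class = "strain_scenario"
  )
}

phase_at <- function(t, bounds) {
  ifelse(t < bounds[1], "exponential",
         ifelse(t < bounds[2], "deceleration", "stationary"))
}

# steady-state exchange fluxes implied by a phase's pathway rates on the
# anaerobic toy network (oxygen and heme synthesis at zero)
toy_exchange_fluxes <- function(p, n_branches) {
  v_aa <- p$v_aa[[1]]
  stopifnot(length(v_aa) >= n_branches)
  v_aa <- v_aa[seq_len(n_branches)]
  mu <- p$mu
  gpd <- p$f_glyc * p$v_glc
  pgk <- p$v_glc - gpd - 0.3 * mu
  ta <- v_aa - c(0.1 * mu, rep(0, n_branches - 1))
  if (pgk < 0 || any(ta < 0)) {
    stop("infeasible scenario phase: glycolysis or transaminase flux ",
         "would be negative")
  }
  pdc <- 2 * pgk - 0.2 * mu
  adh <- pdc - p$v_ester
  if (pdc < 0 || adh < 0 || ta[1] - p$v_ester < 0) {
    stop("infeasible scenario phase: ester rate exceeds upstream flux")
  }
  fluxes <- c(
    glucose = -p$v_glc,
    ethanol = adh,
    glycerol = 2 * gpd,
    ester_1 = p$v_ester
  )
  for (v in seq_len(n_branches)) {
    fluxes[paste0("amino_acid_", v)] <- -v_aa[v]
    fluxes[paste0("fusel_alcohol_", v)] <-
      ta[v] - if (v == 1) p$v_ester else 0
  }
  c(fluxes, mu = mu)
}

#' Map of measured compounds to toy-network exchange reactions
#' @param n_branch_vocs Number of Ehrlich branches in the network.
#' @return Named character vector compound -> exchange reaction id.
#' @export
toy_compound_mapping <- function(n_branch_vocs = 1) {
  m <- c(glucose = "EX_glc", ethanol = "EX_etoh", glycerol = "EX_glyc",
         ester_1 = "EX_ester")
  for (v in seq_len(n_branch_vocs)) {
    m[paste0("amino_acid_", v)] <- paste0("EX_aa_", v)
    m[paste0("fusel_alcohol_", v)] <- paste0("EX_fusol_", v)
  }
  m
}

#' Simulate multi-strain fermentation time courses
#'
#' Integrates, per strain on a fixed grid, the explicit-Euler updates
#' \eqn{C(t + \Delta t) = C(t) + q X(t) \Delta t} and
#' \eqn{X(t + \Delta t) = X(t)(1 + \mu \Delta t)} with phase-wise constant
#' specific rates q derived from the scenario's pathway parameters, then
#' applies multiplicative Gaussian noise (coefficient `noise_cv`,
#' truncated at three CV so readings stay positive) to every biomass and
#' concentration reading. Seeded and reproducible.
#'
#' @param model The toy network the scenario targets (its branch count
#'   sets which compounds exist).
#' @param scenario A `strain_scenario`.
#' @return Named list of `fermentation_series`, one per strain.
#' @export
simulate_strain_timeseries <- function(model, scenario) {
  stopifnot(inherits(scenario, "strain_scenario"))
  n_branches <- sum(grepl("^EX_aa_", model$reactions$id))
  times <- seq(0, scenario$horizon, by = scenario$dt)
  set.seed(scenario$seed)
  out <- lapply(scenario$strains, function(st) {
    pp <- dplyr::filter(scenario$params, .data$strain == st)
    q_by_phase <- lapply(split(pp, pp$phase), toy_exchange_fluxes,
                         n_branches = n_branches)
    compounds <- setdiff(names(q_by_phase[[1]]), "mu")
    C <- matrix(0, nrow = length(times), ncol = length(compounds),
                dimnames = list(NULL, compounds))
    X <- numeric(length(times))
    X[1] <- scenario$x0
    c0 <- scenario$c0
    C[1, intersect(compounds, names(c0))] <-
      c0[intersect(compounds, names(c0))]
    for (i in seq_len(length(times) - 1)) {
      ph <- phase_at(times[i], scenario$phase_bounds)
      q <- q_by_phase[[ph]]
      mu <- q[["mu"]]
      # exact piecewise-exponential integration: X grows as e^(mu dt) and
      # concentrations accumulate the exact integral of q X(t) over the
      # step (limit q X dt when mu = 0)
      growth_int <- if (mu == 0) scenario$dt else expm1(mu * scenario$dt) / mu
      C[i + 1, ] <- C[i, ] + q[compounds] * X[i] * growth_int
      X[i + 1] <- X[i] * exp(mu * scenario$dt)
    }
    if (any(C < 0)) {
      stop("scenario drives concentration(s) negative for strain ", st,
           "; increase initial concentrations or lower the rates")
    }
    noisy <- function(x) {
      if (scenario$noise_cv == 0) return(x)
      eps <- stats::rnorm(length(x), 0, scenario$noise_cv)
      eps <- pmin(pmax(eps, -3 * scenario$noise_cv),
                  3 * scenario$noise_cv)
      x * (1 + eps)
    }
    conc <- tibble::as_tibble(C)
    conc[] <- lapply(conc, noisy)
    fermentation_series(st, times, noisy(X), conc)
  })
  stats::setNames(out, scenario$strains)
}

#' Construct the four-strain benchmark scenario
#'
#' The shipped benchmark emulates a four-strain fermentation comparison on
#' the toy network: strains 1 and 2 share all rates (the similar pair),
#' strain 3 carries a 3x higher Ehrlich-branch amino-acid flux, and strain
#' 4 has globally lower VOC rates with higher central-carbon (glucose)
#' flux. Ground truth records the planted reactions, fold changes and the
#' expected first cluster merge.
#'
#' @param seed RNG seed for the measurement noise.
#' @param noise_cv Measurement noise CV (see the methods vignette for the
#'   default's rationale).
#' @return List with `model`, `scenario`, `expected` (ground truth).
#' @export
make_benchmark_scenario <- function(seed = 1, noise_cv = 0.001) {
  model <- build_toy_wine_network(n_branch_vocs = 1)
  strains <- paste0("strain", 1:4)

  base <- tibble::tribble(
    ~phase,         ~v_glc, ~f_glyc, ~v_ester, ~mu,
    "exponential",    2.5,    0.08,    0.030,  0.070,
    "deceleration",   1.8,    0.08,    0.020,  0.015,
    "stationary",     0.9,    0.06,    0.008,  0.000
  )
  base$v_aa <- list(0.25, 0.12, 0.03)

  mod <- list(
    strain1 = function(p) p,
    strain2 = function(p) p,
    strain3 = function(p) {               # 3x Ehrlich branch
      p$v_aa <- lapply(p$v_aa, `*`, 3)
      p
    },
    strain4 = function(p) {               # low VOC, high central carbon
      p$v_aa <- lapply(p$v_aa, `*`, 0.5)
      p$v_ester <- p$v_ester * 0.5
      p$v_glc <- p$v_glc * 1.3
      p
    }
  )
  params <- purrr::map_dfr(strains, function(st) {
    p <- mod[[st]](base)
    p$strain <- st
    p
  })

  scenario <- strain_scenario(
    strains = strains, params = params, noise_cv = noise_cv, seed = seed,
    c0 = c(glucose = 1100, amino_acid_1 = 100),
    ground_truth = list(
      similar_pair = c("strain1", "strain2"),
      ehrlich_strain = "strain3",
      ehrlich_fold = 3,
      ehrlich_reactions = c("TA_1", "TA1b", "KDC_1", "ADHF_1",
                            "EX_fusol_1", "EX_aa_1"),
      low_voc_strain = "strain4",
      expected_first_merge = c("strain1", "strain2")
    )
  )
  list(model = model, scenario = scenario,
       expected = scenario$ground_truth)
}
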