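#' Anaerobic (enological) modification recipe
#'
#' Describes how to convert an aerobically-parameterized yeast model into
#' its anaerobic fermentation state: oxygen exchange closed (LB = UB = 0),
#' sterol/fatty-acid uptakes opened (anaerobic growth requires supplemented
#' ergosterol and oleate because their biosynthesis needs molecular
#' oxygen), respiratory shuttle reactions blocked, and heme A removed from
#' the biomass equation (not used anaerobically).
#'
#' The default id lists are the conventional yeast-GEM reaction ids:
#' unrestricted uptake of ergosterol (r_1757), lanosterol (r_1915),
#' zymosterol (r_2106), 14-demethyllanosterol (r_2134),
#' ergosta-5,7,22,24(28)-tetraen-3beta-ol (r_2137) and oleate (r_2189);
#' blocked reactions r_0713, r_0714 (oxaloacetate-malate shuttle) and
#' r_0487 (glycerol dehydrogenase). Use [toy_anaerobic_recipe()] for the
#' built-in toy wine network.
#'
#' @param oxygen_exchange_id Id of the oxygen exchange reaction.
#' @param unrestricted_uptake_ids Exchange reactions whose uptake is opened.
#' @param blocked_reaction_ids Reactions forced to LB = UB = 0.
#' @param biomass_removals Metabolite ids deleted from the biomass
#'   stoichiometry.
#' @return An object of class `anaerobic_recipe`.
#' @export
anaerobic_recipe <- function(oxygen_exchange_id,
                             unrestricted_uptake_ids = c(
                               "r_1757", "r_1915", "r_2106",
                               "r_2134", "r_2137", "r_2189"),
                             blocked_reaction_ids = c(
                               "r_0713", "r_0714", "r_0487"),
                             biomass_removals = "s_3714") {
  structure(
    list(
      oxygen_exchange_id = oxygen_exchange_id,
      unrestricted_uptake_ids = unrestricted_uptake_ids,
      blocked_reaction_ids = blocked_reaction_ids,
      biomass_removals = biomass_removals
    ),
    class = "anaerobic_recipe"
  )
}

#' Anaerobic recipe for the built-in toy wine network
#'
#' Closes the toy oxygen exchange, blocks the oxygen-requiring heme
#' synthesis reaction and removes heme A from the toy biomass equation.
#' The toy network has no sterol analogues, so the unrestricted-uptake
#' list is empty.
#'
#' @return An `anaerobic_recipe` resolving in [build_toy_wine_network()]
#'   models.
#' @export
toy_anaerobic_recipe <- function() {
  anaerobic_recipe(
    oxygen_exchange_id = "EX_o2",
    unrestricted_uptake_ids = character(0),
    blocked_reaction_ids = "HEM",
    biomass_removals = "hemeA"
  )
}

#' Read/write an anaerobic recipe as YAML
#' @param path YAML file path.
#' @return `read_recipe_yaml()` returns an `anaerobic_recipe`;
#'   `write_recipe_yaml()` returns `path` invisibly.
#' @export
read_recipe_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  anaerobic_recipe(
    oxygen_exchange_id = x$oxygen_exchange_id,
    unrestricted_uptake_ids = as.character(x$unrestricted_uptake_ids %||% character(0)),
    blocked_reaction_ids = as.character(x$blocked_reaction_ids %||% character(0)),
    biomass_removals = as.character(x$biomass_removals %||% character(0))
  )
}

#' @rdname read_recipe_yaml
#' @param recipe An `anaerobic_recipe`.
#' @export
write_recipe_yaml <- function(recipe, path) {
  yaml::write_yaml(unclass(recipe), path)
  invisible(path)
}

#' Apply anaerobic modifications to a model
#'
#' Sets the oxygen exchange to LB = UB = 0, opens each listed uptake's
#' lower bound to the package default reversible minimum (-1000), blocks
#' the listed reactions at LB = UB = 0 and deletes the listed metabolites
#' from the biomass stoichiometry. All other reactions are untouched; the
#' operation never changes the number of reactions or metabolites and is
#' idempotent.
#'
#' @param model A `metabolic_model`.
#' @param recipe An `anaerobic_recipe`; all ids must resolve in the model.
#' @param uptake_bound Magnitude of the opened uptake lower bound.
#' @return The modified `metabolic_model`.
#' @export
apply_anaerobic_modifications <- function(model, recipe,
                                          uptake_bound = 1000) {
  validate_model(model)
  stopifnot(inherits(recipe, "anaerobic_recipe"))
  rx <- model$reactions
  need_rxn <- c(recipe$oxygen_exchange_id, recipe$unrestricted_uptake_ids,
                recipe$blocked_reaction_ids)
  missing_rxn <- setdiff(need_rxn, rx$id)
  missing_met <- setdiff(recipe$biomass_removals, model$metabolites$id)
  if (length(missing_rxn) + length(missing_met) > 0) {
    stop("anaerobic recipe ids not found in model: ",
         paste(c(missing_rxn, missing_met), collapse = ", "))
  }
  if (length(recipe$biomass_removals) > 0 &&
      is.na(model$biomass_reaction_id)) {
    stop("recipe removes biomass components but the model declares no ",
         "biomass reaction")
  }

  i_o2 <- match(recipe$oxygen_exchange_id, rx$id)
  rx$lower_bound[i_o2] <- 0
  rx$upper_bound[i_o2] <- 0
  i_up <- match(recipe$unrestricted_uptake_ids, rx$id)
  rx$lower_bound[i_up] <- -abs(uptake_bound)
  i_blk <- match(recipe$blocked_reaction_ids, rx$id)
  rx$lower_bound[i_blk] <- 0
  rx$upper_bound[i_blk] <- 0

  if (length(recipe$biomass_removals) > 0) {
    i_bio <- match(model$biomass_reaction_id, rx$id)
    st <- rx$stoichiometry[[i_bio]]
    st <- st[!names(st) %in% recipe$biomass_removals]
    if (length(st) == 0) stop("biomass stoichiometry emptied by removals")
    rx$stoichiometry[[i_bio]] <- st
  }
  model$reactions <- rx
  validate_model(model)
  model
}

#' Fix exchange bounds to measured fluxes
#'
#' Sets, for every constrained reaction, LB = flux - delta and
#' UB = flux + delta with `delta = tolerance_band * |flux|`; at the default
#' band of 0 this is the exact LB = UB = flux fixing of measured exchange
#' rates, with the biomass reaction fixed to the measured growth rate the
#' same way. Unconstrained exchanges keep their prior bounds. The band is a
#' relaxation knob for measurement-error-induced infeasibility.
#'
#' @param model A `metabolic_model`.
#' @param constraints Tibble with columns `reaction_id`, `flux`
#'   (mmol gDW^-1 h^-1; the biomass row carries the growth rate in h^-1).
#'   Extra columns (`strain`, `time_h`, ...) are ignored.
#' @param tolerance_band Relative half-width of the bound box (fraction).
#' @return The constrained `metabolic_model`.
#' @export
fix_exchange_fluxes <- function(model, constraints, tolerance_band = 0) {
  validate_model(model)
  constraints <- tibble::as_tibble(constraints)
  stopifnot(all(c("reaction_id", "flux") %in% names(constraints)),
            tolerance_band >= 0)
  if (any(!is.finite(constraints$flux))) {
    stop("non-finite flux in constraint set")
  }
  rx <- model$reactions
  unknown <- setdiff(constraints$reaction_id, rx$id)
  if (length(unknown) > 0) {
    stop("constraint ids not found in model: ",
         paste(unknown, collapse = ", "))
  }
  allowed <- c(find_exchange_reactions(model), model$biomass_reaction_id)
  bad <- setdiff(constraints$reaction_id, allowed)
  if (length(bad) > 0) {
    stop("constraints may only target exchange or biomass reactions; ",
         "offending ids: ", paste(bad, collapse = ", "))
  }
  for (k in seq_len(nrow(constraints))) {
    i <- match(constraints$reaction_id[k], rx$id)
    f <- constraints$flux[k]
    delta <- tolerance_band * abs(f)
    rx$lower_bound[i] <- f - delta
    rx$upper_bound[i] <- f + delta
  }
  if (any(rx$lower_bound > rx$upper_bound)) {
    stop("internal error: lb > ub after fixing exchange fluxes")
  }
  model$reactions <- rx
  model
}

#' Check feasibility of a constrained model
#'
#' Solves the phase-one LP "find v with Sv = 0, lb <= v <= ub" and returns
#' a witness flux vector when one exists.
#'
#' @param model A `metabolic_model`.
#' @param tol LP tolerance.
#' @return A list with `feasible` (logical) and `certificate` (named flux
#'   vector, or `NULL` when infeasible).
#' @export
check_feasibility <- function(model, tol = 1e-9) {
  system <- build_stoichiometric_system(model)
  res <- solve_lp(system, rep(0, length(system$reaction_ids)), "min", tol)
  if (res$status != "optimal") {
    return(list(feasible = FALSE, certificate = NULL))
  }
  list(feasible = TRUE, certificate = res$flux)
}

#' Reconcile measured fluxes with mass balance
#'
#' Projects a measured exchange-flux vector onto the mass-balance-
#' consistent set by solving the weighted least-squares program
#' \eqn{\min \sum_j ((v_j - f_j)/s_j)^2} subject to \eqn{Sv = 0} and the
#' model bounds, with scale \eqn{s_j = \max(|f_j|, \mathrm{median}|f|)} so
#' adjustments are relative to each flux's magnitude. This is the standard
#' measured-rate reconciliation used when exactly fixed noisy measurements
#' make the polytope empty. Unmeasured fluxes carry a negligible
#' regularization weight so the QP is strictly convex.
#'
#' @param model A `metabolic_model` (bounds as they will be sampled, i.e.
#'   after anaerobic modifications, before fixing).
#' @param constraints Constraint tibble as in [fix_exchange_fluxes()].
#' @return The constraint tibble with `flux` replaced by the reconciled
#'   values and the original measurements kept in `flux_measured`.
#' @export
reconcile_constraints <- function(model, constraints) {
  validate_model(model)
  constraints <- tibble::as_tibble(constraints)
  system <- build_stoichiometric_system(model)
  n <- length(system$reaction_ids)
  idx <- match(constraints$reaction_id, system$reaction_ids)
  if (anyNA(idx)) {
    stop("constraint ids not found in model: ",
         paste(constraints$reaction_id[is.na(idx)], collapse = ", "))
  }
  f <- constraints$flux
  s_floor <- stats::median(abs(f[f != 0]))
  if (!is.finite(s_floor) || s_floor == 0) s_floor <- 1
  w <- rep(1e-6 / s_floor^2, n)
  w[idx] <- 1 / pmax(abs(f), s_floor)^2
  target <- numeric(n)
  target[idx] <- f
  # drop linearly dependent mass-balance rows so the equality block of the
  # QP has full rank (solve.QP requires independent equalities)
  S <- system$S
  qrS <- qr(t(S))
  S <- S[qrS$pivot[seq_len(qrS$rank)], , drop = FALSE]
  # solve.QP: min 1/2 x'Dx - d'x  s.t.  A'x >= b (first meq are equalities)
  D <- diag(w, n)
  d <- w * target
  A <- cbind(t(S), diag(n), -diag(n))
  bvec <- c(rep(0, nrow(S)), unname(system$lb), -unname(system$ub))
  sol <- quadprog::solve.QP(D, d, A, bvec, meq = nrow(S))
  constraints$flux_measured <- constraints$flux
  constraints$flux <- sol$solution[idx]
  constraints
}
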