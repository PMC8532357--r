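#' Construct a fermentation time-course series
#'
#' A fermentation series holds one strain's biomass and compound
#' concentration measurements on a strictly increasing time grid. It is a
#' tibble with columns `strain`, `time_h`, `biomass_gDW_L` and one column
#' per measured compound (mmol/L).
#'
#' @param strain Strain name.
#' @param time_h Strictly increasing vector of sampling times (h).
#' @param biomass_gDW_L Biomass dry weight (gDW/L), positive, same length.
#' @param concentrations Named list or tibble of concentration vectors
#'   (mmol/L), each the same length as `time_h`.
#' @return A tibble of class `fermentation_series`.
#' @export
fermentation_series <- function(strain, time_h, biomass_gDW_L,
                                concentrations) {
  concentrations <- tibble::as_tibble(concentrations)
  out <- dplyr::bind_cols(
    tibble::tibble(strain = strain, time_h = time_h,
                   biomass_gDW_L = biomass_gDW_L),
    concentrations
  )
  validate_series(out)
  class(out) <- c("fermentation_series", class(out))
  out
}

validate_series <- function(series) {
  stopifnot(all(c("strain", "time_h", "biomass_gDW_L") %in% names(series)))
  if (nrow(series) < 3) {
    stop("fermentation series needs at least 3 time points")
  }
  if (any(diff(series$time_h) <= 0)) {
    stop("series times must be strictly increasing")
  }
  if (any(series$biomass_gDW_L <= 0)) {
    stop("biomass must be positive at every time point")
  }
  if (length(unique(series$strain)) != 1) {
    stop("a fermentation series holds exactly one strain")
  }
  invisible(series)
}

series_compounds <- function(series) {
  setdiff(names(series), c("strain", "time_h", "biomass_gDW_L"))
}

#' Read a fermentation series from CSV
#'
#' Expected columns: `time_h`, `biomass_gDW_L`, then one column per
#' compound in mmol/L. The strain name is taken from a `strain` column if
#' present, else from the file name.
#'
#' @param path CSV path.
#' @param strain Optional strain name override.
#' @return A `fermentation_series` tibble.
#' @export
read_fermentation_csv <- function(path, strain = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (is.null(strain)) {
    strain <- if ("strain" %in% names(x)) x$strain[[1]] else {
      tools::file_path_sans_ext(basename(path))
    }
  }
  x$strain <- NULL
  fermentation_series(strain, x$time_h, x$biomass_gDW_L,
                      x[setdiff(names(x), c("time_h", "biomass_gDW_L"))])
}

# central difference at interior points, one-sided at the ends; returns the
# raw time derivative of `values` at index i
finite_difference_at <- function(times, values, i) {
  n <- length(times)
  if (n < 2) stop("need at least 2 points for a finite difference")
  if (i == 1) {
    (values[2] - values[1]) / (times[2] - times[1])
  } else if (i == n) {
    (values[n] - values[n - 1]) / (times[n] - times[n - 1])
  } else {
    (values[i + 1] - values[i - 1]) / (times[i + 1] - times[i - 1])
  }
}

#' Estimate a specific extracellular flux from a time course
#'
#' Differentiates the concentration series at a measured time point by the
#' midpoint (central-difference) rule, using the concentration values on
#' both sides of the point — one-sided at the series endpoints — with no
#' prior smoothing, then normalizes by the biomass concentration:
#' \deqn{q_i = \frac{C(t_{i+1}) - C(t_{i-1})}{t_{i+1} - t_{i-1}} \cdot
#'   \frac{1}{X(t_i)}.}
#' Consumption yields negative flux, production positive, matching the
#' exchange-reaction sign convention.
#'
#' @param series A `fermentation_series`.
#' @param compound Compound column name.
#' @param time_h One of the series' time points.
#' @param biomass_at `"point"` normalizes by X at the evaluation point;
#'   `"interval"` by the mean of X over the difference stencil.
#' @return Specific flux in mmol gDW^-1 h^-1.
#' @export
estimate_specific_flux <- function(series, compound, time_h,
                                   biomass_at = c("point", "interval")) {
  biomass_at <- match.arg(biomass_at)
  validate_series(series)
  if (!compound %in% series_compounds(series)) {
    stop("compound '", compound, "' not measured in this series")
  }
  i <- match(time_h, series$time_h)
  if (is.na(i)) stop("time ", time_h, " h is not a measured time point")
  dCdt <- finite_difference_at(series$time_h, series[[compound]], i)
  X <- stencil_biomass(series, i, biomass_at)
  dCdt / X
}

#' Estimate the specific growth rate from a time course
#'
#' Central difference of the biomass series divided by the biomass at the
#' point (one-sided at the endpoints):
#' \eqn{\mu(t_i) = X'(t_i) / X(t_i)} in h^-1.
#'
#' @inheritParams estimate_specific_flux
#' @return Specific growth rate in h^-1.
#' @export
estimate_growth_rate <- function(series, time_h,
                                 biomass_at = c("point", "interval")) {
  biomass_at <- match.arg(biomass_at)
  validate_series(series)
  i <- match(time_h, series$time_h)
  if (is.na(i)) stop("time ", time_h, " h is not a measured time point")
  dXdt <- finite_difference_at(series$time_h, series$biomass_gDW_L, i)
  dXdt / stencil_biomass(series, i, biomass_at)
}

stencil_biomass <- function(series, i, biomass_at) {
  if (biomass_at == "point") return(series$biomass_gDW_L[i])
  n <- nrow(series)
  lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
  mean(series$biomass_gDW_L[c(lo, hi)])
}

#' Build a constraint flux table from fermentation series
#'
#' Evaluates every mapped compound's specific flux and the specific growth
#' rate at each requested time point for each strain, producing one
#' constraint set per strain x time: the inputs that fix the model's
#' exchange bounds before sampling.
#'
#' @param series_by_strain List of `fermentation_series` (one per strain).
#' @param time_points Times (h) at which to evaluate; must exist in every
#'   series.
#' @param mapping Named character vector, compound name -> exchange
#'   reaction id.
#' @param biomass_reaction_id Reaction id to carry the growth rate.
#' @param biomass_at Passed to the estimators.
#' @return A tibble of class `flux_table` with columns `strain`, `time_h`,
#'   `reaction_id`, `compound`, `flux`; the mapping is kept in the
#'   `"compound_to_exchange"` attribute.
#' @export
build_flux_table <- function(series_by_strain, time_points, mapping,
                             biomass_reaction_id = "BIOMASS",
                             biomass_at = c("point", "interval")) {
  biomass_at <- match.arg(biomass_at)
  stopifnot(length(mapping) > 0, !is.null(names(mapping)))
  rows <- purrr::map_dfr(series_by_strain, function(series) {
    validate_series(series)
    strain <- series$strain[[1]]
    missing_t <- setdiff(time_points, series$time_h)
    if (length(missing_t) > 0) {
      stop("strain ", strain, ": requested time(s) not in series: ",
           paste(missing_t, collapse = ", "))
    }
    compounds <- series_compounds(series)
    unmapped <- setdiff(compounds, names(mapping))
    if (length(unmapped) > 0) {
      warning("strain ", strain, ": unmapped compound(s) excluded: ",
              paste(unmapped, collapse = ", "))
    }
    used <- intersect(compounds, names(mapping))
    purrr::map_dfr(time_points, function(tp) {
      fluxes <- vapply(used, function(cp) {
        estimate_specific_flux(series, cp, tp, biomass_at)
      }, numeric(1))
      mu <- estimate_growth_rate(series, tp, biomass_at)
      tibble::tibble(
        strain = strain, time_h = tp,
        reaction_id = c(unname(mapping[used]), biomass_reaction_id),
        compound = c(used, "biomass"),
        flux = c(unname(fluxes), mu)
      )
    })
  })
  if (anyDuplicated(dplyr::distinct(rows, strain, time_h,
                                    reaction_id)) > 0) {
    stop("duplicate (strain, time, reaction) constraint rows")
  }
  attr(rows, "compound_to_exchange") <- mapping
  class(rows) <- c("flux_table", class(rows))
  rows
}

#' Read/write a constraint flux table as CSV
#' @param path CSV path.
#' @return `read_flux_table_csv()` returns a `flux_table` tibble.
#' @export
read_flux_table_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("strain", "time_h", "reaction_id", "flux") %in% names(x)))
  class(x) <- c("flux_table", class(x))
  x
}

#' @rdname read_flux_table_csv
#' @param flux_table A `flux_table` tibble.
#' @export
write_flux_table_csv <- function(flux_table, path) {
  readr::write_csv(flux_table, path)
  invisible(path)
}
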