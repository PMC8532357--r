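#' Pipeline run configuration
#'
#' Collects every knob of an end-to-end run: inputs (model, series,
#' recipe), evaluation time points, sampler settings, ranking and
#' statistics options, and the output directory. `model = "toy"`,
#' `series = "benchmark"` and `recipe = "toy"` select the built-in
#' network, the shipped four-strain benchmark scenario and the toy
#' anaerobic recipe.
#'
#' @param out_dir Output directory (created if needed).
#' @param model `"toy"`, or a path to an SBML / internal-JSON model.
#' @param series `"benchmark"`, or a character vector of per-strain CSV
#'   paths.
#' @param recipe `"toy"`, or a path to a recipe YAML.
#' @param mapping Compound-to-exchange mapping (named character); filled
#'   automatically for the built-in inputs.
#' @param time_points Evaluation times (h).
#' @param n_samples Recorded samples per strain x time point.
#' @param seed Master seed; per-condition sampler seeds are derived from
#'   it.
#' @param ranking_k Top-k size for the rankings.
#' @param rank_at Time point (h) whose top-k absolute ranking also defines
#'   the clustergram reaction subset (the top fluxes at the early time
#'   point are reused to compare all times).
#' @param min_abs_flux Miniscule-flux exclusion threshold for the percent
#'   ranking.
#' @param pca_scale Unit-variance scaling for the PCA.
#' @param linkage Clustering linkage.
#' @param band_ladder Relative bound-relaxation bands tried, in order,
#'   when the exactly-fixed constraints are infeasible.
#' @param infeasible_action `"reconcile"` (least-squares flux
#'   reconciliation after the ladder fails) or `"abort"`.
#' @param bins Histogram bins.
#' @param thin,projection_period,tolerance Sampler details, see
#'   [sampler_config()].
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, model = "toy", series = "benchmark",
                       recipe = "toy", mapping = NULL,
                       time_points = c(24, 58, 144), n_samples = 2000,
                       seed = 7, ranking_k = 20, rank_at = 24,
                       min_abs_flux = 1e-12, pca_scale = TRUE,
                       linkage = "average", band_ladder = c(0, 0.05),
                       infeasible_action = c("reconcile", "abort"),
                       bins = 30, thin = NULL, projection_period = 50,
                       tolerance = 1e-6) {
  infeasible_action <- match.arg(infeasible_action)
  stopifnot(ranking_k >= 1, length(time_points) >= 1)
  if (!identical(model, "toy") && !file.exists(model)) {
    stop("model file does not exist: ", model)
  }
  if (!identical(series, "benchmark")) {
    missing <- series[!file.exists(series)]
    if (length(missing) > 0) {
      stop("series file(s) do not exist: ", paste(missing, collapse = ", "))
    }
  }
  if (!identical(recipe, "toy") && !file.exists(recipe)) {
    stop("recipe file does not exist: ", recipe)
  }
  structure(
    list(out_dir = out_dir, model = model, series = series,
         recipe = recipe, mapping = mapping, time_points = time_points,
         n_samples = n_samples, seed = as.integer(seed),
         ranking_k = ranking_k, rank_at = rank_at,
         min_abs_flux = min_abs_flux, pca_scale = pca_scale,
         linkage = linkage, band_ladder = band_ladder,
         infeasible_action = infeasible_action, bins = bins, thin = thin,
         projection_period = projection_period, tolerance = tolerance),
    class = "run_config"
  )
}

#' Run the full strain-comparison pipeline
#'
#' Data to fluxes to constrained model to sampling to comparison reports:
#' estimates extracellular fluxes from the time courses, applies the
#' anaerobic recipe, fixes exchange bounds per strain and time point
#' (band ladder, then least-squares reconciliation when configured),
#' samples every constrained polytope, and writes the median table,
#' absolute and percent rankings, per-time-point PCA reports, the strain
#' clustergram (Newick) and per-condition sample/constraint files, plus a
#' `manifest.json` with seeds, checksums and timings. The manifest is
#' written even when a stage fails, with the failure recorded.
#'
#' @param config A `run_config`.
#' @return The manifest, invisibly a list (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("vinoflux")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    status = "failed", failure_stage = NA_character_,
    files = list(), conditions = list()
  )
  finish <- function() {
    manifest$finished <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  record <- function(path) {
    manifest$files[[basename(path)]] <<-
      unname(tools::md5sum(path))
  }
  result <- tryCatch({
    t0 <- Sys.time()
    manifest$failure_stage <- "load-inputs"
    model <- if (identical(config$model, "toy")) {
      build_toy_wine_network()
    } else if (grepl("\\.json$", config$model)) {
      read_model(config$model, "internal-json")
    } else {
      read_model(config$model, "sbml")
    }
    if (identical(config$series, "benchmark")) {
      bench <- make_benchmark_scenario(seed = config$seed)
      model <- bench$model
      series <- simulate_strain_timeseries(model, bench$scenario)
      mapping <- toy_compound_mapping(
        sum(grepl("^EX_aa_", model$reactions$id)))
    } else {
      series <- lapply(config$series, read_fermentation_csv)
      mapping <- config$mapping
      if (is.null(mapping)) stop("mapping required for external series")
    }
    recipe <- if (identical(config$recipe, "toy")) {
      toy_anaerobic_recipe()
    } else {
      read_recipe_yaml(config$recipe)
    }

    manifest$failure_stage <- "flux-estimation"
    flux_table <- build_flux_table(series, config$time_points, mapping,
                                   biomass_reaction_id =
                                     model$biomass_reaction_id)
    ft_path <- file.path(config$out_dir, "flux_table.csv")
    write_flux_table_csv(flux_table, ft_path); record(ft_path)

    manifest$failure_stage <- "anaerobic-setup"
    model_an <- apply_anaerobic_modifications(model, recipe)

    manifest$failure_stage <- "sampling"
    conditions <- dplyr::distinct(flux_table, .data$strain, .data$time_h)
    sample_sets <- vector("list", nrow(conditions))
    for (i in seq_len(nrow(conditions))) {
      st <- conditions$strain[i]; tp <- conditions$time_h[i]
      cons <- dplyr::filter(flux_table, .data$strain == st,
                            .data$time_h == tp)
      fitted <- fit_constraints(model_an, cons, config$band_ladder,
                                config$infeasible_action)
      if (is.null(fitted)) {
        stop("constraints infeasible for ", st, " at ", tp,
             " h after band ladder (",
             paste(config$band_ladder, collapse = ", "), ")")
      }
      cfg <- sampler_config(
        n_samples = config$n_samples, seed = config$seed + 7919L * i,
        thin = config$thin,
        projection_period = config$projection_period,
        tolerance = config$tolerance)
      sys_i <- build_stoichiometric_system(fitted$model)
      ss <- achr_sample(sys_i, cfg, strain = st, time_h = tp)
      rep_i <- check_sample_validity(ss, sys_i)
      if (rep_i$n_bound_violations > 0) {
        stop("sample validity failure for ", st, " at ", tp, " h: ",
             rep_i$n_bound_violations, " bound violations")
      }
      # recorded per condition; the z uses an iid standard error, so
      # residual autocorrelation inflates it — warn only when clearly
      # unmixed
      diag_z <- max(abs(sampling_diagnostics(ss)$z))
      if (diag_z > 20) {
        warning("chain mixing diagnostic |z| = ", round(diag_z, 1),
                " for ", st, " at ", tp, " h; consider a larger thin")
      }
      manifest$conditions[[paste0(st, "_", tp, "h")]] <- list(
        band = fitted$band, reconciled = fitted$reconciled,
        max_abs_sv = rep_i$max_abs_sv,
        max_mean_split_z = diag_z,
        seed = cfg$seed)
      sp <- file.path(config$out_dir,
                      sprintf("samples_%s_%sh.csv", st, tp))
      readr::write_csv(tibble::as_tibble(ss$samples), sp); record(sp)
      sample_sets[[i]] <- ss
    }
    manifest$n_sample_sets <- length(sample_sets)

    manifest$failure_stage <- "comparison"
    strains_of <- vapply(sample_sets, function(s) s$strain, character(1))
    times_of <- vapply(sample_sets, function(s) s$time_h, numeric(1))

    medians_all <- reaction_medians(sample_sets)
    mpath <- file.path(config$out_dir, "median_table.csv")
    readr::write_csv(medians_all, mpath); record(mpath)

    med_rank <- dplyr::filter(medians_all, .data$time_h == config$rank_at)
    rank_abs <- annotate_ranking(
      rank_absolute_median_difference(med_rank, config$ranking_k), model)
    rank_pct <- annotate_ranking(
      rank_percent_median_difference(med_rank, config$ranking_k,
                                     config$min_abs_flux), model)
    rp1 <- file.path(config$out_dir, "ranking_absolute.csv")
    rp2 <- file.path(config$out_dir, "ranking_percent.csv")
    readr::write_csv(rank_abs, rp1); record(rp1)
    readr::write_csv(rank_pct, rp2); record(rp2)
    manifest$n_rankings <- 2L

    # PCA per time point on the measured extracellular fluxes
    manifest$n_pca_reports <- 0L
    for (tp in config$time_points) {
      wide <- flux_table |>
        dplyr::filter(.data$time_h == tp) |>
        dplyr::select("strain", "reaction_id", "flux") |>
        tidyr::pivot_wider(names_from = "reaction_id",
                           values_from = "flux")
      m <- as.matrix(wide[, -1, drop = FALSE])
      rownames(m) <- wide$strain
      keep <- apply(m, 2, function(x) stats::sd(x) > 1e-12 * max(1, max(abs(x))))
      pca <- pca_with_cos2(m[, keep, drop = FALSE],
                           scale = config$pca_scale)
      pp <- file.path(config$out_dir, sprintf("pca_%sh.csv", tp))
      readr::write_csv(dplyr::bind_rows(
        tidy(pca, "scores") |> dplyr::mutate(matrix = "scores"),
        tidy(pca, "loadings") |>
          dplyr::rename(observation = "variable") |>
          dplyr::mutate(matrix = "loadings"),
        tidy(pca, "cos2_variables") |>
          dplyr::rename(observation = "variable") |>
          dplyr::mutate(matrix = "cos2_variables"),
        tibble::tibble(observation = "all",
                       component = paste0("PC", seq_along(
                         pca$variance_explained)),
                       value = pca$variance_explained,
                       matrix = "variance_explained")
      ), pp); record(pp)
      manifest$n_pca_reports <- manifest$n_pca_reports + 1L
    }

    clust <- cluster_strains(med_rank, subset = rank_abs$reaction_id,
                             linkage = config$linkage)
    np <- file.path(config$out_dir, "clustergram.nwk")
    cluster_newick(clust, np); record(np)
    cp <- file.path(config$out_dir, "strain_correlation.csv")
    readr::write_csv(tibble::as_tibble(clust$correlation,
                                       rownames = "strain"), cp)
    record(cp)
    manifest$n_clustergrams <- 1L

    hist_ids <- rank_abs$reaction_id[seq_len(min(6,
                                                 nrow(rank_abs)))]
    hr <- histogram_report(sample_sets, hist_ids, config$bins)
    hp <- file.path(config$out_dir, "histograms.csv")
    readr::write_csv(hr, hp); record(hp)

    manifest$status <- "ok"
    manifest$failure_stage <- NA_character_
    manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0,
                                              units = "secs"))
    list(manifest = manifest, sample_sets = sample_sets,
         medians = medians_all, ranking_absolute = rank_abs,
         ranking_percent = rank_pct, clustering = clust,
         flux_table = flux_table)
  }, error = function(e) {
    manifest$error <<- conditionMessage(e)
    finish()
    stop(e)
  })
  manifest <- result$manifest
  finish()
  invisible(result)
}

# try the band ladder, then optionally reconcile; returns the constrained
# model plus how feasibility was achieved, or NULL
fit_constraints <- function(model_an, cons, band_ladder,
                            infeasible_action) {
  for (band in band_ladder) {
    m2 <- fix_exchange_fluxes(model_an, cons, band)
    if (check_feasibility(m2)$feasible) {
      return(list(model = m2, band = band, reconciled = FALSE))
    }
  }
  if (infeasible_action == "reconcile") {
    cons2 <- reconcile_constraints(model_an, cons)
    m2 <- fix_exchange_fluxes(model_an, cons2, 0)
    if (check_feasibility(m2)$feasible) {
      return(list(model = m2, band = 0, reconciled = TRUE))
    }
  }
  NULL
}
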