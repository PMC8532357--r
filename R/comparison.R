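#' Per-reaction sample medians for each strain
#'
#' Column medians of each strain's flux sample matrix: the summary on
#' which the median-difference rankings and the clustergram are built.
#'
#' @param sample_sets List of `sample_set` objects sharing reaction ids.
#' @return A tibble of class `median_table` with columns `strain`,
#'   `time_h`, `reaction_id`, `median_flux`.
#' @export
reaction_medians <- function(sample_sets) {
  stopifnot(length(sample_sets) >= 1,
            all(vapply(sample_sets, inherits, logical(1), "sample_set")))
  ids <- sample_sets[[1]]$reaction_ids
  for (s in sample_sets) {
    if (!identical(s$reaction_ids, ids)) {
      stop("all sample sets must share the same reaction ids")
    }
  }
  out <- purrr::map_dfr(sample_sets, function(s) {
    tibble::tibble(
      strain = s$strain, time_h = s$time_h, reaction_id = ids,
      median_flux = unname(apply(s$samples, 2, stats::median))
    )
  })
  class(out) <- c("median_table", class(out))
  out
}

median_matrix <- function(table) {
  wide <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(table), "strain", "reaction_id",
                  "median_flux"),
    names_from = "reaction_id", values_from = "median_flux")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$strain
  m
}

check_median_table <- function(table) {
  stopifnot(all(c("strain", "reaction_id", "median_flux") %in%
                  names(table)))
  if (anyDuplicated(paste(table$strain, table$reaction_id))) {
    stop("median table has duplicate (strain, reaction) entries; ",
         "filter to one time point first")
  }
  invisible(table)
}

#' Rank reactions by absolute median difference across strains
#'
#' For each reaction the spread is the range of its per-strain sample
#' medians, \eqn{\max_s m_{sr} - \min_s m_{sr}} (identical to the largest
#' pairwise absolute difference). Reactions are ordered by spread
#' descending, ties broken lexicographically by reaction id, and the top k
#' kept — the shortlist of fluxes that most distinguish the strains.
#'
#' @param table A `median_table` (one time point).
#' @param k Number of reactions to keep (default 20).
#' @return A tibble of class `reaction_ranking`: `rank`, `reaction_id`,
#'   `spread`, one median column per strain; `mode` attribute
#'   `"absolute"`.
#' @export
rank_absolute_median_difference <- function(table, k = 20) {
  check_median_table(table)
  if (length(unique(table$strain)) < 2) {
    stop("ranking needs at least 2 strains")
  }
  spread <- tibble::as_tibble(table) |>
    dplyr::group_by(.data$reaction_id) |>
    dplyr::summarise(spread = max(.data$median_flux) -
                       min(.data$median_flux), .groups = "drop")
  finish_ranking(table, spread, k, mode = "absolute")
}

#' Rank reactions by percent median difference across strains
#'
#' Reactions whose largest absolute per-strain median falls below
#' `min_abs_flux` are excluded first: such miniscule fluxes (below 1e-12
#' mmol gDW^-1 h^-1 by default) carry no metabolic signal and would
#' dominate a relative ranking. For the rest the percent spread is
#' \eqn{100 (\max_s m_{sr} - \min_s m_{sr}) / \max(|\tilde m_r|,
#' \epsilon)} with \eqn{\tilde m_r} the grand median over strains.
#'
#' @inheritParams rank_absolute_median_difference
#' @param min_abs_flux Exclusion threshold and denominator floor.
#' @return A `reaction_ranking` tibble with `percent_spread`; `mode`
#'   attribute `"percent"`.
#' @export
rank_percent_median_difference <- function(table, k = 20,
                                           min_abs_flux = 1e-12) {
  check_median_table(table)
  if (length(unique(table$strain)) < 2) {
    stop("ranking needs at least 2 strains")
  }
  spread <- tibble::as_tibble(table) |>
    dplyr::group_by(.data$reaction_id) |>
    dplyr::summarise(
      max_abs_median = max(abs(.data$median_flux)),
      grand_median = stats::median(.data$median_flux),
      spread = 100 * (max(.data$median_flux) - min(.data$median_flux)) /
        max(abs(stats::median(.data$median_flux)), min_abs_flux),
      .groups = "drop") |>
    dplyr::filter(.data$max_abs_median >= min_abs_flux) |>
    dplyr::select("reaction_id", "spread")
  out <- finish_ranking(table, spread, k, mode = "percent")
  dplyr::rename(out, percent_spread = "spread")
}

finish_ranking <- function(table, spread, k, mode) {
  medians_wide <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(table), "strain", "reaction_id",
                  "median_flux"),
    names_from = "strain", values_from = "median_flux")
  out <- spread |>
    dplyr::arrange(dplyr::desc(.data$spread), .data$reaction_id) |>
    utils::head(k) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1) |>
    dplyr::left_join(medians_wide, by = "reaction_id")
  attr(out, "mode") <- mode
  attr(out, "k") <- k
  class(out) <- c("reaction_ranking", class(out))
  out
}

#' Annotate a ranking with model gene associations and subsystems
#'
#' @param ranking A `reaction_ranking`.
#' @param model The `metabolic_model` the reactions come from.
#' @return The ranking with `reaction_name`, `gene_association` and
#'   `subsystem` columns added.
#' @export
annotate_ranking <- function(ranking, model) {
  ann <- dplyr::select(model$reactions, reaction_id = "id",
                       reaction_name = "name", "gene_association",
                       "subsystem")
  out <- dplyr::left_join(tibble::as_tibble(ranking), ann,
                          by = "reaction_id")
  attributes(out)[c("mode", "k")] <- attributes(ranking)[c("mode", "k")]
  class(out) <- class(ranking)
  out
}

#' Principal component analysis with squared-cosine diagnostics
#'
#' Centered (and, by default, unit-variance scaled) PCA via singular value
#' decomposition. The squared cosine (cos2) measures how well a component
#' represents a variable or an observation: for variables it is the
#' squared correlation with the component (for scaled PCA each variable's
#' cos2 sums to 1 over all components); for observations it is the squared
#' score divided by the observation's squared distance to the origin in
#' centered space.
#'
#' @param flux_matrix Observations x variables: a numeric matrix with row
#'   names, or a data frame whose first non-numeric column labels the
#'   observations.
#' @param scale Scale variables to unit variance (the usual convention for
#'   fluxes of heterogeneous magnitude).
#' @return An object of class `flux_pca` with `scores`, `loadings`,
#'   `variance_explained`, `cos2_variables`, `cos2_individuals`.
#' @export
pca_with_cos2 <- function(flux_matrix, scale = TRUE) {
  if (is.data.frame(flux_matrix)) {
    num <- vapply(flux_matrix, is.numeric, logical(1))
    labels <- if (any(!num)) {
      as.character(flux_matrix[[which(!num)[1]]])
    } else {
      rownames(flux_matrix) %||% as.character(seq_len(nrow(flux_matrix)))
    }
    flux_matrix <- as.matrix(flux_matrix[, num, drop = FALSE])
    rownames(flux_matrix) <- labels
  }
  stopifnot(is.matrix(flux_matrix), nrow(flux_matrix) >= 2,
            ncol(flux_matrix) >= 2)
  if (is.null(rownames(flux_matrix))) {
    rownames(flux_matrix) <- as.character(seq_len(nrow(flux_matrix)))
  }
  vars <- apply(flux_matrix, 2, stats::var)
  if (scale && any(vars < .Machine$double.eps)) {
    stop("constant variable(s) cannot be scaled: ",
         paste(colnames(flux_matrix)[vars < .Machine$double.eps],
               collapse = ", "))
  }
  pc <- stats::prcomp(flux_matrix, center = TRUE, scale. = scale)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  ncomp <- length(pc$sdev)

  # variable cos2: squared correlation with each component; computed from
  # loadings * sdev so null components contribute exactly 0
  col_sd <- if (scale) rep(1, ncol(flux_matrix)) else sqrt(vars)
  corr <- sweep(pc$rotation, 2, pc$sdev, "*") / col_sd
  cos2_vars <- corr^2

  d2 <- rowSums(pc$x^2)
  cos2_ind <- pc$x^2 / ifelse(d2 > 0, d2, 1)

  structure(
    list(
      scores = pc$x,
      loadings = pc$rotation,
      variance_explained = ve,
      cos2_variables = cos2_vars,
      cos2_individuals = cos2_ind,
      scale = scale,
      sdev = pc$sdev
    ),
    class = "flux_pca"
  )
}

#' @export
print.flux_pca <- function(x, ...) {
  cat("<flux_pca> ", nrow(x$scores), " observations x ",
      nrow(x$loadings), " variables\n", sep = "")
  ve <- round(100 * x$variance_explained[seq_len(min(3, length(
    x$variance_explained)))], 1)
  cat("  variance explained: ",
      paste0("PC", seq_along(ve), " = ", ve, "%", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Tidy PCA results
#'
#' @param x A `flux_pca`.
#' @param matrix One of `"scores"`, `"loadings"`, `"cos2_variables"`,
#'   `"cos2_individuals"`.
#' @param ... Unused.
#' @return A long tibble (`observation`/`variable`, `component`, `value`).
#' @export
tidy.flux_pca <- function(x, matrix = c("scores", "loadings",
                                        "cos2_variables",
                                        "cos2_individuals"), ...) {
  matrix <- match.arg(matrix)
  m <- x[[matrix]]
  who <- if (matrix %in% c("scores", "cos2_individuals")) {
    "observation"
  } else "variable"
  tibble::as_tibble(m, rownames = who) |>
    tidyr::pivot_longer(-dplyr::all_of(who), names_to = "component",
                        values_to = "value")
}

#' One-row PCA summary
#' @param x A `flux_pca`.
#' @param ... Unused.
#' @return Tibble with component count and the variance explained by the
#'   first two components (the paper-style "PC1 + PC2" headline figure).
#' @export
glance.flux_pca <- function(x, ...) {
  ve <- x$variance_explained
  tibble::tibble(
    n_components = length(ve),
    pc1_pct = 100 * ve[1],
    pc2_pct = 100 * dplyr::coalesce(ve[2], 0),
    pc1_pc2_pct = 100 * sum(ve[seq_len(min(2, length(ve)))])
  )
}

#' Hierarchically cluster strains on their median flux vectors
#'
#' Distance is 1 minus the Pearson correlation between strain median-flux
#' vectors (so clustering is invariant to positive rescaling of any
#' strain), followed by agglomerative clustering with average linkage by
#' default — the clustergram view of how alike the strains' predicted
#' metabolic states are.
#'
#' @param table A `median_table` (one time point).
#' @param subset Optional reaction ids to restrict to (e.g. the top-20
#'   ranking, or an aroma-associated subset).
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return An object of class `strain_clust`: `correlation` (strains x
#'   strains Pearson matrix), `hclust`, `linkage`.
#' @export
cluster_strains <- function(table, subset = NULL,
                            linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  check_median_table(table)
  m <- median_matrix(table)
  if (nrow(m) < 2) stop("clustering needs at least 2 strains")
  if (!is.null(subset)) {
    missing <- setdiff(subset, colnames(m))
    if (length(missing) > 0) {
      stop("subset reaction ids not in median table: ",
           paste(missing, collapse = ", "))
    }
    m <- m[, subset, drop = FALSE]
  }
  sds <- apply(m, 1, stats::sd)
  if (any(sds < .Machine$double.eps)) {
    stop("strain(s) with constant median vector cannot be correlated: ",
         paste(rownames(m)[sds < .Machine$double.eps], collapse = ", "))
  }
  corr <- stats::cor(t(m), method = "pearson")
  hc <- stats::hclust(stats::as.dist(1 - corr), method = linkage)
  structure(list(correlation = corr, hclust = hc, linkage = linkage),
            class = "strain_clust")
}

#' @export
print.strain_clust <- function(x, ...) {
  cat("<strain_clust> ", nrow(x$correlation), " strains, ", x$linkage,
      " linkage on 1 - Pearson distance\n", sep = "")
  cat("  first merge: ",
      paste(first_merge(x), collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' Strains joined by the first (lowest) merge of the dendrogram
#' @param clust A `strain_clust`.
#' @return Character vector of the strain labels merged first.
#' @export
first_merge <- function(clust) {
  stopifnot(inherits(clust, "strain_clust"))
  hc <- clust$hclust
  pair <- hc$merge[1, ]
  sort(hc$labels[-pair])
}

#' Tidy the cluster merge tree
#' @param x A `strain_clust`.
#' @param ... Unused.
#' @return Tibble with one row per merge: `merge`, `height`, `members`
#'   (list-column of strain labels in the merged cluster).
#' @export
tidy.strain_clust <- function(x, ...) {
  hc <- x$hclust
  members <- vector("list", nrow(hc$merge))
  get_members <- function(idx) {
    if (idx < 0) hc$labels[-idx] else members[[idx]]
  }
  for (i in seq_len(nrow(hc$merge))) {
    members[[i]] <- sort(c(get_members(hc$merge[i, 1]),
                           get_members(hc$merge[i, 2])))
  }
  tibble::tibble(merge = seq_along(hc$height), height = hc$height,
                 members = members)
}

#' Export a strain dendrogram as Newick text
#' @param clust A `strain_clust`.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when writing to file.
#' @export
cluster_newick <- function(clust, path = NULL) {
  stopifnot(inherits(clust, "strain_clust"))
  phy <- ape::as.phylo(clust$hclust)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(path)
  }
}

#' Relative-frequency flux histograms per reaction and strain
#'
#' Histograms of the sampled flux of selected reactions, computed on a
#' shared per-reaction range across strains so distributions are directly
#' comparable; frequencies are normalized to sum to 1 within each strain
#' and reaction.
#'
#' @param sample_sets List of `sample_set` objects.
#' @param reaction_ids Reactions to summarize.
#' @param bins Number of bins.
#' @return Tibble: `reaction_id`, `strain`, `time_h`, `bin_lo`, `bin_hi`,
#'   `bin_mid`, `rel_freq`.
#' @export
histogram_report <- function(sample_sets, reaction_ids, bins = 30) {
  stopifnot(length(sample_sets) >= 1, bins >= 1)
  ids0 <- sample_sets[[1]]$reaction_ids
  missing <- setdiff(reaction_ids, ids0)
  if (length(missing) > 0) {
    stop("unknown reaction id(s): ", paste(missing, collapse = ", "))
  }
  purrr::map_dfr(reaction_ids, function(rid) {
    vals <- purrr::map(sample_sets, ~ .x$samples[, rid])
    rng <- range(unlist(vals))
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = bins + 1)
    purrr::map_dfr(seq_along(sample_sets), function(si) {
      s <- sample_sets[[si]]
      h <- graphics::hist(vals[[si]], breaks = breaks, plot = FALSE)
      tibble::tibble(
        reaction_id = rid, strain = s$strain, time_h = s$time_h,
        bin_lo = utils::head(breaks, -1), bin_hi = breaks[-1],
        bin_mid = h$mids, rel_freq = h$counts / sum(h$counts)
      )
    })
  })
}
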