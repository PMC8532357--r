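#' Plot PCA factor maps
#'
#' `which = "individuals"` draws the observation (strain) factor map;
#' `which = "variables"` draws the variable map with points colored by
#' their cos2 on the displayed components, highlighting which fluxes
#' drive the separation.
#'
#' @param object A `flux_pca`.
#' @param which `"individuals"` or `"variables"`.
#' @param components Two component indices.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flux_pca <- function(object, which = c("individuals",
                                                "variables"),
                              components = c(1, 2), ...) {
  which <- match.arg(which)
  stopifnot(length(components) == 2)
  ve <- round(100 * object$variance_explained[components], 1)
  labs <- paste0("PC", components, " (", ve, "%)")
  if (which == "individuals") {
    df <- tibble::as_tibble(object$scores[, components, drop = FALSE],
                            rownames = "observation")
    names(df)[2:3] <- c("x", "y")
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                     label = .data$observation)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey70") +
      ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey70") +
      ggplot2::geom_point(size = 2) +
      ggplot2::geom_text(vjust = -0.8, size = 3) +
      ggplot2::labs(x = labs[1], y = labs[2],
                    title = "Individual factor map") +
      ggplot2::theme_minimal()
  } else {
    df <- tibble::as_tibble(object$loadings[, components, drop = FALSE],
                            rownames = "variable")
    names(df)[2:3] <- c("x", "y")
    df$cos2 <- rowSums(object$cos2_variables[, components, drop = FALSE])
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                     color = .data$cos2,
                                     label = .data$variable)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey70") +
      ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey70") +
      ggplot2::geom_segment(ggplot2::aes(x = 0, y = 0, xend = .data$x,
                                         yend = .data$y),
                            arrow = grid::arrow(length =
                                                  grid::unit(2, "mm"))) +
      ggplot2::geom_text(vjust = -0.6, size = 3) +
      ggplot2::scale_color_viridis_c(limits = c(0, 1)) +
      ggplot2::labs(x = labs[1], y = labs[2], color = "cos2",
                    title = "Variable factor map") +
      ggplot2::theme_minimal()
  }
}

# x/y segment coordinates of an hclust dendrogram
dendro_segments <- function(hc) {
  n <- length(hc$labels)
  xpos <- numeric(n)
  xpos[hc$order] <- seq_len(n)
  cx <- numeric(nrow(hc$merge))  # cluster center x
  ch <- numeric(nrow(hc$merge))  # cluster height
  segs <- list()
  for (i in seq_len(nrow(hc$merge))) {
    get_xy <- function(idx) {
      if (idx < 0) c(xpos[-idx], 0) else c(cx[idx], ch[idx])
    }
    a <- get_xy(hc$merge[i, 1]); b <- get_xy(hc$merge[i, 2])
    h <- hc$height[i]
    segs[[length(segs) + 1]] <- tibble::tibble(
      x = c(a[1], a[1], b[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], h, h), yend = c(h, h, b[2]))
    cx[i] <- mean(c(a[1], b[1])); ch[i] <- h
  }
  dplyr::bind_rows(segs)
}

#' Plot a strain clustergram
#'
#' Dendrogram of the strains under the 1 - Pearson correlation distance.
#'
#' @param object A `strain_clust`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.strain_clust <- function(object, ...) {
  hc <- object$hclust
  segs <- dendro_segments(hc)
  leaves <- tibble::tibble(label = hc$labels,
                           x = order(hc$order)[seq_along(hc$labels)])
  leaves <- tibble::tibble(label = hc$labels[hc$order],
                           x = seq_along(hc$order))
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = leaves$x,
                                labels = leaves$label) +
    ggplot2::labs(x = NULL, y = "1 - Pearson correlation",
                  title = paste0("Strain clustergram (",
                                 object$linkage, " linkage)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid.major.x = ggplot2::element_blank())
}

#' Plot relative-frequency flux histograms
#'
#' Faceted per reaction, colored per strain: the sampling view of how the
#' strains' feasible flux distributions differ.
#'
#' @param histograms Output of [histogram_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_flux_histograms <- function(histograms, ...) {
  ggplot2::ggplot(histograms,
                  ggplot2::aes(.data$bin_mid, .data$rel_freq,
                               fill = .data$strain)) +
    ggplot2::geom_col(position = "identity", alpha = 0.45,
                      width = NULL) +
    ggplot2::facet_wrap(~reaction_id, scales = "free") +
    ggplot2::labs(x = "predicted flux (mmol/gDW/h)",
                  y = "relative frequency") +
    ggplot2::theme_minimal()
}
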