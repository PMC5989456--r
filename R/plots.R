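#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted growth curve over its data
#'
#' @param object A `growth_fit` from [fit_growth()].
#' @param ... Unused.
#' @return A ggplot: observed ΔOD600 points with the fitted sigmoid overlaid.
#' @method autoplot growth_fit
#' @export
autoplot.growth_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$time_h, y = .data$od600)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "time (h)", y = expression(Delta * OD[600])) +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- tibble::tibble(
      time_h = seq(min(object$data$time_h), max(object$data$time_h),
                   length.out = 200))
    grid$od600 <- growth_model(grid$time_h, object$par$od_asym,
                               object$par$k, object$par$tc)
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p
}

#' Plot simulated or measured growth curves by condition
#'
#' @param data Long growth tibble (`strain`, `substrate`, `replicate`,
#'   `time_h`, `od600`).
#' @return A ggplot faceted by strain, coloured by substrate.
#' @export
plot_growth_curves <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$time_h, y = .data$od600,
                                     colour = .data$substrate,
                                     group = interaction(.data$substrate,
                                                         .data$replicate))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$strain)) +
    ggplot2::labs(x = "time (h)", y = expression(OD[600]),
                  colour = "substrate") +
    ggplot2::theme_minimal()
}

#' Endproduct-ratio bar chart with replicate spread
#'
#' @param ratios Per-replicate ratio tibble from [compute_ratios()].
#' @param ratio Which ratio column to draw; default `"aa_la"`.
#' @return A ggplot of group means with SD error bars, undefined ratios
#'   excluded.
#' @export
plot_ratios <- function(ratios, ratio = "aa_la") {
  defined <- ratios[[paste0(ratio, "_defined")]]
  d <- ratios[defined, , drop = FALSE] |>
    dplyr::group_by(.data$substrate) |>
    dplyr::summarise(mean = mean(.data[[ratio]]),
                     sd = stats::sd(.data[[ratio]]), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$substrate, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = ratio) +
    ggplot2::theme_minimal()
}

#' Biplot-style view of a PCA ordination
#'
#' @param object A `pca_ord` from [pca_ordination()].
#' @param colour Optional identifier column of the scores to colour by.
#' @param ... Unused.
#' @return A ggplot of PC1/PC2 scores with loading arrows.
#' @method autoplot pca_ord
#' @export
autoplot.pca_ord <- function(object, colour = NULL, ...) {
  ve <- object$variance_explained
  sc <- object$scores
  lo <- object$loadings
  arrow_scale <- 0.8 * max(abs(c(sc$PC1, sc$PC2))) /
    max(abs(c(lo$PC1, lo$PC2)), .Machine$double.eps)
  aes_pts <- if (!is.null(colour)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data[[colour]])
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  }
  ggplot2::ggplot(sc, aes_pts) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_segment(
      data = lo, inherit.aes = FALSE,
      ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * arrow_scale,
                   yend = .data$PC2 * arrow_scale),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey40") +
    ggplot2::geom_text(
      data = lo, inherit.aes = FALSE,
      ggplot2::aes(x = .data$PC1 * arrow_scale * 1.08,
                   y = .data$PC2 * arrow_scale * 1.08,
                   label = .data$variable),
      size = 3, colour = "grey30") +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ve[2])) +
    ggplot2::theme_minimal()
}

#' @export
plot.ward_clust <- function(x, ...) {
  plot(x$hclust, hang = -1, xlab = "", sub = "",
       main = "Ward/Euclidean clustering", ...)
  invisible(x)
}
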