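#' Plot an ICC reliability curve
#'
#' Window-length grid on the x axis, ICC on the y axis, with the MP
#' threshold and (when reached) the MP marked.
#'
#' @param object An [icc_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.icc_curve <- function(object, ...) {
  df <- object$curve
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$window_pct, y = .data$icc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = object$mp_threshold, linetype = "dashed") +
    ggplot2::labs(x = "window length (% of run)", y = "ICC(3,1)",
                  subtitle = sprintf("AUC = %.2f, MP = %s", object$auc,
                                     if (is.na(object$mp)) "not reached"
                                     else paste0(object$mp, "%"))) +
    ggplot2::theme_minimal()
  if (!is.na(object$mp))
    p <- p + ggplot2::geom_vline(xintercept = object$mp, linetype = "dotted")
  p
}

#' Carpet plot of a 4D series
#'
#' Renders the [carpet_matrix()] as a raster: one row per in-mask voxel
#' (ordered by global-signal correlation), one column per volume.
#'
#' @param x 4D array or voxels-by-time matrix.
#' @param mask Logical 3D mask.
#' @param max_voxels Rows are thinned to at most this many for rendering.
#' @return A ggplot.
#' @export
plot_carpet <- function(x, mask = NULL, max_voxels = 2000) {
  cm <- carpet_matrix(x, mask)
  if (nrow(cm) > max_voxels)
    cm <- cm[round(seq(1, nrow(cm), length.out = max_voxels)), , drop = FALSE]
  df <- expand.grid(voxel = seq_len(nrow(cm)), volume = seq_len(ncol(cm)))
  df$signal <- as.vector(cm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$volume, y = .data$voxel,
                                   fill = .data$signal)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "volume", y = "voxel (global-signal order)") +
    ggplot2::theme_minimal()
}

#' Plot component features against the motion classifier
#'
#' Scatter of maxRPcorr versus edge fraction with the pretrained LDA
#' decision boundary, colored by label.
#'
#' @param report A [classify_components()] / [preica_denoise()] report.
#' @return A ggplot.
#' @export
plot_component_features <- function(report) {
  hp <- aroma_hyperplane
  slope <- -hp[["max_rp_corr"]] / hp[["edge_fraction"]]
  icpt <- -hp[["intercept"]] / hp[["edge_fraction"]]
  ggplot2::ggplot(report, ggplot2::aes(x = .data$max_rp_corr,
                                       y = .data$edge_fraction,
                                       color = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = slope, intercept = icpt, linetype = "dashed") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "maxRPcorr", y = "edge fraction", color = NULL) +
    ggplot2::theme_minimal()
}
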