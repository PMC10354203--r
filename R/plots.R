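#' Plot a bin-length scan
#'
#' Left: Wasserstein distance between conditions as a function of the
#' growing-window length, with the optimum marked. Right: distance
#' across consecutive non-overlapping bins of the optimal length.
#'
#' @param object A [optimal_bin_search()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bin_scan <- function(object, ...) {
  scan <- dplyr::mutate(object$scan, panel = "growing window")
  bins <- dplyr::transmute(object$bins, length_s = .data$start_s,
                           distance = .data$distance,
                           panel = "consecutive bins")
  df <- dplyr::bind_rows(scan, bins)
  ggplot2::ggplot(df, ggplot2::aes(.data$length_s, .data$distance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_vline(
      data = data.frame(panel = "growing window", x = object$optimum_s),
      ggplot2::aes(xintercept = .data$x), linetype = 2, color = "red") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "time (s)", y = "Wasserstein distance") +
    ggplot2::theme_minimal()
}

#' Plot per-cluster spatial occupancy heatmaps
#'
#' @param object A [cluster_heatmap()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_heatmap <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y,
                                       fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Plot the training loss decomposition of an embedding model
#'
#' @param object An `embedding_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.embedding_model <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$loss_report[c("epoch", "reconstruction", "kl", "l1", "total",
                         "val_total")],
    -"epoch", names_to = "component", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss (per window)") +
    ggplot2::theme_minimal()
}

#' Plot the global SHAP feature ranking
#'
#' @param object A [shap_explain()] report.
#' @param top Number of features shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shap_report <- function(object, top = 15, ...) {
  df <- utils::head(object$global, top)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_abs_shap, .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean |SHAP|", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
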