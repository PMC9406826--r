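need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_renasl("install ggplot2 to use the plotting helpers")
}

utils::globalVariables(c("rbf", "intensity", "position", "frame",
                         "stage", "side"))

#' Plot a perfusion map
#'
#' @param map a [quantify()] result.
#' @return a ggplot object.
#' @export
plot_perfusion_map <- function(map) {
  need_ggplot()
  df <- data.frame(
    row = as.vector(row(map$rbf)),
    col = as.vector(col(map$rbf)),
    rbf = as.vector(map$rbf))
  ggplot2::ggplot(df, ggplot2::aes(col, row, fill = rbf)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "rbf\n(mL/100g/min)",
                                  na.value = "grey80") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Line-profile image across the time dimension
#'
#' Displays a [line_profile()] matrix (position vs. frame); residual
#' motion appears as jagged edges along the frame axis.
#'
#' @param profile matrix from [line_profile()].
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_line_profile <- function(profile, title = NULL) {
  need_ggplot()
  df <- data.frame(
    position = as.vector(row(profile)),
    frame = as.vector(col(profile)),
    intensity = as.vector(profile))
  ggplot2::ggplot(df, ggplot2::aes(frame, position, fill = intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(title = title, x = "frame", y = "position") +
    ggplot2::theme_minimal()
}

#' Boxplot of all-pairs MSSIM before and after registration
#'
#' @param evaluation an [evaluate_processing()] result.
#' @return a ggplot object.
#' @export
plot_mssim <- function(evaluation) {
  need_ggplot()
  df <- evaluation$mssim_pairs
  df$stage <- factor(df$stage, levels = c("before", "after"))
  ggplot2::ggplot(df, ggplot2::aes(stage, mssim)) +
    ggplot2::geom_boxplot(outlier.shape = 3) +
    ggplot2::facet_wrap(~side) +
    ggplot2::labs(y = "MSSIM (all image pairs)") +
    ggplot2::theme_minimal()
}
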