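# ggplot2 visualization of result types.

as_deformation_field <- function(x) {
  class(x) <- c("deformation_field", class(x)[!class(x) %in% "deformation_field"])
  x
}

as_point_cloud <- function(x) {
  class(x) <- c("point_cloud", class(x)[!class(x) %in% "point_cloud"])
  x
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a quasi-dense point cloud
#'
#' Image-plane scatter of the reconstructed points colored by depth, faceted
#' nowhere; stage provenance is mapped to point shape.
#'
#' @param cloud Point-cloud tibble from [reconstruct_cloud()].
#' @return A ggplot object.
#' @export
plot_cloud <- function(cloud) {
  ggplot2::ggplot(cloud,
                  ggplot2::aes(x = .data$col_L, y = -.data$row_L,
                               color = .data$z, shape = .data$stage)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_color_viridis_c(name = "depth z (mm)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "col (px)", y = "row (px)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.point_cloud <- function(object, ...) plot_cloud(object)

#' @export
autoplot.deformation_field <- function(object, image = NULL, ...) {
  plot_deformation(object, image = image, ...)
}

#' Plot a calibrated force-displacement model
#'
#' @param x A `force_displacement_model`.
#' @param data Optional calibration tibble (`displacement_mm`, `force_N`) to
#'   overlay as points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.force_displacement_model <- function(x, data = NULL, ...) {
  d <- seq(0, x$d_max, length.out = 100)
  curve <- evaluate_material(x, d)
  p <- ggplot2::ggplot(curve,
                       ggplot2::aes(x = .data$displacement_mm, y = .data$force_N)) +
    ggplot2::geom_line(linewidth = 0.8, color = "steelblue")
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(data = data, alpha = 0.6)
  }
  p + ggplot2::labs(x = "displacement (mm)", y = "force (N)") +
    ggplot2::theme_minimal()
}
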