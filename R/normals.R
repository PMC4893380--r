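# Shape-from-shading surface normals.
#
# Under a Lambertian surface lit by a point source co-located with the camera
# (the microscope/endoscope geometry), image irradiance falls off with the
# cosine of the angle between the surface normal and the viewing direction:
# I ~ rho / sqrt(p^2 + q^2 + 1), with (p, q) the surface directional gradient.
# Linearizing this on smoothed intensities gives the slope magnitude
# sqrt((I0 / I)^2 - 1); the slope direction is taken opposite the image
# intensity gradient (brightness decreases where the surface tilts away).
# The unit normal is N = (p, q, -1) / sqrt(p^2 + q^2 + 1), so its z component
# is always negative (facing the camera).

#' Estimate a surface normal map by shape-from-shading
#'
#' @param image Grayscale matrix.
#' @param smooth_sigma Gaussian smoothing applied before linearizing the
#'   irradiance equation (px).  Generous smoothing suppresses albedo
#'   (texture) variation so that mostly shading remains.
#' @param focal_px,center_px Optional camera geometry (focal length in px and
#'   0-based principal point).  When given, the known viewing/radial falloff
#'   of the co-located light `(cos^3 alpha)` is divided out before the
#'   irradiance equation is inverted; `center_px` defaults to the image
#'   center.
#' @param albedo_quantile Quantile of the compensated image used as the
#'   fronto-parallel irradiance I0.
#' @return A `surface_normal_map` with matrices `p`, `q` and the three normal
#'   components `nx`, `ny`, `nz`.
#' @export
estimate_normals <- function(image, smooth_sigma = 16, focal_px = NULL,
                             center_px = NULL, albedo_quantile = 0.99) {
  image <- as_gray(image)
  if (!is.null(focal_px)) {
    h <- nrow(image); w <- ncol(image)
    if (is.null(center_px)) center_px <- c((w - 1) / 2, (h - 1) / 2)
    dx <- (outer(rep(1, h), 0:(w - 1)) - center_px[1]) / focal_px
    dy <- (outer(0:(h - 1), rep(1, w)) - center_px[2]) / focal_px
    image <- image * (dx^2 + dy^2 + 1)^1.5
  }
  sm <- gauss_blur(image, smooth_sigma)
  I0 <- quantile(sm, albedo_quantile, names = FALSE)
  ratio <- pmin(pmax(sm / I0, 1e-3), 1)
  slope <- sqrt(1 / ratio^2 - 1)
  g <- image_gradient(sm)
  gn <- sqrt(g$gx^2 + g$gy^2)
  flat <- gn < 1e-8
  ux <- ifelse(flat, 0, -g$gx / pmax(gn, 1e-12))
  uy <- ifelse(flat, 0, -g$gy / pmax(gn, 1e-12))
  p <- slope * ux
  q <- slope * uy
  p[flat] <- 0; q[flat] <- 0
  den <- sqrt(p^2 + q^2 + 1)
  structure(
    list(p = p, q = q, nx = p / den, ny = q / den, nz = -1 / den),
    class = "surface_normal_map"
  )
}

#' @export
print.surface_normal_map <- function(x, ...) {
  cat("<surface_normal_map> ", ncol(x$p), "x", nrow(x$p),
      " px, mean slope ", format(mean(sqrt(x$p^2 + x$q^2)), digits = 3), "\n",
      sep = "")
  invisible(x)
}

# Unit normals at 0-based (col, row) positions -> n x 3 matrix.
normals_at <- function(map, col, row) {
  idx <- cbind(pmin(pmax(round(row) + 1, 1), nrow(map$p)),
               pmin(pmax(round(col) + 1, 1), ncol(map$p)))
  cbind(map$nx[idx], map$ny[idx], map$nz[idx])
}

# Angle in degrees between rows of two n x 3 unit-vector matrices.
normal_angle_deg <- function(n1, n2) {
  d <- pmin(pmax(rowSums(n1 * n2), -1), 1)
  acos(d) * 180 / pi
}
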