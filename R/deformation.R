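# Tissue deformation recovery: per-point 3D displacement against a reference
# structure, and TPS mapping of points without a reliable temporal track.

#' Deformation of stable points against a reference cloud
#'
#' Joins the current and reference clouds by point id and computes the
#' Euclidean 3D displacement magnitude `D = ||S_t - S_ref||` per point.
#' Ids present in only one cloud are skipped with a warning.
#'
#' @param cloud_t Current cloud (tibble with `id`, `x`, `y`, `z`, optionally
#'   `col_L`, `row_L`).
#' @param cloud_ref Reference cloud (same structure).
#' @return A deformation-field tibble: `id`, `col`, `row` (current left-image
#'   position when available), `x`, `y`, `z` (current, mm), `x_ref`, `y_ref`,
#'   `z_ref`, `D` (mm), `stable`, `confidence`.
#' @export
deformation_at_stable <- function(cloud_t, cloud_ref) {
  a <- as_tibble(cloud_t); b <- as_tibble(cloud_ref)
  common <- intersect(a$id, b$id)
  dropped <- length(a$id) + length(b$id) - 2 * length(common)
  if (dropped > 0) {
    warn(sprintf("%d point id(s) present in only one cloud; skipped", dropped))
  }
  a <- a[match(common, a$id), ]
  b <- b[match(common, b$id), ]
  as_deformation_field(tibble(
    id = a$id,
    col = if ("col_L" %in% names(a)) a$col_L else NA_real_,
    row = if ("row_L" %in% names(a)) a$row_L else NA_real_,
    x = a$x, y = a$y, z = a$z,
    x_ref = b$x, y_ref = b$y, z_ref = b$z,
    D = sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2),
    stable = TRUE, confidence = "high"
  ))
}

#' Map unstable points onto the current surface with a TPS warp
#'
#' Points that carry 3D data at the reference time but no reliable temporal
#' track are warped by the TPS fitted on the stable features, projected into
#' the left image, and — when a reconstructed point of the current cloud lies
#' within `radius_px` of the projection — assigned that point's deformation;
#' otherwise the warped position itself is used and flagged low-confidence.
#' Points that project behind the camera are dropped with a warning.
#'
#' @param warp A [fit_tps()] warp from reference-time stable positions to
#'   current-time stable positions.
#' @param unstable_ref Tibble of unstable points at the reference time
#'   (`id`, `x`, `y`, `z`).
#' @param cloud_t Current reconstructed cloud (with `col_L`, `row_L`).
#' @param rig A `camera_rig` or `rectified_rig` for the projection.
#' @return Deformation-field tibble (see [deformation_at_stable()]).
#' @export
map_unstable <- function(warp, unstable_ref, cloud_t, rig) {
  u <- as_tibble(unstable_ref)
  if (!nrow(u)) {
    return(deformation_at_stable(u, u))
  }
  warped <- predict(warp, u)
  behind <- warped$z <= 0
  if (any(behind)) {
    warn(sprintf("%d unstable point(s) project behind the camera; dropped",
                 sum(behind)))
    u <- u[!behind, ]; warped <- warped[!behind, ]
  }
  w <- project_points(warped, rig, "left")
  has_cloud <- nrow(cloud_t) > 0
  r2max <- attr(warp, "radius_px", exact = TRUE) %||% 4
  depth_t <- if (has_cloud) ray_depth(cloud_t, rig) else numeric(0)
  rows <- lapply(seq_len(nrow(u)), function(i) {
    snapped <- FALSE
    xi <- warped$x[i]; yi <- warped$y[i]; zi <- warped$z[i]
    if (has_cloud) {
      d2 <- (cloud_t$col_L - w$col[i])^2 + (cloud_t$row_L - w$row[i])^2
      if (any(d2 <= r2max)) {
        # 3D information is available at w: evaluate the reconstructed
        # surface at the projection itself, from a local plane over a
        # slightly wider neighborhood (adopting a single nearest neighbor
        # would bias depth outward wherever the cloud is one-sided, e.g. at
        # the tool-occlusion boundary)
        nb <- which(d2 <= 9 * r2max)
        z_here <- surface_depth_at(cloud_t, depth_t, nb, d2, w$col[i], w$row[i])
        P <- unproject_left(rig, w$col[i], w$row[i], z_here)
        xi <- P[1]; yi <- P[2]; zi <- P[3]
        snapped <- TRUE
      }
    }
    tibble(id = u$id[i], col = w$col[i], row = w$row[i],
           x = xi, y = yi, z = zi,
           x_ref = u$x[i], y_ref = u$y[i], z_ref = u$z[i],
           D = sqrt((xi - u$x[i])^2 + (yi - u$y[i])^2 + (zi - u$z[i])^2),
           stable = FALSE, confidence = if (snapped) "high" else "low")
  })
  as_deformation_field(dplyr::bind_rows(rows))
}

# Depth of each cloud point along its own viewing ray (rectified z when the
# rig is a rectified_rig, camera z otherwise).
ray_depth <- function(cloud, rig) {
  if (inherits(rig, "rectified_rig")) {
    (rig$rot_L %*% rbind(cloud$x, cloud$y, cloud$z))[3, ]
  } else {
    cloud$z
  }
}

# Ray depth at (col, row) from neighboring cloud points: least-squares plane
# when three or more neighbors are available (and well conditioned),
# inverse-distance weighting otherwise.
surface_depth_at <- function(cloud, depth, nb, d2, col, row) {
  if (length(nb) >= 3) {
    X <- cbind(1, cloud$col_L[nb] - col, cloud$row_L[nb] - row)
    fit <- tryCatch(qr.solve(X, depth[nb]), error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(fit))) return(fit[1])
  }
  wgt <- 1 / (sqrt(d2[nb]) + 0.25)
  sum(depth[nb] * wgt) / sum(wgt)
}

# Back-project an image position at a given ray depth into the left camera
# frame (mm).
unproject_left <- function(rig, col, row, z) {
  if (inherits(rig, "rectified_rig")) {
    K <- rig$K_rect
    X_rect <- z * c((col - K[1, 3]) / K[1, 1], (row - K[2, 3]) / K[2, 2], 1)
    as.numeric(t(rig$rot_L) %*% X_rect)
  } else {
    d <- undistort_normalized((col - rig$K_L[1, 3]) / rig$K_L[1, 1],
                              (row - rig$K_L[2, 3]) / rig$K_L[2, 2], rig$dist_L)
    z * c(d$x, d$y, 1)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Set the snap radius used by [map_unstable()]
#'
#' @param warp A `tps_warp`.
#' @param radius_px Pixel radius within which an existing reconstruction
#'   counts as "3D information already available" (squared internally).
#' @return The warp with the radius attached.
#' @export
with_snap_radius <- function(warp, radius_px = 2) {
  attr(warp, "radius_px") <- radius_px^2
  warp
}

#' Render a deformation heatmap overlay
#'
#' Interpolates the deformation magnitude over the convex hull of the
#' reported image locations (2D thin-plate smoothing of D against (col, row))
#' and alpha-blends it over the grayscale frame with an explicit mm color
#' scale.
#'
#' @param field Deformation-field tibble (needs `col`, `row`, `D`).
#' @param image Optional background grayscale matrix.
#' @param alpha Overlay opacity.
#' @param grid_step Interpolation grid step (px).
#' @return A ggplot object.
#' @export
plot_deformation <- function(field, image = NULL, alpha = 0.55, grid_step = 4) {
  stopifnot(nrow(field) > 0)
  p <- ggplot2::ggplot()
  if (!is.null(image)) {
    p <- p + ggplot2::annotation_raster(
      grDevices::as.raster(pmin(pmax(image, 0), 1)),
      xmin = -0.5, xmax = ncol(image) - 0.5,
      ymin = -(nrow(image) - 0.5), ymax = 0.5
    )
  }
  pts <- field[is.finite(field$col) & is.finite(field$row), ]
  dmax <- max(pts$D)
  grid <- interpolate_field(pts, grid_step)
  p <- p +
    ggplot2::geom_tile(
      data = grid,
      ggplot2::aes(x = .data$col, y = -.data$row, fill = .data$D),
      width = grid_step, height = grid_step, alpha = alpha
    ) +
    ggplot2::scale_fill_viridis_c(
      name = "deformation (mm)", option = "inferno",
      limits = c(0, max(dmax, 1e-6))
    ) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "right")
  p
}

# Smooth interpolation of D over the convex hull of the points: 2D TPS
# (3D warp with z = 0) evaluated on a grid, masked to the hull.
interpolate_field <- function(pts, grid_step, max_control = 400) {
  if (nrow(pts) > max_control) {
    pts <- pts[seq(1, nrow(pts), length.out = max_control), ]
  }
  hull <- grDevices::chull(pts$col, pts$row)
  hx <- pts$col[hull]; hy <- pts$row[hull]
  g <- expand.grid(
    col = seq(min(pts$col), max(pts$col), by = grid_step),
    row = seq(min(pts$row), max(pts$row), by = grid_step)
  )
  inside <- point_in_poly(g$col, g$row, hx, hy)
  g <- g[inside, ]
  if (!nrow(g)) return(tibble(col = pts$col, row = pts$row, D = pts$D))
  # jitter z to avoid a perfectly coplanar TPS source configuration
  src <- cbind(pts$col, pts$row, seq_len(nrow(pts)) %% 7 * 1e-3)
  warp <- fit_tps(src, cbind(pts$D, 0, 0), lambda = 1e-6 * nrow(pts))
  Dv <- predict(warp, cbind(g$col, g$row, 0))$x
  tibble(col = g$col, row = g$row, D = pmax(Dv, 0))
}

# Ray-crossing point-in-polygon test, vectorized over query points.
point_in_poly <- function(x, y, px, py) {
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i] + 1e-300) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Write a deformation field as CSV
#'
#' Columns: point id, image position, 3D position (mm), deformation D (mm),
#' stability flag and confidence.
#'
#' @param field Deformation-field tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deformation_csv <- function(field, path) {
  write.csv(field[, c("id", "col", "row", "x", "y", "z", "D", "stable",
                      "confidence")], path, row.names = FALSE)
  invisible(path)
}
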