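# Synthetic stereo scenes with exact ground truth.
#
# A textured deformable surface is modeled as a heightfield z(x, y) (mm) over
# the left camera's lateral coordinates: a base depth, smooth low-frequency
# relief, and a scheduled Gaussian indentation pushed into the tissue (+z,
# away from the camera).  Frames are rendered for both cameras of a known rig
# by per-pixel ray/heightfield intersection (inverse mapping), with Lambertian
# shading under a light co-located with the camera.  Ground-truth depth and
# 3D displacement are available per pixel, and a force label is derived from
# the scene's material model at each frame's indentation amplitude.

#' Generate a synthetic scene
#'
#' The defaults emulate a stereo surgical microscope viewing soft tissue at
#' about 100 mm: focal length 1000 px, baseline 5 mm, band-limited procedural
#' texture, gentle relief, and an indentation schedule ramping from 0 to
#' `max_indent_mm` (deformations up to 10 mm, matching the regime the method
#' targets).  Frame 1 is always undeformed (the reference).
#'
#' @param depth_mm Nominal stand-off distance (80-150).
#' @param baseline_mm Stereo baseline (4-8).
#' @param focal_px Focal length (800-1500).
#' @param image_size (width, height) px.
#' @param n_frames Number of frames in the indentation schedule.
#' @param max_indent_mm Final indentation amplitude (mm).
#' @param indent_center_mm Lateral (x, y) position of the indentation (mm).
#' @param indent_sigma_mm Gaussian indentation width (mm).
#' @param relief_mm Amplitude of the static surface relief (mm).
#' @param material A `force_displacement_model`; defaults to the demo model.
#' @param tool If `TRUE`, render an opaque dark tool occluder reaching the
#'   indentation center in deformed frames.
#' @param seed Integer; the scene is deterministic given the seed.
#' @return A `synthetic_scene` object.
#' @export
make_scene <- function(depth_mm = 100, baseline_mm = 5, focal_px = 1000,
                       image_size = c(640, 480), n_frames = 5,
                       max_indent_mm = 10, indent_center_mm = c(0, 0),
                       indent_sigma_mm = 6, relief_mm = 2,
                       material = demo_material_model(), tool = TRUE,
                       seed = 1L) {
  check_range <- function(v, lo, hi, name) {
    if (v < lo || v > hi) {
      abort(sprintf("%s = %g outside documented range [%g, %g]", name, v, lo, hi),
            class = "tissuedeform_invalid_parameter")
    }
  }
  check_range(depth_mm, 80, 150, "depth_mm")
  check_range(baseline_mm, 4, 8, "baseline_mm")
  check_range(focal_px, 800, 1500, "focal_px")
  stopifnot(n_frames >= 1, max_indent_mm >= 0, indent_sigma_mm > 0)

  w <- image_size[1]; h <- image_size[2]
  # integer principal point: the optical axis (and an indentation centered on
  # it) then pierces an exact pixel center
  K <- matrix(c(focal_px, 0, w %/% 2, 0, focal_px, h %/% 2, 0, 0, 1),
              3, 3, byrow = TRUE)
  rig <- camera_rig(K_L = K, K_R = K, R_ext = diag(3),
                    t_ext = c(-baseline_mm, 0, 0), image_size = image_size)

  # lateral extent covered by either camera at the far surface, with margin
  half_x <- (w / 2 + 40) / focal_px * (depth_mm + relief_mm + max_indent_mm) + baseline_mm
  half_y <- (h / 2 + 40) / focal_px * (depth_mm + relief_mm + max_indent_mm)
  res <- 0.1        # texture grid resolution, mm
  relief_res <- 1   # relief grid resolution, mm (low-frequency field)
  nx <- ceiling(2 * half_x / res); ny <- ceiling(2 * half_y / res)
  nxr <- ceiling(2 * half_x / relief_res); nyr <- ceiling(2 * half_y / relief_res)

  old <- .Random.seed_save()
  set.seed(seed)
  tex <- matrix(runif(ny * nx), ny, nx)
  tex <- 0.65 * unit_range(gauss_blur(tex, 2)) + 0.35 * unit_range(gauss_blur(tex, 6))
  tex <- 0.15 + 0.8 * unit_range(tex)
  relief <- matrix(runif(nyr * nxr), nyr, nxr)
  relief <- relief_mm * 2 * (unit_range(gauss_blur(relief, 8)) - 0.5)
  .Random.seed_restore(old)

  amplitudes <- if (n_frames == 1) 0 else seq(0, max_indent_mm, length.out = n_frames)
  structure(
    list(
      rig = rig, depth_mm = depth_mm, texture = tex, relief = relief,
      grid_origin = c(-half_x, -half_y), grid_res = res, relief_res = relief_res,
      amplitudes = amplitudes, indent_center = as.numeric(indent_center_mm),
      indent_sigma = indent_sigma_mm, material = material, tool = tool,
      seed = as.integer(seed)
    ),
    class = "synthetic_scene"
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

unit_range <- function(m) {
  r <- range(m)
  if (diff(r) <= 0) return(m * 0)
  (m - r[1]) / diff(r)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("<synthetic_scene> depth ", x$depth_mm, " mm, baseline ",
      format(sqrt(sum(x$rig$t_ext^2)), digits = 3),
      " mm, ", length(x$amplitudes), " frame(s), max indent ",
      format(max(x$amplitudes), digits = 3), " mm\n", sep = "")
  invisible(x)
}

# Bilinear lookup of a lateral-grid matrix at (x, y) mm.
grid_lookup <- function(scene, grid, x, y, res = scene$grid_res) {
  cg <- (x - scene$grid_origin[1]) / res
  rg <- (y - scene$grid_origin[2]) / res
  bilinear_sample(grid, cg, rg)
}

# Surface height z(x, y) at frame amplitude a, and the indentation depth.
surface_height <- function(scene, x, y, a) {
  scene$depth_mm + grid_lookup(scene, scene$relief, x, y, scene$relief_res) +
    indent_depth(scene, x, y, a)
}

indent_depth <- function(scene, x, y, a) {
  a * exp(-((x - scene$indent_center[1])^2 + (y - scene$indent_center[2])^2) /
            (2 * scene$indent_sigma^2))
}

# Numerical lateral gradient of the surface height (mm/mm).
surface_gradient <- function(scene, x, y, a, eps = 0.05) {
  list(
    zx = (surface_height(scene, x + eps, y, a) - surface_height(scene, x - eps, y, a)) / (2 * eps),
    zy = (surface_height(scene, x, y + eps, a) - surface_height(scene, x, y - eps, a)) / (2 * eps)
  )
}

#' Render one frame of a synthetic scene
#'
#' Per-pixel inverse mapping: each camera ray is intersected with the
#' heightfield by fixed-point iteration (the relief is shallow relative to the
#' stand-off distance, so convergence is fast).  Shading is Lambertian with a
#' point light co-located with the camera (`I ~ albedo cos(theta) / r^2`).
#'
#' @param scene A [make_scene()] object.
#' @param frame Frame index (1-based) into the amplitude schedule.
#' @return List: `img_L`, `img_R` (matrices in \[0, 1\]), `gt_depth_L`
#'   (per-pixel z, mm), `gt_displacement_L` (per-pixel magnitude of the 3D
#'   displacement from the reference frame, mm), `mask_L`, `mask_R` (logical
#'   tool-occluder masks), `amplitude` (mm).
#' @export
render_stereo <- function(scene, frame) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (frame < 1 || frame > length(scene$amplitudes)) {
    abort("frame outside the schedule", class = "tissuedeform_invalid_parameter")
  }
  a <- scene$amplitudes[frame]
  L <- render_view(scene, a, camera = "left")
  R <- render_view(scene, a, camera = "right")
  mask_L <- matrix(FALSE, nrow(L$img), ncol(L$img))
  mask_R <- matrix(FALSE, nrow(R$img), ncol(R$img))
  if (scene$tool && a > 0) {
    mask_L <- tool_mask(scene, a, "left")
    mask_R <- tool_mask(scene, a, "right")
    L$img[mask_L] <- 0.04 + 0.02 * L$img[mask_L]
    R$img[mask_R] <- 0.04 + 0.02 * R$img[mask_R]
  }
  list(img_L = L$img, img_R = R$img,
       gt_depth_L = L$depth, gt_displacement_L = L$displacement,
       mask_L = mask_L, mask_R = mask_R, amplitude = a)
}

render_view <- function(scene, a, camera) {
  rig <- scene$rig
  w <- rig$image_size[1]; h <- rig$image_size[2]
  K <- if (camera == "left") rig$K_L else rig$K_R
  grid <- expand.grid(col = 0:(w - 1), row = 0:(h - 1))
  dx <- (grid$col - K[1, 3]) / K[1, 1]
  dy <- (grid$row - K[2, 3]) / K[2, 2]
  if (camera == "left") {
    cx <- 0; cy <- 0; cz <- 0
  } else {
    c2 <- -crossprod(rig$R_ext, rig$t_ext)[, 1]
    d <- t(rig$R_ext) %*% rbind(dx, dy, 1)
    dx <- d[1, ] / d[3, ]; dy <- d[2, ] / d[3, ]
    cx <- c2[1]; cy <- c2[2]; cz <- c2[3]
  }
  # iterate z -> surface(x(z), y(z)); points: (cx + (z - cz) dx, ...)
  z <- rep(scene$depth_mm, length(dx))
  for (it in 1:8) {
    x <- cx + (z - cz) * dx
    y <- cy + (z - cz) * dy
    z <- surface_height(scene, x, y, a)
  }
  x <- cx + (z - cz) * dx
  y <- cy + (z - cz) * dy

  gr <- surface_gradient(scene, x, y, a)
  # single coaxial illuminator at the left camera origin (a stereo microscope
  # lights both optical paths through one objective); per-view lights would
  # make shading differ between the views on slopes and bias stereo matching
  nn <- sqrt(gr$zx^2 + gr$zy^2 + 1)
  r <- sqrt(x^2 + y^2 + z^2)
  cosang <- pmax(0, (gr$zx * x + gr$zy * y - z) * (-1) / (nn * r))
  albedo <- grid_lookup(scene, scene$texture, x, y)
  img <- albedo * cosang * (scene$depth_mm / r)^2
  disp <- indent_depth(scene, x, y, a)
  list(
    img = matrix(pmin(img, 1), h, w, byrow = TRUE),
    depth = matrix(z, h, w, byrow = TRUE),
    displacement = matrix(disp, h, w, byrow = TRUE),
    x = matrix(x, h, w, byrow = TRUE), y = matrix(y, h, w, byrow = TRUE)
  )
}

# Tool occluder: a dark quadrilateral shaft from the top image border down to
# the projected indentation center, plus a disk tip.
tool_mask <- function(scene, a, camera, shaft_halfwidth_px = 9, tip_radius_mm = 2) {
  rig <- scene$rig
  tip3 <- tibble(x = scene$indent_center[1], y = scene$indent_center[2],
                 z = surface_height(scene, scene$indent_center[1],
                                    scene$indent_center[2], a))
  tip <- project_points(tip3, rig, camera)
  w <- rig$image_size[1]; h <- rig$image_size[2]
  cols <- outer(rep(1, h), 0:(w - 1))
  rows <- outer(0:(h - 1), rep(1, w))
  # shaft: vertical band of half-width shrinking slightly toward the tip
  in_shaft <- abs(cols - tip$col) <= shaft_halfwidth_px & rows <= tip$row
  tip_radius_px <- tip_radius_mm * rig$K_L[1, 1] / scene$depth_mm
  in_tip <- (cols - tip$col)^2 + (rows - tip$row)^2 <= tip_radius_px^2
  in_shaft | in_tip
}

#' Ground-truth stereo correspondences for a rendered frame
#'
#' Samples left-image pixels, intersects their rays with the true surface and
#' projects the 3D points into both cameras; used as an oracle for
#' rectification, triangulation and matching.
#'
#' @param scene A scene; `frame` a schedule index.
#' @param n Number of correspondences.
#' @param seed RNG seed for pixel sampling.
#' @param margin Image-border margin (px).
#' @return Tibble with original-image coordinates `col_L`, `row_L`, `col_R`,
#'   `row_R` and the true 3D point `x`, `y`, `z` (mm, left frame).
#' @export
gt_correspondences <- function(scene, frame, n = 100, seed = 1, margin = 20) {
  a <- scene$amplitudes[frame]
  rig <- scene$rig
  w <- rig$image_size[1]; h <- rig$image_size[2]
  old <- .Random.seed_save()
  set.seed(seed)
  col <- runif(n, margin, w - 1 - margin)
  row <- runif(n, margin, h - 1 - margin)
  .Random.seed_restore(old)
  K <- rig$K_L
  dx <- (col - K[1, 3]) / K[1, 1]
  dy <- (row - K[2, 3]) / K[2, 2]
  z <- rep(scene$depth_mm, n)
  for (it in 1:12) z <- surface_height(scene, z * dx, z * dy, a)
  pts <- tibble(x = z * dx, y = z * dy, z = z)
  pr <- project_points(pts, rig, "right")
  tibble(col_L = col, row_L = row, col_R = pr$col, row_R = pr$row,
         x = pts$x, y = pts$y, z = pts$z)
}

#' Ground-truth force label for a frame
#'
#' Evaluates the scene's material model at the scheduled indentation
#' amplitude.
#'
#' @param scene A scene; `frame` a schedule index.
#' @return Force in N.
#' @export
ground_truth_force <- function(scene, frame) {
  a <- scene$amplitudes[frame]
  evaluate_material(scene$material, a)$force_N
}

#' Write a scene to disk as a fixture bundle
#'
#' Writes per-frame PNG stereo pairs (`left_%04d.png` / `right_%04d.png`),
#' the calibration file, per-frame ground-truth depth and displacement
#' rasters (plain-text matrices), tool masks, and a force schedule CSV.
#'
#' @param scene A scene.
#' @param dir Output directory (created if needed).
#' @param frames Which frames to write (default all).
#' @return `dir`, invisibly.
#' @export
write_scene_bundle <- function(scene, dir, frames = seq_along(scene$amplitudes)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_calibration(scene$rig, file.path(dir, "calibration.txt"))
  sched <- tibble(frame = frames,
                  amplitude_mm = scene$amplitudes[frames],
                  force_N = vapply(frames, function(f) ground_truth_force(scene, f), 0))
  write.csv(sched, file.path(dir, "force_schedule.csv"), row.names = FALSE)
  for (f in frames) {
    r <- render_stereo(scene, f)
    write_image(r$img_L, file.path(dir, sprintf("left_%04d.png", f)))
    write_image(r$img_R, file.path(dir, sprintf("right_%04d.png", f)))
    write_matrix_txt(r$gt_depth_L, file.path(dir, sprintf("gt_depth_%04d.txt", f)))
    write_matrix_txt(r$gt_displacement_L,
                     file.path(dir, sprintf("gt_displacement_%04d.txt", f)))
    write_matrix_txt(r$mask_L * 1, file.path(dir, sprintf("tool_mask_%04d.txt", f)))
  }
  invisible(dir)
}

write_matrix_txt <- function(m, path) {
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_matrix_txt <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}
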