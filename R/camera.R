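# Stereo camera model: calibrated rig, rectification, triangulation,
# projection, and calibration-file I/O.
#
# All 3D quantities live in the left camera's frame (x right, y down,
# z forward), in millimeters.  Pixel coordinates are 0-based (col, row).

#' Construct a calibrated stereo rig
#'
#' @param K_L,K_R 3x3 upper-triangular intrinsic matrices (px) with positive
#'   focal lengths.
#' @param R_ext 3x3 rotation mapping left-camera coordinates to right-camera
#'   coordinates (`X_R = R_ext X_L + t_ext`).
#' @param t_ext Length-3 translation (mm); its norm is the stereo baseline.
#' @param dist_L,dist_R Length-5 radial-tangential distortion coefficients
#'   (k1, k2, p1, p2, k3); default zero.
#' @param image_size Integer (width, height) in px.
#' @return A `camera_rig` object.
#' @export
camera_rig <- function(K_L, K_R = K_L, R_ext = diag(3), t_ext,
                       dist_L = numeric(5), dist_R = numeric(5),
                       image_size) {
  K_L <- as_intrinsics(K_L, "K_L")
  K_R <- as_intrinsics(K_R, "K_R")
  R_ext <- matrix(as.numeric(R_ext), 3, 3)
  if (max(abs(crossprod(R_ext) - diag(3))) > 1e-6 || det(R_ext) < 0) {
    abort("R_ext must be a rotation (orthonormal, det +1)",
          class = "tissuedeform_invalid_geometry")
  }
  t_ext <- as.numeric(t_ext)
  stopifnot(length(t_ext) == 3)
  if (sqrt(sum(t_ext^2)) <= 0) {
    abort("zero baseline: ||t_ext|| must be positive",
          class = "tissuedeform_invalid_geometry")
  }
  dist_L <- pad5(dist_L); dist_R <- pad5(dist_R)
  image_size <- as.integer(image_size)
  stopifnot(length(image_size) == 2, all(image_size > 0))
  structure(
    list(K_L = K_L, K_R = K_R, R_ext = R_ext, t_ext = t_ext,
         dist_L = dist_L, dist_R = dist_R, image_size = image_size),
    class = "camera_rig"
  )
}

as_intrinsics <- function(K, name) {
  K <- matrix(as.numeric(K), 3, 3)
  if (K[2, 1] != 0 || K[3, 1] != 0 || K[3, 2] != 0 || abs(K[3, 3] - 1) > 1e-12 ||
      K[1, 1] <= 0 || K[2, 2] <= 0) {
    abort(paste0(name, " must be upper-triangular with positive focal lengths"),
          class = "tissuedeform_invalid_geometry")
  }
  K
}

pad5 <- function(d) {
  d <- as.numeric(d)
  stopifnot(length(d) <= 5)
  c(d, numeric(5 - length(d)))
}

#' @export
print.camera_rig <- function(x, ...) {
  cat("<camera_rig> ", x$image_size[1], "x", x$image_size[2], " px, baseline ",
      format(sqrt(sum(x$t_ext^2)), digits = 4), " mm\n", sep = "")
  invisible(x)
}

# ---- rectification ----------------------------------------------------------

#' Rectify a stereo pair
#'
#' Resamples both images so that epipolar lines are horizontal: corresponding
#' points share (to within `epipolar_tolerance`) the same row.  The rectifying
#' rotation aligns the new x axis with the baseline (Fusiello-style), and both
#' rectified views share common intrinsics `K_rect` (the average of the two
#' original intrinsics, zero skew).
#'
#' @param rig A [camera_rig()].
#' @param img_L,img_R Grayscale image matrices matching `rig$image_size`.
#' @param epipolar_tolerance Row-alignment tolerance recorded on the result (px).
#' @return A list with components `rig` (a `rectified_rig`), `left`, `right`
#'   (the resampled images).
#' @export
rectify_pair <- function(rig, img_L, img_R, epipolar_tolerance = 0.5) {
  stopifnot(inherits(rig, "camera_rig"))
  check_size(img_L, rig$image_size, "img_L")
  check_size(img_R, rig$image_size, "img_R")
  rect <- rectified_rig(rig, epipolar_tolerance)
  list(
    rig = rect,
    left = rectify_resample(img_L, rig$K_L, rig$dist_L, rect$rot_L, rect$K_rect),
    right = rectify_resample(img_R, rig$K_R, rig$dist_R, rect$rot_R, rect$K_rect)
  )
}

check_size <- function(img, size, name) {
  if (ncol(img) != size[1] || nrow(img) != size[2]) {
    abort(paste0(name, " does not match rig image_size"),
          class = "tissuedeform_invalid_image")
  }
}

# Rectifying geometry only (no image resampling); used where images are not
# needed or already rectified.
rectified_rig <- function(rig, epipolar_tolerance = 0.5) {
  c2 <- -crossprod(rig$R_ext, rig$t_ext)[, 1]  # right camera centre, left frame
  baseline <- sqrt(sum(c2^2))
  if (baseline <= .Machine$double.eps) {
    abort("zero baseline: cannot rectify", class = "tissuedeform_invalid_geometry")
  }
  r1 <- c2 / baseline
  ez <- c(0, 0, 1)
  r2 <- vcross(ez, r1); r2 <- r2 / sqrt(sum(r2^2))
  r3 <- vcross(r1, r2)
  Rn <- rbind(r1, r2, r3)  # X_rect = Rn %*% X_L
  K_rect <- (rig$K_L + rig$K_R) / 2
  K_rect[1, 2] <- 0
  rot_L <- Rn
  rot_R <- Rn %*% t(rig$R_ext)
  structure(
    list(
      homography_L = K_rect %*% rot_L %*% solve(rig$K_L),
      homography_R = K_rect %*% rot_R %*% solve(rig$K_R),
      K_rect = K_rect, baseline = baseline,
      epipolar_tolerance = epipolar_tolerance,
      rot_L = rot_L, rot_R = rot_R, rig = rig,
      image_size = rig$image_size
    ),
    class = "rectified_rig"
  )
}

#' @export
print.rectified_rig <- function(x, ...) {
  cat("<rectified_rig> baseline ", format(x$baseline, digits = 4),
      " mm, f ", format(x$K_rect[1, 1], digits = 5), " px\n", sep = "")
  invisible(x)
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Inverse-map resampling: each rectified pixel is traced back through the
# rectifying rotation and the distortion model into the source image.
rectify_resample <- function(img, K, dist, rot, K_rect) {
  w <- ncol(img); h <- nrow(img)
  grid <- expand.grid(col = 0:(w - 1), row = 0:(h - 1))
  rays <- t(rot) %*% solve(K_rect) %*% rbind(grid$col, grid$row, 1)
  xn <- rays[1, ] / rays[3, ]
  yn <- rays[2, ] / rays[3, ]
  d <- distort_normalized(xn, yn, dist)
  src_col <- K[1, 1] * d$x + K[1, 2] * d$y + K[1, 3]
  src_row <- K[2, 2] * d$y + K[2, 3]
  vals <- bilinear_sample(img, src_col, src_row)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

# Standard 5-coefficient radial-tangential model on normalized coordinates.
distort_normalized <- function(x, y, dist) {
  if (all(dist == 0)) return(list(x = x, y = y))
  k1 <- dist[1]; k2 <- dist[2]; p1 <- dist[3]; p2 <- dist[4]; k3 <- dist[5]
  r2 <- x^2 + y^2
  rad <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
  list(
    x = x * rad + 2 * p1 * x * y + p2 * (r2 + 2 * x^2),
    y = y * rad + p1 * (r2 + 2 * y^2) + 2 * p2 * x * y
  )
}

# Inverse of distort_normalized by fixed-point iteration.
undistort_normalized <- function(x, y, dist, iter = 8) {
  if (all(dist == 0)) return(list(x = x, y = y))
  xu <- x; yu <- y
  for (i in seq_len(iter)) {
    d <- distort_normalized(xu, yu, dist)
    xu <- xu + (x - d$x)
    yu <- yu + (y - d$y)
  }
  list(x = xu, y = yu)
}

# ---- triangulation and projection -------------------------------------------

#' Triangulate rectified stereo correspondences
#'
#' Depth follows the rectified pinhole relation `Z = f b / d` with disparity
#' `d = col_L - col_R`; lateral coordinates use the mean row.  Points are
#' returned in the left camera's (unrectified) frame, in mm.
#'
#' @param matches Data frame with columns `col_L`, `row_L`, `col_R`, `row_R`
#'   (rectified px).
#' @param rect A `rectified_rig` from [rectify_pair()].
#' @return The input tibble with columns `x`, `y`, `z` (mm) appended.
#' @export
triangulate_points <- function(matches, rect) {
  stopifnot(inherits(rect, "rectified_rig"))
  m <- as_tibble(matches)
  d <- m$col_L - m$col_R
  if (any(d <= 0)) {
    abort("non-positive disparity: point at or behind infinity",
          class = "tissuedeform_behind_camera")
  }
  K <- rect$K_rect
  z <- K[1, 1] * rect$baseline / d
  x <- (m$col_L - K[1, 3]) / K[1, 1] * z
  y <- ((m$row_L + m$row_R) / 2 - K[2, 3]) / K[2, 2] * z
  P <- t(rect$rot_L) %*% rbind(x, y, z)  # back to the left camera frame
  m$x <- P[1, ]; m$y <- P[2, ]; m$z <- P[3, ]
  m
}

#' Project 3D points through the left camera
#'
#' Homogeneous pinhole projection `w = K_L P` with the rig's distortion model,
#' for points expressed in the left camera frame (mm).
#'
#' @param points Data frame with columns `x`, `y`, `z` (mm).
#' @param rig A [camera_rig()] (or a `rectified_rig`, in which case projection
#'   uses the rectified left camera and `camera` selects the view).
#' @param camera `"left"` or `"right"`.
#' @return Input tibble with `col`, `row` (px) appended.
#' @export
project_points <- function(points, rig, camera = c("left", "right")) {
  camera <- match.arg(camera)
  p <- as_tibble(points)
  X <- rbind(p$x, p$y, p$z)
  if (inherits(rig, "rectified_rig")) {
    Xc <- rig$rot_L %*% X  # rectified frame is shared; views differ by baseline
    if (camera == "right") Xc[1, ] <- Xc[1, ] - rig$baseline
    K <- rig$K_rect
    dist <- numeric(5)
  } else {
    stopifnot(inherits(rig, "camera_rig"))
    if (camera == "left") {
      Xc <- X
      K <- rig$K_L; dist <- rig$dist_L
    } else {
      Xc <- rig$R_ext %*% X + rig$t_ext
      K <- rig$K_R; dist <- rig$dist_R
    }
  }
  if (any(Xc[3, ] <= 0)) {
    abort("point behind camera (z <= 0)", class = "tissuedeform_behind_camera")
  }
  d <- distort_normalized(Xc[1, ] / Xc[3, ], Xc[2, ] / Xc[3, ], dist)
  p$col <- K[1, 1] * d$x + K[1, 2] * d$y + K[1, 3]
  p$row <- K[2, 2] * d$y + K[2, 3]
  p
}

# ---- calibration file I/O ---------------------------------------------------

#' Read / write a stereo calibration file
#'
#' Flat key/value text format, one key per line, values space-separated and
#' written with 17 significant digits so that a write/read cycle is bit-exact.
#' Keys: `image_size` (w h), `K_L`, `K_R` (9 numbers, row-major), `dist_L`,
#' `dist_R` (5 numbers), `R_ext` (9, row-major), `t_ext` (3).
#'
#' @param path File path.
#' @return `read_calibration` returns a [camera_rig()].
#' @export
read_calibration <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- lapply(strsplit(lines, "\\s+"), function(x) {
    list(key = x[1], val = as.numeric(x[-1]))
  })
  vals <- setNames(lapply(kv, `[[`, "val"), vapply(kv, `[[`, "", "key"))
  need <- c("image_size", "K_L", "K_R", "dist_L", "dist_R", "R_ext", "t_ext")
  missing <- setdiff(need, names(vals))
  if (length(missing)) {
    abort(paste("calibration file missing keys:", paste(missing, collapse = ", ")),
          class = "tissuedeform_invalid_calibration")
  }
  camera_rig(
    K_L = matrix(vals$K_L, 3, 3, byrow = TRUE),
    K_R = matrix(vals$K_R, 3, 3, byrow = TRUE),
    R_ext = matrix(vals$R_ext, 3, 3, byrow = TRUE),
    t_ext = vals$t_ext, dist_L = vals$dist_L, dist_R = vals$dist_R,
    image_size = vals$image_size
  )
}

#' @param rig A [camera_rig()].
#' @rdname read_calibration
#' @export
write_calibration <- function(rig, path) {
  stopifnot(inherits(rig, "camera_rig"))
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  lines <- c(
    "# tissuedeform stereo calibration",
    paste("image_size", paste(rig$image_size, collapse = " ")),
    paste("K_L", num(t(rig$K_L))),
    paste("K_R", num(t(rig$K_R))),
    paste("dist_L", num(rig$dist_L)),
    paste("dist_R", num(rig$dist_R)),
    paste("R_ext", num(t(rig$R_ext))),
    paste("t_ext", num(rig$t_ext))
  )
  writeLines(lines, path)
  invisible(path)
}
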