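# Stereo geometry: rectification, triangulation, projection, calibration I/O.

make_K <- function(f = 1000, cx = 320, cy = 240) {
  matrix(c(f, 0, cx, 0, f, cy, 0, 0, 1), 3, 3, byrow = TRUE)
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}
rot_y <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3, byrow = TRUE)
}

test_that("an already row-aligned fronto-parallel rig rectifies to the identity", {
  rig <- camera_rig(K_L = make_K(), t_ext = c(-5, 0, 0), image_size = c(640, 480))
  img <- matrix(runif(640 * 480), 480, 640)
  rp <- rectify_pair(rig, img, img)
  expect_lt(max(abs(rp$rig$homography_L - diag(3))), 1e-10)
  expect_lt(max(abs(rp$rig$homography_R - diag(3))), 1e-10)
  expect_equal(rp$rig$baseline, 5)
})

test_that("a rotated rig rectifies ground-truth correspondences to common rows", {
  R <- rot_z(5) %*% rot_y(3)
  rig <- camera_rig(K_L = make_K(), R_ext = R,
                    t_ext = as.numeric(-R %*% c(5, 0.3, 0.2)),
                    image_size = c(640, 480))
  rect <- rectify_pair(rig, matrix(0.5, 480, 640), matrix(0.5, 480, 640))$rig
  set.seed(3)
  pts <- tibble::tibble(x = runif(100, -20, 20), y = runif(100, -15, 15),
                        z = runif(100, 80, 150))
  # original-camera projections mapped through the rectifying homographies
  pl <- project_points(pts, rig, "left")
  pr <- project_points(pts, rig, "right")
  hl <- rect$homography_L %*% rbind(pl$col, pl$row, 1)
  hr <- rect$homography_R %*% rbind(pr$col, pr$row, 1)
  rows_L <- hl[2, ] / hl[3, ]
  rows_R <- hr[2, ] / hr[3, ]
  expect_lte(max(abs(rows_L - rows_R)), 0.5)
})

test_that("a zero-baseline rig is rejected as invalid geometry", {
  expect_error(
    camera_rig(K_L = make_K(), t_ext = c(0, 0, 0), image_size = c(640, 480)),
    class = "tissuedeform_invalid_geometry"
  )
})

test_that("triangulation follows Z = f b / d and round-trips random points", {
  rig <- camera_rig(K_L = make_K(), t_ext = c(-5, 0, 0), image_size = c(640, 480))
  rect <- rectify_pair(rig, matrix(0.5, 480, 640), matrix(0.5, 480, 640))$rig
  # closed form: focal 1000 px, baseline 5 mm, disparity 50 px at the
  # principal point column -> depth 100 mm
  p <- triangulate_points(
    tibble::tibble(col_L = 320, row_L = 240, col_R = 270, row_R = 240), rect
  )
  expect_equal(p$z, 100, tolerance = 1e-12)

  set.seed(4)
  pts <- tibble::tibble(x = runif(50, -20, 20), y = runif(50, -15, 15),
                        z = runif(50, 80, 150))
  pl <- project_points(pts, rect, "left")
  pr <- project_points(pts, rect, "right")
  tr <- triangulate_points(
    tibble::tibble(col_L = pl$col, row_L = pl$row, col_R = pr$col, row_R = pr$row),
    rect
  )
  expect_lt(max(abs(tr$x - pts$x)), 1e-6)
  expect_lt(max(abs(tr$y - pts$y)), 1e-6)
  expect_lt(max(abs(tr$z - pts$z)), 1e-6)
})

test_that("non-positive disparity raises a behind-camera error", {
  rig <- camera_rig(K_L = make_K(), t_ext = c(-5, 0, 0), image_size = c(640, 480))
  rect <- rectify_pair(rig, matrix(0.5, 480, 640), matrix(0.5, 480, 640))$rig
  expect_error(
    triangulate_points(tibble::tibble(col_L = 100, row_L = 50, col_R = 100,
                                      row_R = 50), rect),
    class = "tissuedeform_behind_camera"
  )
})

test_that("projection maps the optical axis to the principal point and rejects z <= 0", {
  rig <- camera_rig(K_L = make_K(), t_ext = c(-5, 0, 0), image_size = c(640, 480))
  p <- project_points(tibble::tibble(x = 0, y = 0, z = 120), rig, "left")
  expect_equal(c(p$col, p$row), c(320, 240))
  expect_error(
    project_points(tibble::tibble(x = 1, y = 1, z = 0), rig, "left"),
    class = "tissuedeform_behind_camera"
  )
})

test_that("project after triangulate is the identity on rectified correspondences", {
  R <- rot_z(2) %*% rot_y(1)
  rig <- camera_rig(K_L = make_K(), K_R = make_K(f = 1050, cx = 310),
                    R_ext = R, t_ext = as.numeric(-R %*% c(6, 0.1, 0.1)),
                    image_size = c(640, 480))
  rect <- rectify_pair(rig, matrix(0.5, 480, 640), matrix(0.5, 480, 640))$rig
  set.seed(5)
  m <- tibble::tibble(col_L = runif(50, 100, 500), row_L = runif(50, 50, 400))
  m$row_R <- m$row_L
  m$col_R <- m$col_L - runif(50, 20, 80)
  tr <- triangulate_points(m, rect)
  back_L <- project_points(tr, rect, "left")
  back_R <- project_points(tr, rect, "right")
  expect_lt(max(abs(back_L$col - m$col_L)), 1e-6)
  expect_lt(max(abs(back_L$row - (m$row_L + m$row_R) / 2)), 1e-6)
  expect_lt(max(abs(back_R$col - m$col_R)), 1e-6)
})

test_that("triangulated depth strictly decreases with disparity", {
  rig <- camera_rig(K_L = make_K(), t_ext = c(-5, 0, 0), image_size = c(640, 480))
  rect <- rectify_pair(rig, matrix(0.5, 480, 640), matrix(0.5, 480, 640))$rig
  disp <- seq(5, 100, by = 5)
  z <- triangulate_points(
    tibble::tibble(col_L = 320, row_L = 240, col_R = 320 - disp, row_R = 240),
    rect
  )$z
  expect_true(all(diff(z) < 0))
})

test_that("rectification preserves image content away from borders", {
  R <- rot_z(3)
  rig <- camera_rig(K_L = make_K(cx = 160, cy = 120), R_ext = R,
                    t_ext = as.numeric(-R %*% c(5, 0, 0)),
                    image_size = c(320, 240))
  img <- texture_image(240, 320, seed = 9)
  rp <- rectify_pair(rig, img, img)
  # map the rectified image back through the inverse homography and compare
  h <- nrow(img); w <- ncol(img)
  g <- expand.grid(col = 30:(w - 31), row = 30:(h - 31))
  fwd <- rp$rig$homography_L %*% rbind(g$col, g$row, 1)
  vals <- tissuedeform:::bilinear_sample(rp$left, fwd[1, ] / fwd[3, ],
                                         fwd[2, ] / fwd[3, ])
  orig <- img[cbind(g$row + 1, g$col + 1)]
  expect_lt(mean(abs(vals - orig)), 2 / 255)
})

test_that("calibration files round-trip bit-exactly", {
  R <- rot_z(4) %*% rot_y(-2)
  rig <- camera_rig(K_L = make_K(f = 1234.56789), K_R = make_K(f = 987.654321),
                    R_ext = R, t_ext = c(-5.123456789, 0.01, 0.002),
                    dist_L = c(0.1, -0.05, 0.001, -0.002, 0.0003),
                    image_size = c(640, 480))
  path <- withr::local_tempfile(fileext = ".txt")
  write_calibration(rig, path)
  rig2 <- read_calibration(path)
  expect_identical(rig$K_L, rig2$K_L)
  expect_identical(rig$K_R, rig2$K_R)
  expect_identical(rig$R_ext, rig2$R_ext)
  expect_identical(rig$t_ext, rig2$t_ext)
  expect_identical(rig$dist_L, rig2$dist_L)
  expect_identical(rig$image_size, rig2$image_size)
})

test_that("PLY clouds round-trip including a deformation property", {
  cloud <- tibble::tibble(x = c(1.5, -2.25, 0), y = c(0, 3, -1),
                          z = c(100, 101.5, 99.75), deformation = c(0, 0.5, 2))
  path <- withr::local_tempfile(fileext = ".ply")
  write_ply(cloud, path)
  back <- read_ply(path)
  expect_equal(back$x, cloud$x, tolerance = 1e-6)
  expect_equal(back$z, cloud$z, tolerance = 1e-6)
  expect_equal(back$deformation, cloud$deformation, tolerance = 1e-6)
})
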