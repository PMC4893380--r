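# Shared fixtures, generated in code and cached for the duration of the test
# run (several tests reuse the same rendered scenes).

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# Small deforming scene: 320 x 240, five frames ramping to a 10 mm indentation.
small_scene <- function() {
  cached("small_scene",
         make_scene(image_size = c(320, 240), n_frames = 5, max_indent_mm = 10,
                    seed = 7))
}

small_frames <- function() {
  cached("small_frames",
         lapply(seq_along(small_scene()$amplitudes),
                function(f) render_stereo(small_scene(), f)))
}

# Static variant of the same surface (no indentation, no tool).
static_scene <- function() {
  cached("static_scene",
         make_scene(image_size = c(320, 240), n_frames = 1, seed = 7,
                    tool = FALSE))
}

static_render <- function() {
  cached("static_render", render_stereo(static_scene(), 1))
}

static_rect <- function() {
  cached("static_rect", {
    r <- static_render()
    rectify_pair(static_scene()$rig, r$img_L, r$img_R)$rig
  })
}

static_features <- function() {
  cached("static_features", {
    r <- static_render()
    list(L = detect_regions(r$img_L), R = detect_regions(r$img_R))
  })
}

static_matches <- function() {
  cached("static_matches",
         match_global(static_features()$L, static_features()$R))
}

# Full deformation-tracking run on the small deforming scene.
small_tracking <- function() {
  cached("small_tracking", {
    fr <- small_frames()
    suppressWarnings(track_deformation(
      static_rect_for(small_scene()),
      lapply(fr, `[[`, "img_L"), lapply(fr, `[[`, "img_R")
    ))
  })
}

static_rect_for <- function(scene) {
  r <- render_stereo(scene, 1)
  rectify_pair(scene$rig, r$img_L, r$img_R)$rig
}

# Default-geometry scene (640 x 480) used for the full-scale reconstruction
# checks.
default_scene <- function() {
  cached("default_scene", make_scene(seed = 11, n_frames = 1, tool = FALSE))
}

default_render <- function() {
  cached("default_render", render_stereo(default_scene(), 1))
}

default_reconstruction <- function() {
  cached("default_reconstruction", {
    r <- default_render()
    rp <- rectify_pair(default_scene()$rig, r$img_L, r$img_R)
    t0 <- Sys.time()
    rec <- reconstruct_pair(rp$rig, rp$left, rp$right)
    rec$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    rec
  })
}

# True depth along the left-camera ray of each cloud point (mm).
true_z_along_ray <- function(scene, col, row, amplitude = 0) {
  K <- scene$rig$K_L
  dx <- (col - K[1, 3]) / K[1, 1]
  dy <- (row - K[2, 3]) / K[2, 2]
  z <- rep(scene$depth_mm, length(col))
  for (i in 1:12) {
    z <- tissuedeform:::surface_height(scene, z * dx, z * dy, amplitude)
  }
  z
}

# True right-image column for left pixels (for disparity accuracy checks).
true_right_col <- function(scene, col, row, amplitude = 0) {
  K <- scene$rig$K_L
  dx <- (col - K[1, 3]) / K[1, 1]
  dy <- (row - K[2, 3]) / K[2, 2]
  z <- true_z_along_ray(scene, col, row, amplitude)
  pr <- project_points(tibble::tibble(x = z * dx, y = z * dy, z = z),
                       scene$rig, "right")
  pr$col
}

# Test image with anisotropic Gaussian blobs at known positions.
blob_image <- function(n_blobs = 20, size = 200, seed = 42, amp = 0.6) {
  set.seed(seed)
  xs <- outer(rep(1, size), 0:(size - 1))
  ys <- outer(0:(size - 1), rep(1, size))
  img <- matrix(0.3, size, size)
  truth <- cbind(col = runif(n_blobs, 20, size - 20),
                 row = runif(n_blobs, 20, size - 20))
  for (i in seq_len(n_blobs)) {
    th <- runif(1, 0, pi); sx <- runif(1, 2, 4); sy <- runif(1, 2, 4)
    dx <- xs - truth[i, 1]; dy <- ys - truth[i, 2]
    u <- cos(th) * dx + sin(th) * dy
    v <- -sin(th) * dx + cos(th) * dy
    img <- img + amp * exp(-(u^2 / (2 * sx^2) + v^2 / (2 * sy^2)))
  }
  list(image = img, truth = truth)
}

# Band-limited random texture image (for tracking / warp tests).
texture_image <- function(h = 160, w = 200, seed = 5) {
  set.seed(seed)
  img <- matrix(runif(h * w), h, w)
  img <- tissuedeform:::gauss_blur(img, 2)
  r <- range(img)
  0.2 + 0.6 * (img - r[1]) / diff(r)
}

# Resample an image under an affine map of pixel coordinates:
# output(u) = input(A^{-1} (u - t)), i.e. features move as u' = A u + t.
warp_image_affine <- function(img, A, t) {
  h <- nrow(img); w <- ncol(img)
  g <- expand.grid(col = 0:(w - 1), row = 0:(h - 1))
  Ainv <- solve(A)
  src <- t(Ainv %*% (t(as.matrix(g)) - t))
  vals <- tissuedeform:::bilinear_sample(img, src[, 1], src[, 2])
  matrix(vals, h, w, byrow = TRUE)
}

expect_error_class <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
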