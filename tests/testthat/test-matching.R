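# Constrained global matching, densification, normals, propagation and
# triangulation to a cloud.

test_that("similarity score combines overlap and saliency agreement", {
  f <- tibble::tibble(id = 1:2, col = c(50, 50), row = c(50, 50),
                      c = c(3, 3), sigma = 3,
                      s11 = 100, s12 = 0, s22 = 100, patch = list(NULL, NULL))
  expect_equal(similarity_score(f[1, ], f[2, ]), 2.0)
  # disjoint regions with saliencies 1 and 2 -> 0 + 0.5
  g <- f
  g$col <- c(0, 100); g$c <- c(1, 2)
  expect_equal(similarity_score(g[1, ], g[2, ]), 0.5)
  # overlapping circles (r = 10, centers 10 px apart), saliencies 3 and 4
  h <- f
  h$col <- c(0, 10); h$row <- c(0, 0); h$c <- c(3, 4)
  lens <- 2 * 100 * acos(0.5) - 5 * sqrt(300)
  iou <- lens / (2 * pi * 100 - lens)
  expect_equal(similarity_score(h[1, ], h[2, ]), iou + 0.75, tolerance = 1e-3)
  # invalid saliency
  bad <- f; bad$c <- c(0, 1)
  expect_error(similarity_score(bad[1, ], bad[2, ]),
               class = "tissuedeform_invalid_feature")
})

test_that("a single admissible candidate is matched; constraint failures are not", {
  base <- tibble::tibble(id = 1L, col = 100, row = 50, c = 2, sigma = 3,
                         s11 = 60, s12 = 0, s22 = 60,
                         patch = list(matrix(seq(0, 1, length.out = 441), 21, 21)))
  right <- base
  right$col <- 80
  expect_equal(nrow(match_global(base, right)), 1)
  # candidate outside the epipolar band
  far <- right; far$row <- 55
  expect_equal(nrow(match_global(base, far)), 0)
  # appearance below thr_s
  noisy <- right
  set.seed(2); noisy$patch <- list(matrix(runif(441), 21, 21))
  expect_equal(nrow(match_global(base, noisy)), 0)
})

test_that("global matching equals the exhaustive constrained-argmax oracle", {
  f <- static_features()
  fL <- head(f$L, 200)
  fR <- head(f$R, 200)
  got <- match_global(fL, fR)
  want <- brute_force_match(fL, fR)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$left_id, want$left_id)
  expect_equal(got$right_id, want$right_id)
  expect_equal(got$M, want$M, tolerance = 1e-12)
})

test_that("global matching is invariant to feature ordering and one-to-one", {
  f <- static_features()
  fL <- head(f$L, 120); fR <- head(f$R, 120)
  m1 <- match_global(fL, fR)
  set.seed(99)
  m2 <- match_global(fL[sample(nrow(fL)), ], fR[sample(nrow(fR)), ])
  key <- function(m) paste(m$left_id, m$right_id)
  expect_setequal(key(m1), key(m2))
  expect_false(any(duplicated(m1$left_id)))
  expect_false(any(duplicated(m1$right_id)))
})

test_that("raising the appearance threshold never increases the match count", {
  f <- static_features()
  fL <- head(f$L, 150); fR <- head(f$R, 150)
  counts <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.99), function(t) {
    nrow(match_global(fL, fR, match_config(thr_s = t)))
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("matches respect the epipolar band and both thresholds", {
  m <- static_matches()
  cfg <- match_config()
  expect_gt(nrow(m), 0)
  expect_true(all(abs(m$row_L - m$row_R) <= cfg$epipolar_tolerance))
  expect_true(all(m$A > cfg$thr_s))
  expect_true(all(m$M > cfg$thr_r))  # M = iou + ratio with iou > thr_r
})

test_that("local densification strictly increases matches and is a superset", {
  r <- static_render()
  seeds <- head(static_matches(), 30)
  out <- densify_local(seeds, r$img_L, r$img_R)
  expect_gt(nrow(out), nrow(seeds))
  expect_true(all(paste(seeds$left_id, seeds$right_id) %in%
                  paste(out$left_id, out$right_id)))
  added <- out[out$stage == "local", ]
  cfg <- match_config()
  expect_true(all(abs(added$row_L - added$row_R) <= cfg$epipolar_tolerance))
  expect_true(all(added$A > cfg$thr_s))
})

test_that("densification adds nothing inside a textureless region", {
  img <- matrix(0.5, 160, 160)
  # one lonely blob pair so there is a seed, surrounded by flatness
  xs <- outer(rep(1, 160), 0:159); ys <- outer(0:159, rep(1, 160))
  blob <- 0.4 * exp(-((xs - 80)^2 + (ys - 80)^2) / (2 * 9))
  img_L <- img + blob
  img_R <- img + 0.4 * exp(-((xs - 70)^2 + (ys - 80)^2) / (2 * 9))
  fL <- detect_regions(img_L)
  fR <- detect_regions(img_R)
  m <- match_global(fL, fR, match_config(thr_s = 0.5))
  if (nrow(m)) {
    out <- densify_local(m, img_L, img_R, match_config(thr_s = 0.5))
    expect_equal(sum(out$stage == "local"), 0)
  } else succeed()
})

test_that("surface normals follow N = (p, q, -1)/sqrt(p^2+q^2+1) with unit norm", {
  r <- static_render()
  nm <- estimate_normals(r$img_L, focal_px = static_scene()$rig$K_L[1, 1])
  norm2 <- nm$nx^2 + nm$ny^2 + nm$nz^2
  expect_lt(max(abs(norm2 - 1)), 1e-9)
  expect_true(all(nm$nz < 0))
  # direct substitutions of the normal formula
  den <- sqrt(nm$p^2 + nm$q^2 + 1)
  expect_equal(nm$nx, nm$p / den, tolerance = 1e-12)
  expect_equal(nm$nz, -1 / den, tolerance = 1e-12)
  # a flat region (p = q = 0) maps to [0, 0, -1]
  flat <- which(nm$p == 0 & nm$q == 0)
  if (length(flat)) {
    expect_equal(nm$nz[flat][1], -1)
  }
})

test_that("a fronto-parallel uniform Lambertian plane yields near-vertical normals", {
  sc <- make_scene(image_size = c(320, 240), n_frames = 1, seed = 7,
                   relief_mm = 1e-9, tool = FALSE)
  sc$texture[] <- 0.7
  r <- render_stereo(sc, 1)
  nm <- estimate_normals(r$img_L, focal_px = sc$rig$K_L[1, 1],
                         center_px = c(sc$rig$K_L[1, 3], sc$rig$K_L[2, 3]))
  ang <- acos(pmin(-nm$nz, 1)) * 180 / pi
  interior <- ang[30:210, 30:290]
  expect_gte(mean(interior < 1), 0.9)
})

test_that("propagation with an identity seed affine is a pure disparity shift", {
  # seed with identical left/right ellipses and identical patches
  patch <- tissuedeform:::gauss_blur(matrix(runif(441), 21, 21), 1)
  A <- tissuedeform:::seed_affine(c(25, 0, 25), c(25, 0, 25), patch, patch)
  expect_lt(max(abs(A - diag(2))), 1e-9)
  # predicted location: f_R = A (f_L - seed_L) + seed_R
  fc <- A %*% c(3, -2) + c(80, 50)
  expect_equal(as.numeric(fc), c(83, 48))
})

test_that("candidates whose normal differs beyond the gate are not propagated", {
  r <- static_render()
  m <- head(static_matches(), 20)
  f <- static_features()
  cand <- f$L[!f$L$id %in% m$left_id, ]
  # constant normal map: everything passes a 1-degree gate
  h <- nrow(r$img_L); w <- ncol(r$img_L)
  flat <- structure(list(p = matrix(0, h, w), q = matrix(0, h, w),
                         nx = matrix(0, h, w), ny = matrix(0, h, w),
                         nz = matrix(-1, h, w)),
                    class = "surface_normal_map")
  p_flat <- propagate_matches(m, cand, r$img_L, r$img_R, flat)
  # tilt the candidate normals by 2 degrees: the same candidates are rejected
  th <- 2 * pi / 180
  tilted <- flat
  tilted$nx <- matrix(sin(th), h, w); tilted$nz <- matrix(-cos(th), h, w)
  n_seed <- tissuedeform:::normals_at(flat, m$col_L, m$row_L)
  tilted_map <- flat
  # seed rows keep flat normals, everything else tilted
  tilted_map$nx <- tilted$nx; tilted_map$nz <- tilted$nz
  idx <- cbind(round(m$row_L) + 1, round(m$col_L) + 1)
  tilted_map$nx[idx] <- 0; tilted_map$nz[idx] <- -1
  p_gate <- propagate_matches(m, cand, r$img_L, r$img_R, tilted_map)
  expect_equal(nrow(p_gate), 0)
  expect_gte(nrow(p_flat), nrow(p_gate))
})

test_that("propagated positions agree with a known affine warp of the image", {
  img_L <- texture_image(180, 220, seed = 77)
  A_true <- matrix(c(1.04, 0.015, -0.02, 0.97), 2, 2)
  t_true <- c(-14, 1)
  img_R <- warp_image_affine(img_L, A_true, t_true)
  fL <- detect_regions(img_L)
  fR <- detect_regions(img_R)
  m <- match_global(fL, fR, match_config(epipolar_tolerance = 6, thr_s = 0.7,
                                         thr_r = 0.3))
  m <- refine_matches(m, img_L, img_R)  # prune outlier seeds
  cand <- fL[!fL$id %in% m$left_id, ]
  h <- nrow(img_L); w <- ncol(img_L)
  flat <- structure(list(p = matrix(0, h, w), q = matrix(0, h, w),
                         nx = matrix(0, h, w), ny = matrix(0, h, w),
                         nz = matrix(-1, h, w)),
                    class = "surface_normal_map")
  prop <- propagate_matches(m, cand, img_L, img_R, flat,
                            match_config(epipolar_tolerance = 6,
                                         propagation_threshold = 0.6,
                                         seed_area_scale = 4))
  expect_gt(nrow(prop), 0)
  pred_true <- t(A_true %*% t(cbind(prop$col_L, prop$row_L)) + t_true)
  err <- sqrt((prop$col_R - pred_true[, 1])^2 + (prop$row_R - pred_true[, 2])^2)
  # the one-shot affine adaptation of the blob detector limits the raw
  # prediction to sub-pixel but not deep-sub-pixel accuracy ...
  expect_lt(stats::median(err), 0.8)
  # ... and the subsequent gradient-based refinement (as run by the pipeline)
  # restores deep-sub-pixel correspondence
  ref <- refine_matches(prop, img_L, img_R, min_ncc = 0.6)
  ref_true <- t(A_true %*% t(cbind(ref$col_L, ref$row_L)) + t_true)
  err_ref <- sqrt((ref$col_R - ref_true[, 1])^2 + (ref$row_R - ref_true[, 2])^2)
  expect_lt(stats::median(err_ref), 0.15)
})

test_that("reconstruction conserves matches and hits the true surface", {
  m <- static_matches()
  rect <- static_rect()
  cloud <- reconstruct_cloud(m, rect)
  expect_equal(nrow(cloud), nrow(m))  # no behind-camera rejections here
  z_true <- true_z_along_ray(static_scene(), cloud$col_L, cloud$row_L)
  expect_lt(mean(abs(cloud$z - z_true)), 0.5)
  # empty input -> empty cloud
  expect_equal(nrow(reconstruct_cloud(m[0, ], rect)), 0)
  # a non-positive disparity match is dropped with a warning
  bad <- m[1, ]
  bad$col_R <- bad$col_L + 5
  expect_warning(out <- reconstruct_cloud(rbind(bad, m[2:3, ]), rect),
                 "non-positive disparity")
  expect_equal(nrow(out), 2)
})
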