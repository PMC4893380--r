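# Quasi-dense stereo correspondence: constrained global matching of salient
# regions, local densification, and normal-gated affine propagation, followed
# by sub-pixel refinement and triangulation.

#' Matching configuration
#'
#' @param thr_r Region-overlap threshold (intersection-over-union of the
#'   disparity-compensated ellipses must exceed this); default 0.60.
#' @param thr_s Appearance-similarity threshold (histogram-equalized NCC of
#'   the region patches must exceed this); default 0.90.
#' @param epipolar_tolerance Half-height of the epipolar search band (px).
#' @param normal_gate_deg Maximum surface-normal difference (degrees) between
#'   a propagation seed and a candidate; default 1.
#' @param propagation_threshold Minimum appearance similarity at the predicted
#'   location for a propagated match to be kept; default 0.80.
#' @param min_disparity,max_disparity Admissible disparity range (px);
#'   `max_disparity = Inf` disables the upper bound.
#' @param seed_area_scale Candidates count as lying "within the area" of a
#'   seed when inside the seed ellipse inflated by this linear factor.
#' @return A `match_config` list.
#' @export
match_config <- function(thr_r = 0.60, thr_s = 0.90, epipolar_tolerance = 1.5,
                         normal_gate_deg = 1, propagation_threshold = 0.80,
                         min_disparity = 0, max_disparity = Inf,
                         seed_area_scale = 3) {
  stopifnot(thr_r >= 0, thr_r <= 1, thr_s >= 0, thr_s <= 1,
            normal_gate_deg > 0, epipolar_tolerance > 0)
  structure(
    list(thr_r = thr_r, thr_s = thr_s, epipolar_tolerance = epipolar_tolerance,
         normal_gate_deg = normal_gate_deg,
         propagation_threshold = propagation_threshold,
         min_disparity = min_disparity, max_disparity = max_disparity,
         seed_area_scale = seed_area_scale),
    class = "match_config"
  )
}

feature_ellipse <- function(feats, i) {
  ellipse(c(feats$col[i], feats$row[i]),
          c(feats$s11[i], feats$s12[i], feats$s22[i]))
}

#' Similarity of two salient regions
#'
#' The sum of the relative region overlap (intersection-over-union of the
#' elliptical regions) and the saliency-agreement ratio
#' `min(c_i, c_j) / max(c_i, c_j)`, hence a score in \[0, 2\].
#'
#' @param f_i,f_j Single-row feature tibbles (see [detect_regions()]).
#' @param compensate If `TRUE`, translate `f_j`'s ellipse onto `f_i`'s center
#'   before computing the overlap (used for cross-camera comparison, where
#'   disparity would otherwise destroy the overlap).
#' @return Scalar M in \[0, 2\].
#' @export
similarity_score <- function(f_i, f_j, compensate = FALSE) {
  if (f_i$c[1] <= 0 || f_j$c[1] <= 0) {
    abort("saliency strength must be positive", class = "tissuedeform_invalid_feature")
  }
  e_i <- feature_ellipse(f_i, 1)
  e_j <- feature_ellipse(f_j, 1)
  if (compensate) e_j$center <- e_i$center
  ellipse_overlap(e_i, e_j) + min(f_i$c[1], f_j$c[1]) / max(f_i$c[1], f_j$c[1])
}

# Histogram-equalized, mean-centered, unit-norm patch vectors as a matrix
# (one row per feature); zero-variance rows are left at zero.
patch_matrix <- function(feats) {
  if (!nrow(feats)) return(matrix(0, 0, 0))
  m <- t(vapply(feats$patch, function(p) {
    v <- as.vector(hist_equalize(p))
    v <- v - mean(v)
    n <- sqrt(sum(v^2))
    if (n > 0) v / n else v
  }, numeric(length(feats$patch[[1]]))))
  m
}

#' Global constrained stereo matching
#'
#' For each left feature, candidates are the right features inside the
#' epipolar band; the match is the candidate maximizing the region similarity
#' M (overlap + saliency ratio), subject to overlap > `thr_r` and appearance
#' similarity A > `thr_s`.  Overlap is computed after translating the right
#' ellipse onto the left center (disparity compensation).  Ties are broken by
#' higher A, then smaller disparity.  Each right feature is kept at most once
#' (highest M wins), so the output is one-to-one.
#'
#' @param features_L,features_R Feature tibbles from [detect_regions()] on the
#'   rectified left/right images.
#' @param config A [match_config()].
#' @return Match tibble: `left_id`, `right_id`, `col_L`, `row_L`, `col_R`,
#'   `row_R`, `M`, `A`, `stage` plus per-side saliency, shape and patch
#'   columns used by later stages.
#' @export
match_global <- function(features_L, features_R, config = match_config()) {
  out <- empty_matches()
  if (!nrow(features_L) || !nrow(features_R)) return(out)
  PL <- patch_matrix(features_L)
  PR <- patch_matrix(features_R)
  A_all <- PL %*% t(PR)

  rows <- vector("list", nrow(features_L))
  for (i in seq_len(nrow(features_L))) {
    d <- features_L$col[i] - features_R$col
    J <- which(abs(features_R$row - features_L$row[i]) <= config$epipolar_tolerance &
               d >= config$min_disparity & d <= config$max_disparity)
    if (!length(J)) next
    A <- A_all[i, J]
    J <- J[A > config$thr_s]; A <- A[A > config$thr_s]
    if (!length(J)) next
    e_i <- feature_ellipse(features_L, i)
    iou <- vapply(J, function(j) {
      e_j <- feature_ellipse(features_R, j)
      e_j$center <- e_i$center
      ellipse_overlap(e_i, e_j)
    }, 0)
    keep <- iou > config$thr_r
    if (!any(keep)) next
    J <- J[keep]; A <- A[keep]; iou <- iou[keep]
    cr <- pmin(features_L$c[i], features_R$c[J]) / pmax(features_L$c[i], features_R$c[J])
    M <- iou + cr
    disp <- features_L$col[i] - features_R$col[J]
    best <- order(-M, -A, disp)[1]
    rows[[i]] <- tibble(
      left_id = features_L$id[i], right_id = features_R$id[J[best]],
      M = M[best], A = A[best]
    )
  }
  cand <- dplyr::bind_rows(rows)
  if (!nrow(cand)) return(out)
  # left-right uniqueness: keep the highest-M claim on each right feature
  cand <- cand[order(-cand$M, -cand$A, cand$left_id), ]
  cand <- cand[!duplicated(cand$right_id), ]
  cand <- cand[order(cand$left_id), ]
  build_matches(cand, features_L, features_R, stage = "global")
}

empty_matches <- function() {
  tibble(left_id = integer(), right_id = integer(),
         col_L = numeric(), row_L = numeric(), col_R = numeric(), row_R = numeric(),
         M = numeric(), A = numeric(), stage = character(),
         c_L = numeric(), c_R = numeric(),
         shape_L = list(), shape_R = list(), patch_L = list(), patch_R = list())
}

build_matches <- function(cand, features_L, features_R, stage) {
  il <- match(cand$left_id, features_L$id)
  ir <- match(cand$right_id, features_R$id)
  tibble(
    left_id = cand$left_id, right_id = cand$right_id,
    col_L = features_L$col[il], row_L = features_L$row[il],
    col_R = features_R$col[ir], row_R = features_R$row[ir],
    M = cand$M, A = cand$A, stage = stage,
    c_L = features_L$c[il], c_R = features_R$c[ir],
    shape_L = lapply(il, function(i) c(features_L$s11[i], features_L$s12[i], features_L$s22[i])),
    shape_R = lapply(ir, function(i) c(features_R$s11[i], features_R$s12[i], features_R$s22[i])),
    patch_L = features_L$patch[il], patch_R = features_R$patch[ir]
  )
}

#' Local densification of stereo matches
#'
#' Re-detects features at a finer threshold inside the image areas covered by
#' the seed matches' ellipses (inflated), then matches the new detections
#' under the same constraints as [match_global()].  The result is a superset
#' of the input; added matches carry `stage = "local"`.
#'
#' @param matches Seed matches from [match_global()].
#' @param img_L,img_R Rectified images.
#' @param config A [match_config()].
#' @param detect_args Arguments passed on to [detect_regions()] for the local
#'   pass (the response threshold is halved by default).
#' @return Augmented match tibble.
#' @export
densify_local <- function(matches, img_L, img_R, config = match_config(),
                          detect_args = list()) {
  if (!nrow(matches)) return(matches)
  da <- modifyList(list(threshold = 2.5e-4, min_separation = 3,
                        max_features = 4000), detect_args)
  mask_L <- seed_mask(matches, img_L, side = "L")
  mask_R <- seed_mask(matches, img_R, side = "R")
  fL <- do.call(detect_regions, c(list(img_L), da))
  fR <- do.call(detect_regions, c(list(img_R), da))
  fL <- fL[mask_lookup(mask_L, fL) &
           !near_existing(fL, matches$col_L, matches$row_L, da$min_separation), ]
  fR <- fR[mask_lookup(mask_R, fR) &
           !near_existing(fR, matches$col_R, matches$row_R, da$min_separation), ]
  if (!nrow(fL) || !nrow(fR)) return(matches)
  id0_L <- max(matches$left_id); id0_R <- max(matches$right_id)
  fL$id <- id0_L + seq_len(nrow(fL)); fR$id <- id0_R + seq_len(nrow(fR))
  add <- match_global(fL, fR, config)
  if (nrow(add)) {
    add$stage <- "local"
    matches <- dplyr::bind_rows(matches, add)
  }
  # expose the local detections so propagation can draw on the unmatched ones
  attr(matches, "local_features_L") <- fL
  attr(matches, "local_features_R") <- fR
  matches
}

# Logical mask covering the (inflated) bounding boxes of seed ellipses.
seed_mask <- function(matches, img, side, inflate = 2) {
  m <- matrix(FALSE, nrow(img), ncol(img))
  cols <- matches[[paste0("col_", side)]]
  rows <- matches[[paste0("row_", side)]]
  shapes <- matches[[paste0("shape_", side)]]
  for (i in seq_along(cols)) {
    s <- shapes[[i]]
    rx <- inflate * sqrt(s[1]); ry <- inflate * sqrt(s[3])
    c0 <- max(1, floor(cols[i] - rx) + 1); c1 <- min(ncol(img), ceiling(cols[i] + rx) + 1)
    r0 <- max(1, floor(rows[i] - ry) + 1); r1 <- min(nrow(img), ceiling(rows[i] + ry) + 1)
    if (c0 <= c1 && r0 <= r1) m[r0:r1, c0:c1] <- TRUE
  }
  m
}

mask_lookup <- function(mask, feats) {
  if (!nrow(feats)) return(logical(0))
  mask[cbind(pmin(pmax(round(feats$row) + 1, 1), nrow(mask)),
             pmin(pmax(round(feats$col) + 1, 1), ncol(mask)))]
}

near_existing <- function(feats, cols, rows, min_sep) {
  if (!nrow(feats)) return(logical(0))
  vapply(seq_len(nrow(feats)), function(i) {
    any((cols - feats$col[i])^2 + (rows - feats$row[i])^2 < min_sep^2)
  }, FALSE)
}

#' Sub-pixel refinement of match positions
#'
#' Refines each right-image location by gradient-based (Lucas-Kanade)
#' translation alignment of the right image against the left patch around the
#' matched left location, which removes the detector's residual localization
#' error before triangulation.  Matches whose verification NCC falls below
#' `min_ncc` are dropped.
#'
#' @param matches Match tibble.
#' @param img_L,img_R Rectified images.
#' @param patch_radius Half-size of the alignment window (px).
#' @param min_ncc Post-refinement NCC acceptance threshold.
#' @return Match tibble with updated `col_R`, `row_R` and `A`.
#' @export
refine_matches <- function(matches, img_L, img_R, patch_radius = 7, min_ncc = 0.5) {
  if (!nrow(matches)) return(matches)
  keep <- rep(TRUE, nrow(matches))
  for (i in seq_len(nrow(matches))) {
    tmpl <- sample_window(img_L, matches$col_L[i], matches$row_L[i], patch_radius)
    res <- lk_align(img_R, tmpl, matches$col_R[i], matches$row_R[i], patch_radius)
    if (is.null(res) || res$ncc < min_ncc || !is.finite(res$col)) {
      keep[i] <- FALSE
      next
    }
    matches$col_R[i] <- res$col
    matches$row_R[i] <- res$row
    matches$A[i] <- res$ncc
  }
  matches[keep, ]
}

sample_window <- function(img, col, row, r) {
  u <- seq(-r, r)
  g <- expand.grid(dx = u, dy = u)
  matrix(bilinear_sample(img, col + g$dx, row + g$dy), 2 * r + 1, 2 * r + 1)
}

# Affine-extended Lucas-Kanade: refines a 2x2 linear warp A and center so
# that img(A u + center) matches tmpl(u) over template offsets u.  Used after
# translation-only alignment where the local deformation includes scale or
# shear (a translation-only tracker lags systematically there).  Returns the
# refined center, warp and NCC of the warped patch.
lk_align_affine <- function(img, tmpl, col, row, r, max_iter = 25, tol = 1e-4,
                            max_shift = 5) {
  u <- seq(-r, r)
  g <- as.matrix(expand.grid(dx = u, dy = u))
  Tv <- as.vector(tmpl)
  A <- diag(2)
  c0 <- col; r0 <- row
  for (it in seq_len(max_iter)) {
    pts <- g %*% t(A)
    xs <- col + pts[, 1]; ys <- row + pts[, 2]
    P <- bilinear_sample(img, xs, ys)
    gx <- bilinear_sample(img, xs + 0.5, ys) - bilinear_sample(img, xs - 0.5, ys)
    gy <- bilinear_sample(img, xs, ys + 0.5) - bilinear_sample(img, xs, ys - 0.5)
    e <- Tv - P
    # parameters: da11, da12, da21, da22, dcol, drow
    J <- cbind(gx * g[, 1], gx * g[, 2], gy * g[, 1], gy * g[, 2], gx, gy)
    H <- crossprod(J)
    rhs <- crossprod(J, e)
    dp <- tryCatch(solve(H, rhs), error = function(e2) NULL)
    if (is.null(dp)) return(NULL)
    A <- A + matrix(dp[1:4], 2, 2, byrow = TRUE)
    col <- col + dp[5]; row <- row + dp[6]
    if ((col - c0)^2 + (row - r0)^2 > max_shift^2) return(NULL)
    if (abs(det(A) - 1) > 0.6) return(NULL)  # degenerate warp
    if (sqrt(sum(dp[5:6]^2)) < tol && max(abs(dp[1:4])) < tol / r) break
  }
  pts <- g %*% t(A)
  P <- matrix(bilinear_sample(img, col + pts[, 1], row + pts[, 2]),
              2 * r + 1, 2 * r + 1)
  list(col = col, row = row, warp = A, ncc = ncc(P, tmpl))
}

# Iterative translation-only Lucas-Kanade alignment of `img` to template
# `tmpl` starting at (col, row); returns refined position and NCC.
lk_align <- function(img, tmpl, col, row, r, max_iter = 20, tol = 1e-3,
                     max_shift = 5) {
  u <- seq(-r, r)
  g <- expand.grid(dx = u, dy = u)
  c0 <- col; r0 <- row
  for (it in seq_len(max_iter)) {
    xs <- col + g$dx; ys <- row + g$dy
    P <- bilinear_sample(img, xs, ys)
    gx <- (bilinear_sample(img, xs + 0.5, ys) - bilinear_sample(img, xs - 0.5, ys))
    gy <- (bilinear_sample(img, xs, ys + 0.5) - bilinear_sample(img, xs, ys - 0.5))
    e <- as.vector(tmpl) - P
    H <- matrix(c(sum(gx * gx), sum(gx * gy), sum(gx * gy), sum(gy * gy)), 2, 2)
    if (abs(det(H)) < 1e-12) return(NULL)
    d <- solve(H, c(sum(gx * e), sum(gy * e)))
    col <- col + d[1]; row <- row + d[2]
    if ((col - c0)^2 + (row - r0)^2 > max_shift^2) return(NULL)
    if (sqrt(sum(d^2)) < tol) break
  }
  P <- matrix(bilinear_sample(img, col + g$dx, row + g$dy), 2 * r + 1, 2 * r + 1)
  list(col = col, row = row, ncc = ncc(P, tmpl))
}

#' Triangulate matches into a quasi-dense point cloud
#'
#' Matches with non-positive disparity are dropped with a warning; surviving
#' points keep their match stage as provenance.
#'
#' @param matches Match tibble.
#' @param rect A `rectified_rig`.
#' @return Point-cloud tibble: `id` (left feature id), `col_L`, `row_L`,
#'   `col_R`, `row_R`, `x`, `y`, `z` (mm, left camera frame), `stage`.
#' @export
reconstruct_cloud <- function(matches, rect) {
  if (!nrow(matches)) {
    return(as_point_cloud(tibble(
      id = integer(), col_L = numeric(), row_L = numeric(),
      col_R = numeric(), row_R = numeric(),
      x = numeric(), y = numeric(), z = numeric(), stage = character())))
  }
  d <- matches$col_L - matches$col_R
  bad <- d <= 0
  if (any(bad)) {
    warn(sprintf("dropping %d match(es) with non-positive disparity", sum(bad)))
    matches <- matches[!bad, ]
  }
  tr <- triangulate_points(
    matches[, c("col_L", "row_L", "col_R", "row_R")], rect
  )
  as_point_cloud(tibble(
    id = matches$left_id,
    col_L = matches$col_L, row_L = matches$row_L,
    col_R = matches$col_R, row_R = matches$row_R,
    x = tr$x, y = tr$y, z = tr$z, stage = matches$stage))
}
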