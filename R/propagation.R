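# Normal-gated affine propagation of stereo matches.
#
# A seed match defines an affine map between the left and right image
# neighborhoods: with M_L, M_R the transforms normalizing the seed ellipses to
# unit circles and R the relative orientation of the normalized patches, a
# candidate left feature f_L lying within a seed's region is transferred to
# the right image at
#   f_R = M_R^{-1} R M_L (f_L - f_L^seed) + f_R^seed.
# The anchor is the nearest admissible seed; the linear part is averaged over
# the nearest few seed maps, which suppresses the shape noise of individual
# detections while preserving the local affine model.  A candidate is
# admissible for a seed when it lies inside the (inflated) seed ellipse and
# the surface normals at candidate and seed agree within the gate; the
# transferred match is kept only when the appearance similarity at the
# predicted location is high enough.

#' Propagate matches to unmatched candidate features
#'
#' @param seeds Match tibble (global and local stages).
#' @param candidates Feature tibble of unmatched left-image features.
#' @param img_L,img_R Rectified images.
#' @param normals A `surface_normal_map` for the left image (see
#'   [estimate_normals()]).
#' @param config A [match_config()].
#' @param n_average Number of nearest seed maps averaged for the linear part.
#' @return Match tibble of propagated matches (`stage = "propagated"`).
#' @export
propagate_matches <- function(seeds, candidates, img_L, img_R, normals,
                              config = match_config(), n_average = 5) {
  out <- empty_matches()
  if (!nrow(seeds) || !nrow(candidates)) return(out)
  n_seed <- normals_at(normals, seeds$col_L, seeds$row_L)
  n_cand <- normals_at(normals, candidates$col, candidates$row)

  affs <- lapply(seq_len(nrow(seeds)), function(s) {
    seed_affine(seeds$shape_L[[s]], seeds$shape_R[[s]],
                seeds$patch_L[[s]], seeds$patch_R[[s]])
  })
  singular <- vapply(affs, is.null, FALSE)
  if (any(singular)) {
    warn(sprintf("%d seed(s) with singular normalizing transform skipped",
                 sum(singular)))
  }

  # inverse Mahalanobis gating of candidates against every seed ellipse
  Q <- lapply(seq_len(nrow(seeds)), function(s) {
    solve(matrix(seeds$shape_L[[s]][c(1, 2, 2, 3)], 2, 2))
  })

  rows <- list()
  for (ci in seq_len(nrow(candidates))) {
    dx <- candidates$col[ci] - seeds$col_L
    dy <- candidates$row[ci] - seeds$row_L
    maha <- vapply(seq_len(nrow(seeds)), function(s) {
      Q[[s]][1, 1] * dx[s]^2 + 2 * Q[[s]][1, 2] * dx[s] * dy[s] +
        Q[[s]][2, 2] * dy[s]^2
    }, 0)
    ang <- normal_angle_deg(matrix(n_cand[ci, ], nrow(seeds), 3, byrow = TRUE),
                            n_seed)
    ok <- !singular & maha <= config$seed_area_scale^2 &
      ang < config$normal_gate_deg
    if (!any(ok)) next
    d2 <- dx^2 + dy^2
    d2[!ok] <- Inf
    anchor <- which.min(d2)
    nb <- order(d2)[seq_len(min(n_average, sum(ok)))]
    A <- Reduce(`+`, affs[nb]) / length(nb)
    pred <- A %*% c(dx[anchor], dy[anchor]) +
      c(seeds$col_R[anchor], seeds$row_R[anchor])
    col_R <- pred[1]; row_R <- pred[2]
    if (abs(row_R - candidates$row[ci]) > config$epipolar_tolerance) next
    if (col_R < 0 || col_R > ncol(img_R) - 1 ||
        row_R < 0 || row_R > nrow(img_R) - 1) next
    shc <- matrix(c(candidates$s11[ci], candidates$s12[ci],
                    candidates$s12[ci], candidates$s22[ci]), 2, 2)
    shp <- A %*% shc %*% t(A)
    patch_R <- sample_ellipse_patch(img_R, c(col_R, row_R), shp,
                                    nrow(candidates$patch[[ci]]))
    if (mean(patch_R < 0.08) > 0.15) next  # lands on a dark occluder
    Asim <- appearance_similarity(candidates$patch[[ci]], patch_R)
    if (Asim < config$propagation_threshold) next
    rows[[length(rows) + 1]] <- tibble(
      left_id = candidates$id[ci], right_id = NA_integer_,
      col_L = candidates$col[ci], row_L = candidates$row[ci],
      col_R = col_R, row_R = row_R,
      M = NA_real_, A = Asim, stage = "propagated",
      c_L = candidates$c[ci], c_R = NA_real_,
      shape_L = list(c(shc[1, 1], shc[1, 2], shc[2, 2])),
      shape_R = list(c(shp[1, 1], shp[1, 2], shp[2, 2])),
      patch_L = list(candidates$patch[[ci]]), patch_R = list(patch_R)
    )
  }
  if (!length(rows)) return(out)
  dplyr::bind_rows(rows)
}

# Affine map M_R^{-1} R M_L for a seed: M_* are inverse square roots of the
# ellipse shapes; R rotates by the difference of the normalized patches'
# dominant gradient orientations, shrunk by the orientation coherence of both
# patches (nearly isotropic patches carry no reliable orientation, and for a
# small-baseline rig the true relative orientation is close to zero).
# NULL when a normalizing transform is singular.
seed_affine <- function(shape_L, shape_R, patch_L, patch_R) {
  SL <- matrix(shape_L[c(1, 2, 2, 3)], 2, 2)
  SR <- matrix(shape_R[c(1, 2, 2, 3)], 2, 2)
  if (det(SL) < 1e-12 || det(SR) < 1e-12) return(NULL)
  ML <- solve(shape_sqrt(SL[1, 1], SL[1, 2], SL[2, 2]))
  MRi <- shape_sqrt(SR[1, 1], SR[1, 2], SR[2, 2])
  oL <- patch_orientation(patch_L)
  oR <- patch_orientation(patch_R)
  dth <- oR[1] - oL[1]
  dth <- atan2(sin(2 * dth), cos(2 * dth)) / 2  # wrap to (-pi/2, pi/2]
  th <- dth * (oL[2] * oR[2])^2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  MRi %*% R %*% ML
}

# Dominant gradient orientation of a patch (radians) and its coherence in
# [0, 1], from the structure tensor.
patch_orientation <- function(patch) {
  if (is.null(patch)) return(c(0, 0))
  n <- nrow(patch)
  gx <- patch[, c(2:n, n)] - patch[, c(1, 1:(n - 1))]
  gy <- patch[c(2:n, n), ] - patch[c(1, 1:(n - 1)), ]
  jxx <- sum(gx * gx); jyy <- sum(gy * gy); jxy <- sum(gx * gy)
  if (jxx + jyy <= 0) return(c(0, 0))
  th <- 0.5 * atan2(2 * jxy, jxx - jyy)
  coh <- sqrt((jxx - jyy)^2 + 4 * jxy^2) / (jxx + jyy)
  c(th, coh)
}

# Sample an elliptical region (center px, SPD shape) onto an n x n grid.
sample_ellipse_patch <- function(image, center, shape, n = 21) {
  A <- shape_sqrt(shape[1, 1], shape[1, 2], shape[2, 2])
  u <- seq(-1, 1, length.out = n)
  g <- as.matrix(expand.grid(ux = u, uy = u))
  pts <- g %*% t(A)
  matrix(bilinear_sample(image, center[1] + pts[, 1], center[2] + pts[, 2]), n, n)
}
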