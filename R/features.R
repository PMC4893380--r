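# Affine-covariant salient region detection and appearance scoring.
#
# The detector is an affine-adapted, scale-normalized determinant-of-Hessian
# blob detector.  Each feature carries a sub-pixel location, a positive
# saliency strength c (the scale-normalized detector response), an elliptical
# region described by a 2x2 SPD shape matrix (px^2; the region is
# {u : (u - x)' S^{-1} (u - x) <= 1}), and a patch resampled from the ellipse
# onto a fixed 21x21 normalized grid.

#' Detect affine-covariant elliptical salient regions
#'
#' Multi-scale determinant-of-Hessian extrema with sub-pixel refinement.  The
#' elliptical shape is adapted from the local second-moment matrix, scaled so
#' the ellipse area matches the detection scale.  Output is sorted by
#' descending saliency and thinned so no two centers are closer than
#' `min_separation`.
#'
#' @param image Grayscale matrix (values in \[0, 1\]).
#' @param threshold Minimum scale-normalized response (absolute units).
#' @param scales Detection scales (Gaussian sigma, px).
#' @param min_separation Minimum distance between feature centers (px).
#' @param max_features Keep at most this many strongest features.
#' @param ellipse_scale Ellipse semi-axis scale relative to detection sigma.
#' @param max_anisotropy Cap on the ellipse axis ratio.
#' @param patch_size Side of the normalized patch grid.
#' @param border Margin (px) inside which detections are discarded.
#' @param dark_threshold,max_dark_fraction A feature whose elliptical support
#'   contains more than `max_dark_fraction` of samples darker than
#'   `dark_threshold` is discarded: such regions lie on (or straddle the
#'   silhouette of) a dark occluder such as an instrument, and their apparent
#'   image structure does not belong to the tissue surface.
#' @return Tibble with columns `id`, `col`, `row`, `c`, `sigma`, `s11`, `s12`,
#'   `s22` (shape matrix entries) and list-column `patch`.
#' @export
detect_regions <- function(image, threshold = 5e-4,
                           scales = 2^seq(0.7, 2.7, by = 0.4),
                           min_separation = 4, max_features = 1500,
                           ellipse_scale = 2, max_anisotropy = 4,
                           patch_size = 21, border = 6,
                           dark_threshold = 0.08, max_dark_fraction = 0.15) {
  image <- as_gray(image)
  h <- nrow(image); w <- ncol(image)
  if (diff(range(image)) <= .Machine$double.eps) return(empty_features())

  ns <- length(scales)
  resp <- vector("list", ns)
  for (k in seq_len(ns)) {
    s <- scales[k]
    L <- gauss_blur(image, s)
    g <- image_gradient(L)
    gxx <- image_gradient(g$gx)
    gyy <- image_gradient(g$gy)
    resp[[k]] <- s^4 * (gxx$gx * gyy$gy - gxx$gy^2)  # det of the Hessian
  }

  cand <- list()
  for (k in seq_len(ns)) {
    r <- resp[[k]]
    mx <- local_maxima(r, threshold)
    if (!nrow(mx)) next
    # enforce scale extremum against neighboring scales at the same pixel
    keep <- rep(TRUE, nrow(mx))
    v <- r[mx]
    if (k > 1) keep <- keep & v >= resp[[k - 1]][mx]
    if (k < ns) keep <- keep & v >= resp[[k + 1]][mx]
    mx <- mx[keep, , drop = FALSE]
    if (!nrow(mx)) next
    cand[[length(cand) + 1]] <- data.frame(
      ri = mx[, 1], ci = mx[, 2], k = k, c = r[mx]
    )
  }
  if (!length(cand)) return(empty_features())
  cand <- do.call(rbind, cand)
  cand <- cand[cand$ri > border & cand$ri <= h - border &
               cand$ci > border & cand$ci <= w - border, , drop = FALSE]
  if (!nrow(cand)) return(empty_features())

  # sub-pixel refinement by quadratic fit on the 3x3 response neighborhood
  off <- t(vapply(seq_len(nrow(cand)), function(i) {
    quad_refine(resp[[cand$k[i]]], cand$ri[i], cand$ci[i])
  }, numeric(2)))
  col <- cand$ci - 1 + off[, 2]
  row <- cand$ri - 1 + off[, 1]

  ord <- order(-cand$c, col, row)
  cand <- cand[ord, , drop = FALSE]
  col <- col[ord]; row <- row[ord]

  keep <- nms_separation(col, row, min_separation)
  cand <- cand[keep, , drop = FALSE]
  col <- col[keep]; row <- row[keep]
  if (nrow(cand) > max_features) {
    cand <- cand[seq_len(max_features), , drop = FALSE]
    col <- col[seq_len(max_features)]; row <- row[seq_len(max_features)]
  }

  # affine adaptation from the second-moment matrix at the detection scale
  g1 <- image_gradient(gauss_blur(image, 1))
  mxx <- list(); myy <- list(); mxy <- list()
  for (k in sort(unique(cand$k))) {
    si <- 1.4 * scales[k]
    mxx[[k]] <- gauss_blur(g1$gx * g1$gx, si)
    myy[[k]] <- gauss_blur(g1$gy * g1$gy, si)
    mxy[[k]] <- gauss_blur(g1$gx * g1$gy, si)
  }
  n <- nrow(cand)
  S <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    k <- cand$k[i]
    idx <- cbind(cand$ri[i], cand$ci[i])
    mu <- matrix(c(mxx[[k]][idx], mxy[[k]][idx], mxy[[k]][idx], myy[[k]][idx]), 2, 2)
    S[i, ] <- shape_from_moment(mu, ellipse_scale * scales[k], max_anisotropy)
  }

  feats <- tibble(
    id = seq_len(n), col = col, row = row, c = cand$c,
    sigma = scales[cand$k], s11 = S[, 1], s12 = S[, 2], s22 = S[, 3]
  )
  feats$patch <- extract_patches(image, feats, patch_size)
  dark <- vapply(feats$patch, function(p) mean(p < dark_threshold), 0)
  feats <- feats[dark <= max_dark_fraction, ]
  feats$id <- seq_len(nrow(feats))
  feats
}

empty_features <- function() {
  tibble(id = integer(), col = numeric(), row = numeric(), c = numeric(),
         sigma = numeric(), s11 = numeric(), s12 = numeric(), s22 = numeric(),
         patch = list())
}

# Interior local maxima of r above `threshold`, returned as (row, col) index
# matrix (1-based).
local_maxima <- function(r, threshold) {
  h <- nrow(r); w <- ncol(r)
  ctr <- r[2:(h - 1), 2:(w - 1)]
  is_max <- ctr > threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & ctr >= r[2:(h - 1) + dr, 2:(w - 1) + dc]
  }
  which(rbind(FALSE, cbind(FALSE, is_max, FALSE), FALSE), arr.ind = TRUE)
}

# Sub-pixel offset (drow, dcol) from a 2D quadratic fit, clipped to [-1, 1].
quad_refine <- function(r, ri, ci) {
  if (ri < 2 || ci < 2 || ri > nrow(r) - 1 || ci > ncol(r) - 1) return(c(0, 0))
  nb <- r[(ri - 1):(ri + 1), (ci - 1):(ci + 1)]
  gy <- (nb[3, 2] - nb[1, 2]) / 2
  gx <- (nb[2, 3] - nb[2, 1]) / 2
  hyy <- nb[3, 2] - 2 * nb[2, 2] + nb[1, 2]
  hxx <- nb[2, 3] - 2 * nb[2, 2] + nb[2, 1]
  hxy <- (nb[3, 3] - nb[3, 1] - nb[1, 3] + nb[1, 1]) / 4
  det <- hxx * hyy - hxy^2
  if (abs(det) < 1e-12) return(c(0, 0))
  d <- -solve(matrix(c(hyy, hxy, hxy, hxx), 2, 2), c(gy, gx))
  pmin(pmax(d, -1), 1)
}

# Greedy distance-based non-maximum suppression; input must be sorted by
# descending strength.  Returns logical keep mask.
nms_separation <- function(col, row, min_sep) {
  n <- length(col)
  keep <- logical(n)
  kc <- numeric(0); kr <- numeric(0)
  min2 <- min_sep^2
  for (i in seq_len(n)) {
    if (!length(kc) || min((kc - col[i])^2 + (kr - row[i])^2) >= min2) {
      keep[i] <- TRUE
      kc <- c(kc, col[i]); kr <- c(kr, row[i])
    }
  }
  keep
}

# Ellipse shape matrix (s11, s12, s22) from a second-moment matrix mu: axes
# along mu's eigenvectors, anisotropy sqrt of the eigenvalue ratio (capped),
# area fixed to a circle of radius `radius`.
shape_from_moment <- function(mu, radius, max_anisotropy) {
  if (!all(is.finite(mu)) || mu[1, 1] + mu[2, 2] <= 1e-12) {
    return(c(radius^2, 0, radius^2))
  }
  e <- eigen(mu, symmetric = TRUE)
  ev <- pmax(e$values, max(e$values) * 1e-6)
  ax <- sqrt(sqrt(ev[2] / ev[1]))  # longer axis along the weaker-gradient direction
  ax <- min(ax, sqrt(max_anisotropy))
  a <- radius * ax; b <- radius / ax
  V <- e$vectors
  Sm <- V %*% diag(c(b^2, a^2)) %*% t(V)
  c(Sm[1, 1], Sm[1, 2], Sm[2, 2])
}

# ---- patches ----------------------------------------------------------------

# Matrix square root of a 2x2 SPD shape matrix: A with A A' = S.  A maps the
# unit circle onto the ellipse.
shape_sqrt <- function(s11, s12, s22) {
  Sm <- matrix(c(s11, s12, s12, s22), 2, 2)
  e <- eigen(Sm, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 1e-12))) %*% t(e$vectors)
}

# Resample the elliptical support of each feature onto an n x n normalized
# grid (the unit square [-1,1]^2 mapped through the ellipse's sqrt).
extract_patches <- function(image, feats, n = 21) {
  u <- seq(-1, 1, length.out = n)
  grid <- as.matrix(expand.grid(ux = u, uy = u))
  lapply(seq_len(nrow(feats)), function(i) {
    A <- shape_sqrt(feats$s11[i], feats$s12[i], feats$s22[i])
    pts <- grid %*% t(A)
    vals <- bilinear_sample(image, feats$col[i] + pts[, 1], feats$row[i] + pts[, 2])
    matrix(vals, n, n)
  })
}

#' Appearance similarity of two patches
#'
#' Each patch is histogram-equalized on its own intensity range (256 bins) and
#' the normalized cross-correlation of the equalized patches is returned.
#' A zero-variance patch yields 0 (unmatchable).
#'
#' @param patch_a,patch_b Numeric matrices on a common grid.
#' @return Scalar in \[-1, 1\].
#' @export
appearance_similarity <- function(patch_a, patch_b) {
  stopifnot(all(dim(patch_a) == dim(patch_b)))
  ncc(hist_equalize(patch_a), hist_equalize(patch_b))
}
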