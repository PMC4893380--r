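# 3D thin-plate splines with the biharmonic kernel U(r) = r.
#
# The warp f(u) = a0 + A u + sum_k w_k U(||u - c_k||) is fitted per output
# dimension by solving the bordered system
#   [ K + lambda I   P ] [ w ]   [ y ]
#   [ P'             0 ] [ a ] = [ 0 ],
# with P = [1 | source] and the side conditions P' w = 0 (weights orthogonal
# to the affine monomials).  With lambda = 0 the warp interpolates the
# control points exactly.

#' Fit a 3D thin-plate-spline warp
#'
#' @param control_source,control_target n x 3 matrices (or data frames with
#'   columns `x`, `y`, `z`) of corresponding control points (mm).
#' @param lambda Regularization weight (>= 0); 0 gives pure interpolation.
#' @return A `tps_warp` object.
#' @export
fit_tps <- function(control_source, control_target, lambda = 0) {
  S <- as_xyz_matrix(control_source)
  Tg <- as_xyz_matrix(control_target)
  stopifnot(nrow(S) == nrow(Tg), lambda >= 0)
  n <- nrow(S)
  if (n < 4) {
    abort("need at least 4 control points for the affine part",
          class = "tissuedeform_degenerate")
  }
  P <- cbind(1, S)
  if (qr(P)$rank < 4) {
    abort("degenerate control-point configuration (coplanar or collinear)",
          class = "tissuedeform_degenerate")
  }
  K <- pairwise_dist(S, S) + lambda * diag(n)
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(Tg, matrix(0, 4, 3))
  sol <- tryCatch(solve(M, rhs), error = function(e) {
    abort("rank-deficient TPS system", class = "tissuedeform_degenerate")
  })
  sol <- sol + solve(M, rhs - M %*% sol)  # one step of iterative refinement
  structure(
    list(centers = S, weights = sol[seq_len(n), , drop = FALSE],
         affine = sol[n + 1:4, , drop = FALSE], lambda = lambda),
    class = "tps_warp"
  )
}

as_xyz_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("x", "y", "z")])
  storage.mode(x) <- "double"
  stopifnot(ncol(x) == 3)
  unname(x)
}

pairwise_dist <- function(A, B) {
  # coordinate-difference form: the expanded sum-of-squares identity loses
  # precision when coordinates are large relative to the separations
  sqrt(outer(A[, 1], B[, 1], "-")^2 +
       outer(A[, 2], B[, 2], "-")^2 +
       outer(A[, 3], B[, 3], "-")^2)
}

#' Apply a TPS warp to points
#'
#' @param object A `tps_warp`.
#' @param newdata n x 3 matrix or data frame with `x`, `y`, `z` (mm).
#' @param ... Unused.
#' @return Tibble with warped `x`, `y`, `z`.
#' @export
predict.tps_warp <- function(object, newdata, ...) {
  X <- as_xyz_matrix(newdata)
  U <- pairwise_dist(X, object$centers)
  Y <- cbind(1, X) %*% object$affine + U %*% object$weights
  tibble(x = Y[, 1], y = Y[, 2], z = Y[, 3])
}

#' @export
print.tps_warp <- function(x, ...) {
  cat("<tps_warp> ", nrow(x$centers), " control points, lambda ",
      format(x$lambda, digits = 3), ", max |side condition| ",
      format(max(abs(crossprod(cbind(1, x$centers), x$weights))), digits = 3),
      "\n", sep = "")
  invisible(x)
}
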