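# Elliptical region geometry: areas and intersection-over-union.
#
# An ellipse is {u : (u - center)' S^{-1} (u - center) <= 1} with S a 2x2 SPD
# shape matrix (px^2).

#' Construct an ellipse
#'
#' @param center Numeric (col, row) in px.
#' @param shape 2x2 SPD shape matrix (px^2), or the triple (s11, s12, s22).
#' @return An `ellipse` list with `center` and `shape`.
#' @export
ellipse <- function(center, shape) {
  if (!is.matrix(shape)) shape <- matrix(shape[c(1, 2, 2, 3)], 2, 2)
  if (!isTRUE(all.equal(shape, t(shape))) || any(eigen(shape, symmetric = TRUE,
                                                       only.values = TRUE)$values <= 0)) {
    abort("ellipse shape matrix must be SPD", class = "tissuedeform_invalid_feature")
  }
  structure(list(center = as.numeric(center), shape = shape), class = "ellipse")
}

ellipse_area <- function(e) pi * sqrt(det(e$shape))

# Half-width of the ellipse's y-interval at horizontal offset dx from the
# center, via the quadratic in dy; returns the interval or NULL.
ellipse_y_interval <- function(e, x) {
  Q <- solve(e$shape)
  dx <- x - e$center[1]
  disc <- (Q[1, 2] * dx)^2 - Q[2, 2] * (Q[1, 1] * dx^2 - 1)
  lo <- hi <- numeric(length(x))
  ok <- disc >= 0
  sq <- sqrt(pmax(disc, 0))
  mid <- e$center[2] - Q[1, 2] * dx / Q[2, 2]
  lo <- mid - sq / Q[2, 2]
  hi <- mid + sq / Q[2, 2]
  list(lo = lo, hi = hi, ok = ok)
}

#' Intersection-over-union of two elliptical regions
#'
#' The intersection area is computed by slicing both ellipses along x and
#' integrating the overlap of their y-intervals (trapezoidal rule on a fine
#' grid); areas are exact (`pi * sqrt(det S)`).
#'
#' @param e_i,e_j [ellipse()] objects.
#' @param n Number of integration slices.
#' @return Scalar overlap ratio in \[0, 1\]; symmetric in its arguments.
#' @export
ellipse_overlap <- function(e_i, e_j, n = 1024) {
  stopifnot(inherits(e_i, "ellipse"), inherits(e_j, "ellipse"))
  if (max(abs(e_i$center - e_j$center)) < 1e-12 &&
      max(abs(e_i$shape - e_j$shape)) < 1e-12 * max(abs(e_i$shape))) {
    return(1)
  }
  ai <- ellipse_area(e_i); aj <- ellipse_area(e_j)
  inter <- ellipse_intersection_area(e_i, e_j, n)
  if (inter <= 0) return(0)
  ratio <- inter / (ai + aj - inter)
  min(max(ratio, 0), 1)
}

ellipse_intersection_area <- function(e_i, e_j, n = 1024) {
  hw <- function(e) sqrt(e$shape[1, 1])
  x_lo <- max(e_i$center[1] - hw(e_i), e_j$center[1] - hw(e_j))
  x_hi <- min(e_i$center[1] + hw(e_i), e_j$center[1] + hw(e_j))
  if (x_hi <= x_lo) return(0)
  # Chebyshev-distributed slices absorb the sqrt singularity at the ends of
  # the overlap interval.
  th <- seq(0, pi, length.out = n)
  mid <- (x_lo + x_hi) / 2; half <- (x_hi - x_lo) / 2
  x <- mid - half * cos(th)
  yi <- ellipse_y_interval(e_i, x)
  yj <- ellipse_y_interval(e_j, x)
  ok <- yi$ok & yj$ok
  ov <- pmax(0, pmin(yi$hi, yj$hi) - pmax(yi$lo, yj$lo))
  ov[!ok] <- 0
  w <- half * sin(th)  # dx = half * sin(theta) dtheta
  f <- ov * w
  sum((f[-1] + f[-n]) / 2) * pi / (n - 1)
}
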