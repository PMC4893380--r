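# Image utilities.
#
# Images are numeric matrices with nrow = image height and ncol = image width,
# intensities in [0, 1].  Pixel coordinates are 0-based (col, row) with
# sub-pixel floats: pixel (0, 0) is the centre of the top-left sample.

#' Read an image as a grayscale intensity matrix
#'
#' RGB(A) images are converted to luma (Rec. 709 weights).
#'
#' @param path Path to a PNG file.
#' @return Numeric matrix (height x width) with intensities in \[0, 1\].
#' @export
read_image <- function(path) {
  arr <- png::readPNG(path)
  as_gray(arr)
}

#' Write an intensity matrix as an 8-bit grayscale PNG
#'
#' @param image Numeric matrix; values are clamped to \[0, 1\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  img <- pmin(pmax(image, 0), 1)
  png::writePNG(img, path)
  invisible(path)
}

#' Convert an image array to a grayscale matrix
#'
#' @param image Matrix or 3-d array (height x width x channels).
#' @return Numeric matrix in \[0, 1\].
#' @export
as_gray <- function(image) {
  if (is.matrix(image)) return(image)
  if (length(dim(image)) == 3) {
    nc <- dim(image)[3]
    if (nc >= 3) {
      return(0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3])
    }
    return(image[, , 1])
  }
  abort("cannot interpret image array", class = "tissuedeform_invalid_image")
}

# Bilinear interpolation at 0-based (col, row) positions, vectorized.
# Out-of-range samples are clamped to the border.
bilinear_sample <- function(image, col, row) {
  h <- nrow(image); w <- ncol(image)
  x <- pmin(pmax(col, 0), w - 1)
  y <- pmin(pmax(row, 0), h - 1)
  x0 <- pmin(floor(x), w - 2); y0 <- pmin(floor(y), h - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- image[cbind(y0 + 1, x0 + 1)]
  i01 <- image[cbind(y0 + 1, x0 + 2)]
  i10 <- image[cbind(y0 + 2, x0 + 1)]
  i11 <- image[cbind(y0 + 2, x0 + 2)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

gaussian_kernel_1d <- function(sigma, max_radius = Inf) {
  r <- max(1L, min(ceiling(3 * sigma), max_radius))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Gaussian blur with replicated borders (separable, via EBImage's filter2).
# The kernel is truncated to fit small images.
gauss_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  kr <- gaussian_kernel_1d(sigma, max_radius = (nrow(image) - 1) %/% 2)
  kc <- gaussian_kernel_1d(sigma, max_radius = (ncol(image) - 1) %/% 2)
  out <- EBImage::filter2(image, matrix(kr, ncol = 1), boundary = "replicate")
  EBImage::filter2(out, matrix(kc, nrow = 1), boundary = "replicate")
}

# Central-difference gradients; gx = d/dcol, gy = d/drow.
image_gradient <- function(image) {
  kx <- matrix(c(0.5, 0, -0.5), nrow = 1)  # filter2 correlates: value at +1 col gets +0.5
  list(
    gx = EBImage::filter2(image, kx, boundary = "replicate"),
    gy = EBImage::filter2(image, t(kx), boundary = "replicate")
  )
}

# Downsample by 2 after anti-alias blur.  A coarse pixel at 0-based coordinate
# u corresponds to fine coordinate 2u.
downsample2 <- function(image) {
  sm <- gauss_blur(image, 1)
  sm[seq(1, nrow(sm), by = 2), seq(1, ncol(sm), by = 2), drop = FALSE]
}

# Image pyramid, finest first.
build_pyramid <- function(image, levels) {
  pyr <- vector("list", levels)
  pyr[[1]] <- image
  for (l in seq_len(levels - 1)) pyr[[l + 1]] <- downsample2(pyr[[l]])
  pyr
}

# Histogram equalization on the patch's own intensity range (256 bins).
# A constant patch is returned unchanged (zero variance is handled by NCC).
hist_equalize <- function(patch, bins = 256) {
  rng <- range(patch)
  if (diff(rng) <= 0) return(patch * 0)
  idx <- pmin(floor((patch - rng[1]) / diff(rng) * bins) + 1, bins)
  cnt <- tabulate(idx, nbins = bins)
  cdf <- cumsum(cnt) / sum(cnt)
  out <- cdf[idx]
  matrix(out, nrow(patch), ncol(patch))
}

# Normalized cross-correlation of two equal-size patches; zero-variance
# patches yield 0 (unmatchable).
ncc <- function(a, b) {
  a <- as.vector(a) - mean(a)
  b <- as.vector(b) - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}
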