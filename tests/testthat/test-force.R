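# Force-displacement calibration, Gaussian indentation inference, force
# readout.

test_that("an exact quadratic is recovered to numerical precision", {
  d <- seq(0, 10, by = 0.5)
  dat <- tibble::tibble(displacement_mm = d, force_N = 0.01 * d^2 + 0.02 * d)
  m <- calibrate_material(dat)
  expect_equal(m$a2, 0.01, tolerance = 1e-10)
  expect_equal(m$a1, 0.02, tolerance = 1e-10)
  expect_equal(m$a0, 0, tolerance = 1e-10)
  expect_equal(m$d_max, 10)
  expect_lt(m$residual_rms, 1e-12)
})

test_that("all-zero forces give a zero model", {
  dat <- tibble::tibble(displacement_mm = seq(0, 5, by = 1), force_N = 0)
  m <- calibrate_material(dat)
  expect_equal(c(m$a2, m$a1, m$a0), c(0, 0, 0), tolerance = 1e-14)
})

test_that("noisy calibration matches a closed-form normal-equations oracle", {
  set.seed(12)
  d <- runif(100, 0, 10)
  f <- 0.012 * d^2 + 0.018 * d + 0.001 + rnorm(100, sd = 0.01)
  m <- calibrate_material(tibble::tibble(displacement_mm = d, force_N = f))
  X <- cbind(1, d, d^2)
  beta <- solve(t(X) %*% X, t(X) %*% f)
  expect_equal(m$a0, beta[1], tolerance = 1e-9)
  expect_equal(m$a1, beta[2], tolerance = 1e-9)
  expect_equal(m$a2, beta[3], tolerance = 1e-9)
})

test_that("fewer than 3 distinct displacements is underdetermined", {
  dat <- tibble::tibble(displacement_mm = c(1, 1, 2, 2), force_N = c(1, 1, 2, 2))
  expect_error(calibrate_material(dat), class = "tissuedeform_underdetermined")
})

test_that("the reported residual bounds the training reproduction error", {
  set.seed(13)
  d <- runif(60, 0, 8)
  f <- 0.01 * d^2 + 0.03 * d + rnorm(60, sd = 0.02)
  m <- calibrate_material(tibble::tibble(displacement_mm = d, force_N = f))
  pred <- evaluate_material(m, d)$force_N
  expect_lte(sqrt(mean((pred - f)^2)), m$residual_rms + 1e-12)
})

test_that("the forced-origin fit pins the intercept at zero", {
  set.seed(14)
  d <- runif(50, 0, 8)
  f <- 0.01 * d^2 + 0.03 * d + rnorm(50, sd = 0.01)
  m <- calibrate_material(tibble::tibble(displacement_mm = d, force_N = f),
                          force_origin = TRUE)
  expect_identical(m$a0, 0)
})

test_that("material model files round-trip and tidy/glance report the fit", {
  m <- calibrate_material(tibble::tibble(displacement_mm = 0:8,
                                         force_N = 0.01 * (0:8)^2))
  path <- withr::local_tempfile(fileext = ".txt")
  write_material_model(m, path)
  m2 <- read_material_model(path)
  expect_equal(m2$a2, m$a2)
  expect_equal(m2$d_max, m$d_max)
  td <- tidy(m)
  expect_equal(td$term, c("a2", "a1", "a0"))
  expect_equal(glance(m)$d_max, 8)
})

gauss_samples <- function(A, sigma, center = c(0, 0), baseline = 0, n = 200,
                          seed = 1, noise = 0, r_max = 20) {
  set.seed(seed)
  r <- sqrt(runif(n)) * r_max
  th <- runif(n, 0, 2 * pi)
  x <- center[1] + r * cos(th); y <- center[2] + r * sin(th)
  D <- A * exp(-((x - center[1])^2 + (y - center[2])^2) / (2 * sigma^2)) +
    baseline + rnorm(n, sd = noise)
  tibble::tibble(x = x, y = y, D = D)
}

test_that("an all-zero displacement field fits a zero-amplitude indentation", {
  s <- gauss_samples(0, 6)
  fit <- fit_indentation(s)
  expect_equal(fit$amplitude, 0)
  expect_equal(fit$peak, 0)
})

test_that("the occluded peak is recovered by extrapolating the Gaussian", {
  s <- gauss_samples(8, 6, seed = 2)
  occ <- list(center = c(0, 0), radius = 4)
  fit <- fit_indentation(s, occlusion = occ)
  expect_lt(abs(fit$amplitude - 8), 0.1)
  expect_lt(sqrt(sum(fit$center^2)), 0.5)
  # the extrapolated peak exceeds every observed (occluded) sample
  kept <- s[(s$x^2 + s$y^2) > 16, ]
  expect_gte(fit$peak, max(kept$D))
})

test_that("parameter recovery holds across random indentation draws", {
  errs <- vapply(1:60, function(i) {
    set.seed(i)
    A <- runif(1, 1, 10); sg <- runif(1, 3, 12)
    s <- gauss_samples(A, sg, seed = i + 1000)
    fit <- fit_indentation(s, occlusion = list(center = c(0, 0), radius = 4))
    abs(fit$amplitude - A)
  }, 0)
  expect_lt(median(errs), 0.1)
})

test_that("too few samples outside the occlusion is an error", {
  s <- gauss_samples(5, 6, n = 8, r_max = 3)
  expect_error(fit_indentation(s, occlusion = list(center = c(0, 0), radius = 4)),
               class = "tissuedeform_underdetermined")
})

test_that("force readout evaluates the polynomial at the Gaussian peak", {
  m <- force_displacement_model(a2 = 0.01, a1 = 0.02, a0 = 0, d_max = 12)
  ind <- gaussian_indentation(amplitude = 5, center = c(0, 0), sigma = 6)
  out <- estimate_force(m, ind)
  expect_equal(out$force_N, 0.35)
  expect_false(out$extrapolated)
  # peak 0 -> intercept
  m2 <- force_displacement_model(a2 = 0.01, a1 = 0.02, a0 = 0.005, d_max = 12)
  expect_equal(estimate_force(m2, 0)$force_N, 0.005)
})

test_that("force readout flags extrapolation and rejects invalid peaks", {
  m <- force_displacement_model(a2 = 0.01, a1 = 0.02, a0 = 0, d_max = 10)
  expect_true(estimate_force(m, 11)$extrapolated)
  expect_error(estimate_force(m, 13), class = "tissuedeform_invalid_input")
  expect_error(estimate_force(m, -1), class = "tissuedeform_invalid_input")
})

test_that("a non-monotone model warns; a monotone model is monotone in the peak", {
  bad <- force_displacement_model(a2 = 0.05, a1 = -0.5, a0 = 2, d_max = 8)
  expect_warning(estimate_force(bad, 3), "not monotone")
  good <- demo_material_model()
  f <- vapply(seq(0, 10, by = 1), function(d) estimate_force(good, d)$force_N, 0)
  expect_true(all(diff(f) >= 0))
})

test_that("closed-loop force from a synthetic Gaussian field is accurate", {
  model <- demo_material_model()
  for (A in c(2, 6, 10)) {
    s <- gauss_samples(A, 6, seed = A, noise = 0)
    fld <- tibble::tibble(x_ref = s$x, y_ref = s$y, D = s$D)
    est <- estimate_force_from_field(fld, model,
                                     occlusion = list(center = c(0, 0), radius = 4))
    truth <- evaluate_material(model, A)$force_N
    expect_lt(abs(est$force_N - truth), 0.05)
  }
})
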