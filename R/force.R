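# Vision-based force estimation: quadratic force-displacement material model,
# Gaussian indentation fitting under tool occlusion, and force readout.

#' Calibrate a force-displacement material model
#'
#' Least-squares fit of the degree-2 polynomial `F = a2 d^2 + a1 d + a0`
#' relating tool-tip surface displacement d (mm) to exerted force F (N);
#' a second-order polynomial provides the best fit for soft-tissue
#' indentation data of this kind.
#'
#' @param data Data frame with columns `displacement_mm` and `force_N`.
#' @param force_origin If `TRUE`, constrain the intercept `a0 = 0`.
#' @return A `force_displacement_model` with coefficients `a2`, `a1`, `a0`,
#'   valid range `[0, d_max]` and residual RMS (N).
#' @export
calibrate_material <- function(data, force_origin = FALSE) {
  d <- data$displacement_mm; f <- data$force_N
  stopifnot(length(d) == length(f), all(is.finite(d)), all(is.finite(f)))
  if (length(unique(d)) < 3) {
    abort("need at least 3 distinct displacement values for a quadratic fit",
          class = "tissuedeform_underdetermined")
  }
  if (force_origin) {
    fit <- lm(f ~ 0 + d + I(d^2))
    a <- c(a0 = 0, a1 = unname(coef(fit)[1]), a2 = unname(coef(fit)[2]))
  } else {
    fit <- lm(f ~ d + I(d^2))
    a <- c(a0 = unname(coef(fit)[1]), a1 = unname(coef(fit)[2]),
           a2 = unname(coef(fit)[3]))
  }
  force_displacement_model(a2 = a[["a2"]], a1 = a[["a1"]], a0 = a[["a0"]],
                           d_max = max(d),
                           residual_rms = sqrt(mean(fit$residuals^2)),
                           n = length(d))
}

#' Construct a force-displacement model from coefficients
#'
#' @param a2,a1,a0 Polynomial coefficients (N/mm^2, N/mm, N).
#' @param d_max Upper end of the calibrated displacement range (mm).
#' @param residual_rms Fit residual RMS (N).
#' @param n Number of calibration samples.
#' @return A `force_displacement_model`.
#' @export
force_displacement_model <- function(a2, a1, a0 = 0, d_max, residual_rms = 0,
                                     n = NA_integer_) {
  stopifnot(is.finite(a2), is.finite(a1), is.finite(a0), d_max > 0)
  structure(list(a2 = a2, a1 = a1, a0 = a0, d_max = d_max,
                 residual_rms = residual_rms, n = n),
            class = "force_displacement_model")
}

#' Demo material model (non-physical)
#'
#' A toy quadratic `F = 0.01 d^2 + 0.02 d` whose scale is consistent with
#' sub-0.3 N forces at few-mm displacements.  It is a stand-in for a real
#' calibration (which must always be measured for the actual material) and is
#' intended for demos and synthetic closed-loop tests only.
#'
#' @param d_max Valid displacement range (mm).
#' @return A `force_displacement_model`.
#' @export
demo_material_model <- function(d_max = 12) {
  force_displacement_model(a2 = 0.01, a1 = 0.02, a0 = 0, d_max = d_max)
}

#' Evaluate a material model at given displacements
#'
#' @param model A `force_displacement_model`.
#' @param displacement_mm Displacements (mm).
#' @return Tibble with `displacement_mm`, `force_N`, `extrapolated`.
#' @export
evaluate_material <- function(model, displacement_mm) {
  stopifnot(inherits(model, "force_displacement_model"))
  tibble(
    displacement_mm = displacement_mm,
    force_N = model$a2 * displacement_mm^2 + model$a1 * displacement_mm + model$a0,
    extrapolated = displacement_mm > model$d_max
  )
}

#' @export
print.force_displacement_model <- function(x, ...) {
  cat(sprintf("<force_displacement_model> F = %.4g d^2 + %.4g d + %.4g (d in [0, %.3g] mm, RMS %.3g N)\n",
              x$a2, x$a1, x$a0, x$d_max, x$residual_rms))
  invisible(x)
}

#' @export
tidy.force_displacement_model <- function(x, ...) {
  tibble(term = c("a2", "a1", "a0"), estimate = c(x$a2, x$a1, x$a0))
}

#' @export
glance.force_displacement_model <- function(x, ...) {
  tibble(residual_rms = x$residual_rms, d_max = x$d_max, n = x$n)
}

#' Read / write a material model file
#'
#' Key/value text layout: `a2`, `a1`, `a0`, `d_max`, `residual_rms`.
#'
#' @param path File path.
#' @return `read_material_model` returns a `force_displacement_model`.
#' @export
read_material_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "\\s+")
  vals <- setNames(vapply(kv, function(x) as.numeric(x[2]), 0),
                   vapply(kv, `[[`, "", 1))
  force_displacement_model(a2 = vals[["a2"]], a1 = vals[["a1"]], a0 = vals[["a0"]],
                           d_max = vals[["d_max"]],
                           residual_rms = vals[["residual_rms"]])
}

#' @param model A `force_displacement_model`.
#' @rdname read_material_model
#' @export
write_material_model <- function(model, path) {
  writeLines(c(
    "# tissuedeform material model: F = a2 d^2 + a1 d + a0 (d mm, F N)",
    sprintf("a2 %.17g", model$a2), sprintf("a1 %.17g", model$a1),
    sprintf("a0 %.17g", model$a0), sprintf("d_max %.17g", model$d_max),
    sprintf("residual_rms %.17g", model$residual_rms)
  ), path)
  invisible(path)
}

# ---- Gaussian indentation ---------------------------------------------------

#' Fit a Gaussian indentation to a displacement field
#'
#' Models the surface displacement magnitude around the tool as an isotropic
#' Gaussian over lateral surface coordinates,
#' `D(u) = A exp(-||u - center||^2 / (2 sigma^2)) + baseline`, and fits it by
#' nonlinear least squares.  Because the tool occludes the contact point,
#' samples inside `occlusion` are discarded and the peak displacement
#' (`A + baseline`) is an extrapolation of the fitted model.
#'
#' @param samples Data frame with lateral surface coordinates `x`, `y` (mm)
#'   and displacement magnitude `D` (mm).
#' @param occlusion Optional list with `center` (x, y mm) and `radius` (mm):
#'   samples inside this disk (the tool footprint) are excluded.
#' @param baseline If `FALSE`, fix the baseline offset to 0.
#' @return A `gaussian_indentation` with `amplitude`, `center`, `sigma`,
#'   `baseline`, `peak` and fit diagnostics.
#' @export
fit_indentation <- function(samples, occlusion = NULL, baseline = TRUE) {
  s <- as_tibble(samples)
  stopifnot(all(c("x", "y", "D") %in% names(s)))
  if (!is.null(occlusion)) {
    keep <- (s$x - occlusion$center[1])^2 + (s$y - occlusion$center[2])^2 >
      occlusion$radius^2
    s <- s[keep, ]
  }
  if (nrow(s) < 5) {
    abort("need at least 5 samples outside the occluded region",
          class = "tissuedeform_underdetermined")
  }
  if (all(abs(s$D) < 1e-12)) {
    return(gaussian_indentation(amplitude = 0, center = c(mean(s$x), mean(s$y)),
                                sigma = 1, baseline = 0, rss = 0, n = nrow(s)))
  }
  b0 <- if (baseline) min(s$D) else 0
  wgt <- pmax(s$D - b0, 0)
  if (sum(wgt) <= 0) wgt <- rep(1, nrow(s))
  cx0 <- sum(s$x * wgt) / sum(wgt)
  cy0 <- sum(s$y * wgt) / sum(wgt)
  s2 <- sum(((s$x - cx0)^2 + (s$y - cy0)^2) * wgt) / sum(wgt)
  start <- list(A = max(s$D) - b0, cx = cx0, cy = cy0,
                sg = sqrt(max(s2 / 2, 0.25)), b = b0)
  lower <- c(A = 0, cx = -Inf, cy = -Inf, sg = 1e-2, b = -Inf)
  if (!baseline) {
    start$b <- NULL
    lower <- lower[names(lower) != "b"]
  }
  resid_fn <- function(par) {
    b <- if (baseline) par[["b"]] else 0
    par[["A"]] * exp(-((s$x - par[["cx"]])^2 + (s$y - par[["cy"]])^2) /
                       (2 * par[["sg"]]^2)) + b - s$D
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = unlist(start), fn = resid_fn, lower = lower,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      abort(paste0("Gaussian indentation fit did not converge: ",
                   conditionMessage(e)),
            class = "tissuedeform_fit_error")
    }
  )
  if (fit$info < 1 || fit$info > 4) {
    abort(sprintf("Gaussian indentation fit did not converge (nls.lm info %d: %s)",
                  fit$info, fit$message),
          class = "tissuedeform_fit_error")
  }
  cf <- fit$par
  gaussian_indentation(
    amplitude = unname(cf[["A"]]), center = unname(c(cf[["cx"]], cf[["cy"]])),
    sigma = unname(cf[["sg"]]), baseline = if (baseline) unname(cf[["b"]]) else 0,
    rss = sum(fit$fvec^2), n = nrow(s)
  )
}

#' Construct a Gaussian indentation description
#'
#' @param amplitude Gaussian amplitude A (mm), >= 0.
#' @param center Lateral center (x, y) in mm.
#' @param sigma Width (mm), > 0.
#' @param baseline Offset (mm).
#' @param rss,n Fit diagnostics.
#' @return A `gaussian_indentation`.
#' @export
gaussian_indentation <- function(amplitude, center, sigma, baseline = 0,
                                 rss = NA_real_, n = NA_integer_) {
  stopifnot(amplitude >= 0, sigma > 0)
  structure(list(amplitude = amplitude, center = as.numeric(center),
                 sigma = sigma, baseline = baseline,
                 peak = amplitude + baseline, rss = rss, n = n),
            class = "gaussian_indentation")
}

#' @export
print.gaussian_indentation <- function(x, ...) {
  cat(sprintf("<gaussian_indentation> peak %.3g mm (A %.3g, baseline %.3g), sigma %.3g mm, center (%.3g, %.3g) mm\n",
              x$peak, x$amplitude, x$baseline, x$sigma, x$center[1], x$center[2]))
  invisible(x)
}

#' @export
tidy.gaussian_indentation <- function(x, ...) {
  tibble(term = c("amplitude", "center_x", "center_y", "sigma", "baseline"),
         estimate = c(x$amplitude, x$center[1], x$center[2], x$sigma, x$baseline))
}

#' @export
glance.gaussian_indentation <- function(x, ...) {
  tibble(peak = x$peak, rss = x$rss, n = x$n)
}

# ---- force readout ----------------------------------------------------------

#' Estimate the tool-tip force from an indentation fit
#'
#' The tissue displacement at the (occluded) tool tip is the peak of the
#' fitted Gaussian; the force is read off the calibrated force-displacement
#' polynomial.  Peaks up to 20 % beyond the calibrated range are evaluated
#' with an extrapolation flag; larger peaks are an error.
#'
#' @param model A `force_displacement_model`.
#' @param indentation A `gaussian_indentation` (or a single numeric peak
#'   displacement in mm).
#' @return One-row tibble: `peak_mm`, `force_N`, `extrapolated`.
#' @export
estimate_force <- function(model, indentation) {
  stopifnot(inherits(model, "force_displacement_model"))
  peak <- if (inherits(indentation, "gaussian_indentation")) {
    indentation$peak
  } else {
    as.numeric(indentation)
  }
  if (!is.finite(peak) || peak < 0) {
    abort("peak displacement must be non-negative",
          class = "tissuedeform_invalid_input")
  }
  if (peak > 1.2 * model$d_max) {
    abort(sprintf("peak displacement %.3g mm is beyond 1.2 x d_max (%.3g mm)",
                  peak, model$d_max),
          class = "tissuedeform_invalid_input")
  }
  # warn when the calibrated polynomial is not monotone on its valid range
  dvals <- seq(0, model$d_max, length.out = 50)
  slope <- 2 * model$a2 * dvals + model$a1
  if (any(slope < 0)) {
    warn("force-displacement model is not monotone non-decreasing on [0, d_max]")
  }
  tibble(peak_mm = peak,
         force_N = model$a2 * peak^2 + model$a1 * peak + model$a0,
         extrapolated = peak > model$d_max)
}

#' Estimate tool-tip force from a recovered deformation field
#'
#' Convenience wrapper: builds Gaussian-fit samples from a deformation field
#' (lateral reference-surface coordinates against displacement magnitude),
#' excludes the tool-occluded disk, fits the indentation and reads the force
#' off the material model.
#'
#' @param field Deformation-field tibble (needs `x_ref`, `y_ref`, `D`).
#' @param model A `force_displacement_model`.
#' @param occlusion List with `center` (x, y mm) and `radius` (mm) for the
#'   tool footprint, or `NULL`.
#' @param high_confidence_only Use only points whose deformation was measured
#'   or confirmed on the current reconstruction (`confidence == "high"`);
#'   extrapolated low-confidence points would bias the fit exactly where the
#'   peak is inferred.
#' @return One-row tibble: `peak_mm`, `force_N`, `extrapolated` plus the
#'   fitted `center_x`, `center_y`, `sigma_mm`.
#' @export
estimate_force_from_field <- function(field, model, occlusion = NULL,
                                      high_confidence_only = TRUE) {
  if (high_confidence_only && "confidence" %in% names(field)) {
    keep <- field$confidence == "high"
    if (sum(keep) >= 5) field <- field[keep, ]
  }
  # samples are placed at the lateral position where the surface was actually
  # measured (current position): near the occlusion boundary the TPS-mapped
  # points carry a small outward lateral bias, and labeling their D at the
  # reference position would systematically flatten the fitted peak
  has_cur <- all(c("x", "y") %in% names(field)) && !anyNA(field$x)
  samples <- tibble(x = if (has_cur) field$x else field$x_ref,
                    y = if (has_cur) field$y else field$y_ref,
                    D = field$D)
  ind <- fit_indentation(samples, occlusion = occlusion)
  out <- estimate_force(model, ind)
  out$center_x <- ind$center[1]
  out$center_y <- ind$center[2]
  out$sigma_mm <- ind$sigma
  out
}
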