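# Strain-controlled tensile ramp on scleral strips and the exponential
# stress-strain model sigma = A (exp(B eps) - 1); A*B is the initial tangent
# modulus, B the rate of stiffening with stress.

#' Strip geometry from repeated B-mode readings
#'
#' Thickness is the mean of the nine B-mode thickness readings (3 per
#' cross-sectional scan, 3 scans) and width the mean of the three width
#' readings.
#'
#' @param thickness_readings Numeric vector of thickness readings in mm.
#' @param width_readings Numeric vector of width readings in mm.
#' @param gauge_length Post-preload grip separation in mm.
#' @return A `strip_geometry` list with `thickness`, `width`, `gauge_length`
#'   and the raw readings.
#' @export
strip_geometry <- function(thickness_readings, width_readings, gauge_length) {
  stop_if_not_positive(thickness_readings, "thickness_readings")
  stop_if_not_positive(width_readings, "width_readings")
  stop_if_not_positive(gauge_length, "gauge_length")
  structure(
    list(
      thickness = mean(thickness_readings),
      width = mean(width_readings),
      gauge_length = gauge_length,
      raw_thickness_readings = thickness_readings,
      raw_width_readings = width_readings
    ),
    class = "strip_geometry"
  )
}

#' Engineering stress and strain from raw force/displacement records
#'
#' Engineering definitions with the undeformed cross-section: stress is axial
#' force over `thickness x width` (N/mm^2 = MPa) and strain is grip
#' displacement over the post-preload gauge length.
#'
#' @param force Axial force series in N.
#' @param displacement Grip displacement series in mm, measured from the
#'   post-preload gauge length.
#' @param geometry A [strip_geometry()].
#' @return A data frame with columns `strain` and `stress` (MPa).
#' @export
stress_strain_from_raw <- function(force, displacement, geometry) {
  stopifnot(inherits(geometry, "strip_geometry"))
  area <- geometry$thickness * geometry$width
  if (area <= 0) stop("zero or negative cross-section", call. = FALSE)
  data.frame(
    strain = displacement / geometry$gauge_length,
    stress = force / area
  )
}

#' Simulate a strain-controlled tensile ramp
#'
#' Strain increases linearly at `strain_rate` up to `strain_max`; stress
#' follows the exponential model `sigma = A (exp(B eps) - 1)` plus optional
#' Gaussian noise. Protocol defaults: 0.1%/s ramp to 3.5% strain.
#'
#' @param A Scale parameter in MPa.
#' @param B Dimensionless exponent (stiffening rate).
#' @param strain_rate Strain rate per second (default 0.001).
#' @param strain_max Final strain (default 0.035).
#' @param sample_rate Sampling rate in Hz (default 50, typical of a
#'   mechanical test frame).
#' @param noise_sd Gaussian stress noise SD in MPa.
#' @param seed Optional integer seed.
#' @return A data frame with columns `time`, `strain`, `stress`.
#' @export
simulate_ramp <- function(A, B, strain_rate = 0.001, strain_max = 0.035,
                          sample_rate = 50, noise_sd = 0, seed = NULL) {
  stop_if_not_positive(A, "A")
  stop_if_not_positive(B, "B")
  stop_if_not_positive(strain_rate, "strain_rate")
  stop_if_not_positive(strain_max, "strain_max")
  time <- seq(0, strain_max / strain_rate, by = 1 / sample_rate)
  strain <- strain_rate * time
  stress <- A * (exp(B * strain) - 1)
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) {
      stats::rnorm(length(time), 0, noise_sd)
    } else {
      with_seed(seed, stats::rnorm(length(time), 0, noise_sd))
    }
    stress <- stress + noise
  }
  data.frame(time = time, strain = strain, stress = stress)
}

# Initial values from the log-linearised tangent modulus:
# d sigma/d eps = A B exp(B eps), so log(d sigma/d eps) is linear in eps with
# slope B and intercept log(A B).  The curve is binned before differencing so
# per-sample noise does not swamp the finite differences.
ramp_start_values <- function(strain, stress, n_bins = 15) {
  n_bins <- min(n_bins, max(4, length(strain) %/% 3))
  bins <- cut(strain, breaks = n_bins, labels = FALSE)
  eps_b <- as.numeric(tapply(strain, bins, mean))
  sig_b <- as.numeric(tapply(stress, bins, mean))
  d <- diff(sig_b) / diff(eps_b)
  mid <- (eps_b[-1] + eps_b[-length(eps_b)]) / 2
  ok <- is.finite(d) & d > 0
  if (sum(ok) < 3) return(list(A = 0.05, B = 50))
  fit <- stats::lm.fit(cbind(1, mid[ok]), log(d[ok]))$coefficients
  B0 <- min(max(unname(fit[2]), 1e-3), 1000)
  A0 <- max(exp(unname(fit[1])) / B0, 1e-6)
  list(A = A0, B = B0)
}

#' Fit the exponential stress-strain model to a tensile ramp
#'
#' Levenberg-Marquardt least squares for `sigma = A (exp(B eps) - 1)`.
#' Starting values come from the slope of `log(d sigma / d eps)` versus strain
#' (finite differences); on non-convergence the fit restarts from up to five
#' jittered starts. `A * B` is reported as the initial tangent modulus, with
#' RMSE and R^2 as goodness of fit.
#'
#' @param strain Strictly increasing dimensionless strain series (>= 10
#'   samples).
#' @param stress Stress series in MPa.
#' @return A `ramp_fit` list: `A` (MPa), `B`, `AB` (MPa), `rmse` (MPa),
#'   `r_squared`, plus the data and the underlying `nls` object.
#' @export
fit_exponential <- function(strain, stress) {
  if (length(strain) < 10) stop("need at least 10 samples", call. = FALSE)
  if (any(diff(strain) <= 0)) stop("strain must be strictly increasing", call. = FALSE)
  dat <- data.frame(strain = strain, stress = stress)
  start <- ramp_start_values(strain, stress)
  fit <- NULL
  for (try in 0:5) {
    st <- if (try == 0) start else {
      list(A = start$A * exp(stats::runif(1, -1, 1)),
           B = start$B * exp(stats::runif(1, -0.5, 0.5)))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(
        stress ~ A * (exp(B * strain) - 1), data = dat, start = st,
        lower = c(A = 1e-8, B = 1e-4),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("exponential fit failed to converge after multi-start", call. = FALSE)
  }
  cf <- stats::coef(fit)
  resid <- dat$stress - stats::predict(fit)
  ss_res <- sum(resid^2)
  ss_tot <- sum((dat$stress - mean(dat$stress))^2)
  structure(
    list(
      A = unname(cf["A"]), B = unname(cf["B"]),
      AB = unname(cf["A"] * cf["B"]),
      rmse = sqrt(mean(resid^2)),
      r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
      data = dat, nls = fit
    ),
    class = "ramp_fit"
  )
}

#' @export
print.ramp_fit <- function(x, ...) {
  cat("Exponential stress-strain fit: sigma = A (exp(B eps) - 1)\n")
  cat(sprintf("  A = %.4f MPa, B = %.2f, A*B = %.3f MPa\n", x$A, x$B, x$AB))
  cat(sprintf("  RMSE = %.4g MPa, R^2 = %.4f, n = %d\n",
              x$rmse, x$r_squared, nrow(x$data)))
  invisible(x)
}

#' @export
coef.ramp_fit <- function(object, ...) {
  c(A = object$A, B = object$B, AB = object$AB)
}

#' @export
predict.ramp_fit <- function(object, newdata = NULL, ...) {
  strain <- if (is.null(newdata)) object$data$strain else newdata$strain
  object$A * (exp(object$B * strain) - 1)
}

#' @export
residuals.ramp_fit <- function(object, ...) {
  object$data$stress - predict(object)
}

#' @export
plot.ramp_fit <- function(x, ...) {
  graphics::plot(x$data$strain, x$data$stress, xlab = "strain",
                 ylab = "stress (MPa)", ...)
  eps <- seq(0, max(x$data$strain), length.out = 200)
  graphics::lines(eps, x$A * (exp(x$B * eps) - 1), col = 2)
  invisible(x)
}
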