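# Dynamic mechanical analysis of scleral strips: small-amplitude sinusoidal
# strain, stress response with phase lag delta; linear-viscoelastic parameters
# E* (complex modulus), tan(delta), storage and loss moduli.

# Linearity bound on strain amplitude established in preliminary testing.
DMA_LINEARITY_BOUND <- 0.0025

# Protocol constants: drive frequencies (Hz) and static preloads (N).
DMA_FREQUENCIES <- c(0.1, 0.5, 1, 3, 5, 10)
DMA_PRELOADS <- c(0.04, 0.1)

#' Laplace-law hoop stress in a thin spherical shell
#'
#' Used to choose strip preloads that reproduce the scleral-shell wall stress at
#' a reference IOP: `sigma = P * r / (2 t)` with generic globe geometry (radius
#' of curvature 12 mm, scleral thickness 0.5 mm).
#'
#' @param pressure IOP in mmHg.
#' @param radius Shell radius of curvature in mm.
#' @param thickness Wall thickness in mm.
#' @return Hoop stress in MPa.
#' @examples
#' laplace_preload_stress(15, 12, 0.5) # ~0.024 MPa
#' @export
laplace_preload_stress <- function(pressure, radius = 12, thickness = 0.5) {
  stop_if_not_positive(pressure, "pressure")
  stop_if_not_positive(radius, "radius")
  stop_if_not_positive(thickness, "thickness")
  pressure * MMHG_TO_PA * radius / (2 * thickness) / 1e6
}

#' Simulate a sinusoidal DMA stress/strain record
#'
#' Strain is driven as `eps0 * sin(2 pi f t)`; for a linearly viscoelastic strip
#' the stress responds at the same frequency with amplitude `E* * eps0` and
#' phase lead `delta`, superimposed on the static preload stress. Protocol
#' defaults follow the strip-testing protocol: 12 cycles, 0.15% strain
#' amplitude. Amplitudes above the 0.25% linearity bound are simulated but the
#' returned series carries a `nonlinear_warning` attribute.
#'
#' @param E_star Complex modulus in MPa (> 0).
#' @param delta Phase lag in radians, in `[0, pi/2)`.
#' @param frequency Drive frequency in Hz.
#' @param strain_amplitude Dimensionless strain amplitude (default 0.0015).
#' @param preload_stress Static preload stress in MPa.
#' @param n_cycles Number of drive cycles (default 12).
#' @param sample_rate Sampling rate in Hz (>= 20 x frequency).
#' @param noise_sd Additive Gaussian stress noise SD in MPa.
#' @param drift Linear stress drift in MPa/s (models preload relaxation).
#' @param seed Optional integer seed.
#' @return A `stress_strain_series` data frame with columns `time`, `strain`,
#'   `stress` and attributes `frequency`, `preload_stress`, `n_cycles`,
#'   `sample_rate`, `nonlinear_warning`.
#' @export
simulate_dma <- function(E_star, delta, frequency = 1,
                         strain_amplitude = 0.0015,
                         preload_stress = laplace_preload_stress(15),
                         n_cycles = 12, sample_rate = 100,
                         noise_sd = 0, drift = 0, seed = NULL) {
  stop_if_not_positive(E_star, "E_star")
  if (delta < 0 || delta >= pi / 2) stop("delta must be in [0, pi/2)", call. = FALSE)
  if (sample_rate < 20 * frequency) {
    stop("sample_rate must be at least 20 x drive frequency", call. = FALSE)
  }
  time <- seq(0, n_cycles / frequency, by = 1 / sample_rate)
  strain <- strain_amplitude * sin(2 * pi * frequency * time)
  stress <- preload_stress + E_star * strain_amplitude *
    sin(2 * pi * frequency * time + delta) + drift * time
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) {
      stats::rnorm(length(time), 0, noise_sd)
    } else {
      with_seed(seed, stats::rnorm(length(time), 0, noise_sd))
    }
    stress <- stress + noise
  }
  out <- data.frame(time = time, strain = strain, stress = stress)
  attr(out, "frequency") <- frequency
  attr(out, "preload_stress") <- preload_stress
  attr(out, "n_cycles") <- n_cycles
  attr(out, "sample_rate") <- sample_rate
  attr(out, "nonlinear_warning") <- strain_amplitude > DMA_LINEARITY_BOUND
  class(out) <- c("stress_strain_series", "data.frame")
  out
}

#' Harmonic least-squares fit of one channel of a DMA record
#'
#' Fits `a + b sin(2 pi f t) + c cos(2 pi f t)` (optionally plus a linear drift
#' term) by ordinary least squares at the known drive frequency; amplitude is
#' `sqrt(b^2 + c^2)` and phase `atan2(c, b)`, so the channel is
#' `a + amplitude * sin(2 pi f t + phase)`. The analysis window defaults to the
#' last 8 of 12 drive cycles.
#'
#' @param series A `stress_strain_series`.
#' @param channel `"stress"` or `"strain"`.
#' @param window Length-2 vector of cycle indices delimiting the analysis
#'   window (default `c(4, 12)`: last 8 of 12 cycles).
#' @param drift If `TRUE`, include a linear time regressor to absorb slow
#'   preload relaxation.
#' @return A list with `amplitude`, `phase` (radians), `offset`, `drift`.
#' @export
fit_harmonic <- function(series, channel = c("stress", "strain"),
                         window = NULL, drift = FALSE) {
  channel <- match.arg(channel)
  f <- attr(series, "frequency")
  if (is.null(f)) stop("series lacks a drive frequency attribute", call. = FALSE)
  n_cycles <- attr(series, "n_cycles")
  if (is.null(window)) window <- c(max(0, n_cycles - 8), n_cycles)
  if (diff(window) < 2) stop("analysis window must span at least 2 cycles", call. = FALSE)
  idx <- series$time >= window[1] / f & series$time <= window[2] / f
  if (sum(idx) < 8) stop("insufficient samples in analysis window", call. = FALSE)
  t <- series$time[idx]
  y <- series[[channel]][idx]
  X <- cbind(1, sin(2 * pi * f * t), cos(2 * pi * f * t))
  if (drift) X <- cbind(X, t)
  beta <- stats::lm.fit(X, y)$coefficients
  list(
    amplitude = unname(sqrt(beta[2]^2 + beta[3]^2)),
    phase = unname(atan2(beta[3], beta[2])),
    offset = unname(beta[1]),
    drift = if (drift) unname(beta[4]) else 0
  )
}

#' Extract linear-viscoelastic parameters from a DMA record
#'
#' Fits both channels harmonically; the phase lag is
#' `delta = phase(stress) - phase(strain)` wrapped to `[0, pi/2)` and the
#' complex modulus is the stress/strain amplitude ratio. Storage and loss
#' moduli follow as `E' = E* cos(delta)`, `E'' = E* sin(delta)`, and
#' `tan(delta) = E''/E'`.
#'
#' @inheritParams fit_harmonic
#' @return A `dma_fit` list: `E_star` (MPa), `delta` (rad), `tan_delta`,
#'   `E_storage`, `E_loss`, `frequency`, `preload_stress`.
#' @export
viscoelastic_params <- function(series, window = NULL, drift = FALSE) {
  fs <- fit_harmonic(series, "stress", window = window, drift = drift)
  fe <- fit_harmonic(series, "strain", window = window, drift = drift)
  if (fe$amplitude < 1e-12) stop("degenerate input: strain amplitude ~ 0", call. = FALSE)
  delta <- (fs$phase - fe$phase) %% (2 * pi)
  if (delta > pi) delta <- delta - 2 * pi  # wrap to (-pi, pi]
  if (delta < -1e-6 || delta >= pi / 2) {
    stop(sprintf("recovered phase lag %.3f rad outside [0, pi/2)", delta), call. = FALSE)
  }
  delta <- max(delta, 0)
  E_star <- fs$amplitude / fe$amplitude
  structure(
    list(
      E_star = E_star, delta = delta, tan_delta = tan(delta),
      E_storage = E_star * cos(delta), E_loss = E_star * sin(delta),
      frequency = attr(series, "frequency"),
      preload_stress = attr(series, "preload_stress")
    ),
    class = "dma_fit"
  )
}

#' Run the full DMA frequency x preload sweep for one strip
#'
#' Analyzes a bundle of 12 records (6 frequencies x 2 preloads) and returns one
#' row per condition; the 1 Hz / 0.04 N row is flagged as the reference
#' condition used in all cohort statistics. Missing cells are reported as `NA`
#' rows, never imputed.
#'
#' @param bundle A list of `stress_strain_series`, each carrying a `preload_N`
#'   attribute (as produced by [render_raw_records()]).
#' @param frequencies,preloads Conditions expected in the sweep.
#' @return A data frame with columns `frequency`, `preload`, `E_star`,
#'   `tan_delta`, `E_storage`, `E_loss`, `reference`.
#' @export
run_dma_sweep <- function(bundle, frequencies = DMA_FREQUENCIES,
                          preloads = DMA_PRELOADS) {
  grid <- expand.grid(frequency = frequencies, preload = preloads,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    hit <- Filter(function(s) {
      isTRUE(all.equal(attr(s, "frequency"), grid$frequency[i])) &&
        isTRUE(all.equal(attr(s, "preload_N"), grid$preload[i]))
    }, bundle)
    if (length(hit) == 0L) {
      return(c(E_star = NA_real_, tan_delta = NA_real_,
               E_storage = NA_real_, E_loss = NA_real_))
    }
    p <- viscoelastic_params(hit[[1]])
    c(E_star = p$E_star, tan_delta = p$tan_delta,
      E_storage = p$E_storage, E_loss = p$E_loss)
  })
  out <- cbind(grid, do.call(rbind, res))
  out$reference <- out$frequency == 1 & out$preload == 0.04
  out
}

#' @export
print.dma_fit <- function(x, ...) {
  cat(sprintf("DMA fit at %.1f Hz: E* = %.3f MPa, tan(delta) = %.4f\n",
              x$frequency, x$E_star, x$tan_delta))
  cat(sprintf("  E' = %.3f MPa, E'' = %.3f MPa, delta = %.4f rad\n",
              x$E_storage, x$E_loss, x$delta))
  invisible(x)
}

#' @export
coef.dma_fit <- function(object, ...) {
  c(E_star = object$E_star, tan_delta = object$tan_delta,
    E_storage = object$E_storage, E_loss = object$E_loss)
}
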