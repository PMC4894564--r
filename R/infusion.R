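# Whole-globe bolus infusion: forward simulation of the pressure trace and
# Friedenwald ocular-rigidity estimation.
#
# Friedenwald's pressure-volume relation: K = ln(IOP/IOP0) / (V - V0), so that
# during a constant-rate bolus IOP(t) = IOP0 * exp(K * flow * t).

#' Simulate a bolus infusion pressure trace
#'
#' The globe is held at a stable baseline IOP, then infused at a constant flow
#' for a short bolus; under Friedenwald's relation the pressure rises
#' exponentially in injected volume, and is held at the plateau afterwards
#' (post-bolus equilibration drift is out of scope). Default protocol: 15 mmHg
#' baseline, 15 uL/s for 1 s.
#'
#' @param K Ocular rigidity, per uL (> 0).
#' @param iop0 Baseline IOP in mmHg.
#' @param flow Infusion rate in uL/s.
#' @param duration Bolus duration in s.
#' @param sample_rate Sampling rate in Hz.
#' @param baseline_s Pre-infusion baseline length in s.
#' @param post_s Post-infusion plateau length in s.
#' @param noise_sd Additive Gaussian pressure noise SD in mmHg.
#' @param seed Optional integer seed for the noise.
#' @return A `pressure_trace` data frame with columns `time` (s), `iop` (mmHg)
#'   and `injected_volume` (uL, cumulative), and attributes `baseline_iop`,
#'   `sample_rate`, `flow`, `onset`, `duration`.
#' @export
simulate_infusion <- function(K, iop0 = 15, flow = 15, duration = 1,
                              sample_rate = 100, baseline_s = 5, post_s = 3,
                              noise_sd = 0, seed = NULL) {
  stop_if_not_positive(K, "K")
  stop_if_not_positive(iop0, "iop0")
  stop_if_not_positive(flow, "flow")
  stop_if_not_positive(duration, "duration")
  stop_if_not_positive(sample_rate, "sample_rate")
  time <- seq(0, baseline_s + duration + post_s, by = 1 / sample_rate)
  t_inf <- pmin(pmax(time - baseline_s, 0), duration)
  vol <- flow * t_inf
  iop <- iop0 * exp(K * vol)
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) {
      stats::rnorm(length(time), 0, noise_sd)
    } else {
      with_seed(seed, stats::rnorm(length(time), 0, noise_sd))
    }
    iop <- iop + noise
  }
  out <- data.frame(time = time, iop = iop, injected_volume = vol)
  attr(out, "baseline_iop") <- iop0
  attr(out, "sample_rate") <- sample_rate
  attr(out, "flow") <- flow
  attr(out, "onset") <- baseline_s
  attr(out, "duration") <- duration
  class(out) <- c("pressure_trace", "data.frame")
  out
}

#' Estimate Friedenwald ocular rigidity from a pressure trace
#'
#' Baseline and plateau pressures are means over configurable windows (defaults:
#' the 5 s before infusion onset, and 1-3 s after the bolus ends); rigidity is
#' `K = ln(iop_peak / iop0) / dV` and the volume-normalized rigidity is
#' `k_norm = V0 * K` (dimensionless, uL * per-uL).
#'
#' @param trace A `pressure_trace` from [simulate_infusion()] or
#'   [read_pressure_trace()].
#' @param V0 Baseline ocular volume in uL (e.g. from [ellipsoid_volume()]).
#' @param baseline_window Length-2 vector of times (s) relative to infusion
#'   onset defining the baseline mean window (negative = before onset).
#' @param plateau_window Length-2 vector of times (s) relative to bolus end
#'   defining the plateau mean window.
#' @return A `rigidity_fit` list: `K` (per uL), `k_norm`, `iop0`, `iop_peak`
#'   (mmHg), `dV` (uL), `V0`.
#' @export
estimate_rigidity <- function(trace, V0,
                              baseline_window = c(-5, 0),
                              plateau_window = c(1, 3)) {
  stop_if_not_positive(V0, "V0")
  onset <- attr(trace, "onset")
  duration <- attr(trace, "duration")
  if (is.null(onset) || is.null(duration)) {
    stop("trace lacks infusion onset/duration metadata", call. = FALSE)
  }
  t_end <- onset + duration
  base_idx <- trace$time >= onset + baseline_window[1] & trace$time <= onset + baseline_window[2]
  plat_idx <- trace$time >= t_end + plateau_window[1] & trace$time <= t_end + plateau_window[2]
  if (!any(base_idx) || !any(plat_idx)) {
    stop("baseline or plateau window contains no samples", call. = FALSE)
  }
  iop0 <- mean(trace$iop[base_idx])
  iop_peak <- mean(trace$iop[plat_idx])
  dV <- max(trace$injected_volume) - min(trace$injected_volume)
  if (dV <= 0) stop("injected volume dV must be > 0", call. = FALSE)
  if (iop_peak <= iop0) {
    stop("non-physical trace: plateau IOP does not exceed baseline IOP", call. = FALSE)
  }
  K <- log(iop_peak / iop0) / dV
  structure(
    list(K = K, k_norm = V0 * K, iop0 = iop0, iop_peak = iop_peak,
         dV = dV, V0 = V0),
    class = "rigidity_fit"
  )
}

#' Pool replicate rigidity estimates from repeated infusions on one eye
#'
#' The infusion protocol repeats the bolus twice with re-equilibration between;
#' the per-eye rigidity is reported as the mean of the replicate estimates.
#'
#' @param fits A list of `rigidity_fit` objects for the same eye.
#' @return A `rigidity_fit` with averaged fields and an `n_reps` element.
#' @export
pool_rigidity <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "rigidity_fit")))
  avg <- function(f) mean(vapply(fits, `[[`, numeric(1), f))
  structure(
    list(K = avg("K"), k_norm = avg("k_norm"), iop0 = avg("iop0"),
         iop_peak = avg("iop_peak"), dV = avg("dV"), V0 = avg("V0"),
         n_reps = length(fits)),
    class = "rigidity_fit"
  )
}

#' @export
print.rigidity_fit <- function(x, ...) {
  cat("Friedenwald ocular rigidity\n")
  cat(sprintf("  K      = %.5f per uL\n", x$K))
  cat(sprintf("  k_norm = %.2f (V0 = %.0f uL)\n", x$k_norm, x$V0))
  cat(sprintf("  IOP %.2f -> %.2f mmHg over dV = %.1f uL\n",
              x$iop0, x$iop_peak, x$dV))
  if (!is.null(x$n_reps)) cat(sprintf("  pooled over %d infusions\n", x$n_reps))
  invisible(x)
}

#' @export
coef.rigidity_fit <- function(object, ...) {
  c(K = object$K, k_norm = object$k_norm)
}

#' @export
plot.pressure_trace <- function(x, ...) {
  graphics::plot(x$time, x$iop, type = "l", xlab = "time (s)",
                 ylab = "IOP (mmHg)", ...)
  graphics::abline(v = attr(x, "onset"), lty = 2)
  invisible(x)
}
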