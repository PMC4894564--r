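# Inflation testing of the posterior scleral shell: synthetic high-frequency
# ultrasound RF speckle frames, normalized cross-correlation block-matching
# displacement tracking, least-squares strain estimation, and the coordinate
# transform from beam-aligned (axial/lateral) to tissue-aligned
# (radial/tangential) strains.
#
# Conventions: axial axis points away from the transducer; 0-based physical
# coordinates; extension-positive strains (compression negative).

#' Default point-spread function for the 55 MHz phantom
#'
#' Gaussian-enveloped cosine pulse along the axial (depth) axis at the 55 MHz
#' center frequency sampled at 500 MHz, with a Gaussian lateral beam profile.
#' Envelope widths correspond to roughly 30 um axial and 62 um lateral
#' resolution (FWHM).
#'
#' @param center_frequency Transducer center frequency in Hz.
#' @param sample_rate Axial RF sampling rate in Hz.
#' @param sound_speed Sound speed in m/s used for the depth axis.
#' @param sigma_axial_mm,sigma_lateral_mm Gaussian envelope SDs in mm.
#' @return A list of PSF parameters.
#' @export
speckle_psf <- function(center_frequency = 55e6, sample_rate = 500e6,
                        sound_speed = 1540,
                        sigma_axial_mm = 0.013, sigma_lateral_mm = 0.0265) {
  if (sample_rate < 4 * center_frequency) {
    stop("sample rate must be at least 4 x center frequency", call. = FALSE)
  }
  list(
    center_frequency = center_frequency,
    sample_rate = sample_rate,
    sound_speed = sound_speed,
    # pulse-echo axial sample spacing, mm
    dz_mm = sound_speed / (2 * sample_rate) * 1000,
    # pulse-echo axial spatial frequency, cycles/mm
    k_axial = 2 * center_frequency / sound_speed / 1000,
    sigma_axial_mm = sigma_axial_mm,
    sigma_lateral_mm = sigma_lateral_mm
  )
}

# Synthesize one RF frame from a point-scatterer field by local PSF deposition.
synth_rf_frame <- function(scat_z, scat_x, amp, nz, nx, pitch, psf) {
  frame <- matrix(0, nz, nx)
  dz <- psf$dz_mm
  half_z <- ceiling(4 * psf$sigma_axial_mm / dz)
  half_x <- ceiling(3 * psf$sigma_lateral_mm / pitch)
  z_axis <- (seq_len(nz) - 1) * dz
  x_axis <- (seq_len(nx) - 1) * pitch
  for (s in seq_along(scat_z)) {
    iz <- round(scat_z[s] / dz) + 1
    ix <- round(scat_x[s] / pitch) + 1
    z_lo <- max(1, iz - half_z)
    z_hi <- min(nz, iz + half_z)
    x_lo <- max(1, ix - half_x)
    x_hi <- min(nx, ix + half_x)
    if (z_lo > z_hi || x_lo > x_hi) next
    zi <- z_lo:z_hi
    xi <- x_lo:x_hi
    d_z <- z_axis[zi] - scat_z[s]
    d_x <- x_axis[xi] - scat_x[s]
    g_z <- exp(-d_z^2 / (2 * psf$sigma_axial_mm^2)) *
      cos(2 * pi * psf$k_axial * d_z)
    g_x <- exp(-d_x^2 / (2 * psf$sigma_lateral_mm^2))
    frame[zi, xi] <- frame[zi, xi] + amp[s] * outer(g_z, g_x)
  }
  frame
}

#' Simulate a pre/post RF speckle frame pair under a homogeneous deformation
#'
#' A random point-scatterer field is convolved with the PSF to form the
#' pre-deformation frame; the post frame re-convolves the *same* scatterers
#' after applying the affine deformation implied by the prescribed strains
#' (about the field center). Truth strains may be given either beam-aligned
#' (`axial_strain`, `lateral_strain`) or tissue-aligned (`tangential_strain`,
#' `radial_strain` plus `orientation`), in which case they are rotated into
#' beam coordinates first.
#'
#' @param axial_strain,lateral_strain Beam-aligned truth strains
#'   (dimensionless; extension positive; |strain| < 5%).
#' @param shear Tensor shear strain component (default 0).
#' @param tangential_strain,radial_strain Optional tissue-aligned truth
#'   strains; used with `orientation` when the beam-aligned strains are not
#'   given directly.
#' @param orientation Angle (radians) of the local surface tangent relative to
#'   the lateral axis.
#' @param depth_mm,width_mm Field of view in mm.
#' @param lateral_pitch Lateral line spacing in mm.
#' @param scatterer_density Scatterers per mm^2; below about 5 per resolution
#'   cell the frame is flagged as under-developed speckle.
#' @param psf PSF parameters from [speckle_psf()].
#' @param pressures Length-2 vector of chamber pressures (mmHg) for metadata.
#' @param seed Integer seed for the scatterer field.
#' @return An `rf_frame_pair` list: `pre`, `post` matrices (axial samples x
#'   lateral lines), geometry/PSF metadata, the truth strains, and a
#'   `developed_speckle` flag.
#' @export
simulate_speckle_pair <- function(axial_strain = NULL, lateral_strain = NULL,
                                  shear = 0,
                                  tangential_strain = NULL, radial_strain = NULL,
                                  orientation = 0,
                                  depth_mm = 0.7, width_mm = 1.0,
                                  lateral_pitch = 0.02,
                                  scatterer_density = 3500,
                                  psf = speckle_psf(),
                                  pressures = c(5, 15), seed = 1L) {
  if (is.null(axial_strain)) {
    if (is.null(tangential_strain) || is.null(radial_strain)) {
      stop("supply either axial/lateral or tangential/radial truth strains",
           call. = FALSE)
    }
    beam <- from_tissue_strains(tangential_strain, radial_strain,
                                shear = shear, orientation = orientation)
    axial_strain <- beam$axial_strain
    lateral_strain <- beam$lateral_strain
    shear <- beam$shear
  }
  if (max(abs(c(axial_strain, lateral_strain, shear))) > 0.05) {
    stop("truth strains must be small (|strain| < 5%)", call. = FALSE)
  }
  dz <- psf$dz_mm
  nz <- floor(depth_mm / dz) + 1
  nx <- floor(width_mm / lateral_pitch) + 1
  # generate scatterers with a margin so deformed scatterers still cover edges
  mz <- 5 * psf$sigma_axial_mm
  mx <- 4 * psf$sigma_lateral_mm
  area <- (depth_mm + 2 * mz) * (width_mm + 2 * mx)
  n_scat <- round(scatterer_density * area)
  sc <- with_seed(seed, list(
    z = stats::runif(n_scat, -mz, depth_mm + mz),
    x = stats::runif(n_scat, -mx, width_mm + mx),
    a = stats::rnorm(n_scat)
  ))
  pre <- synth_rf_frame(sc$z, sc$x, sc$a, nz, nx, lateral_pitch, psf)
  z0 <- depth_mm / 2
  x0 <- width_mm / 2
  # affine deformation about the field center, F = I + strain tensor
  z_post <- z0 + (1 + axial_strain) * (sc$z - z0) + shear * (sc$x - x0)
  x_post <- x0 + shear * (sc$z - z0) + (1 + lateral_strain) * (sc$x - x0)
  post <- synth_rf_frame(z_post, x_post, sc$a, nz, nx, lateral_pitch, psf)
  cell_area_mm2 <- (2.355 * psf$sigma_axial_mm) * (2.355 * psf$sigma_lateral_mm)
  per_cell <- scatterer_density * cell_area_mm2
  structure(
    list(
      pre = pre, post = post,
      axial_sample_rate = psf$sample_rate,
      center_frequency = psf$center_frequency,
      dz_mm = dz, lateral_pitch = lateral_pitch,
      pressure_pre = pressures[1], pressure_post = pressures[2],
      truth = list(axial_strain = axial_strain,
                   lateral_strain = lateral_strain, shear = shear),
      scatterers_per_cell = per_cell,
      developed_speckle = per_cell >= 5
    ),
    class = "rf_frame_pair"
  )
}

# Parabolic sub-sample peak refinement from three correlation values.
parabolic_peak <- function(cm, c0, cp) {
  den <- cm - 2 * c0 + cp
  if (!is.finite(den) || den >= 0) return(0)
  d <- 0.5 * (cm - cp) / den
  max(min(d, 0.5), -0.5)
}

# Gaussian sub-sample refinement (parabola on log-correlation): exact when the
# correlation profile is Gaussian, as it is along the lateral (beam-profile)
# axis; falls back to the plain parabola if any correlation is non-positive.
gaussian_peak <- function(cm, c0, cp) {
  if (any(!is.finite(c(cm, c0, cp))) || min(cm, c0, cp) <= 0) {
    return(parabolic_peak(cm, c0, cp))
  }
  parabolic_peak(log(cm), log(c0), log(cp))
}

#' Track displacements between an RF frame pair by block matching
#'
#' 2-D normalized cross-correlation block matching on a regular grid of kernel
#' centers: the integer-lag NCC peak is refined by parabolic sub-sample
#' interpolation independently along each axis. Nodes whose peak correlation
#' falls below `corr_threshold`, or whose peak sits on the search border, are
#' flagged invalid.
#'
#' @param pair An `rf_frame_pair`.
#' @param kernel Kernel size `c(axial_samples, lateral_lines)` (odd).
#' @param search Search range `c(axial_samples, lateral_lines)` around zero
#'   lag.
#' @param step Grid spacing `c(axial_samples, lateral_lines)` between kernel
#'   centers.
#' @param corr_threshold Minimum acceptable peak NCC.
#' @param compand If `TRUE` (default), run a second tracking pass after
#'   axially resampling the post frame by the first-pass global axial strain
#'   (temporal stretching): removing the bulk axial stretch restores kernel
#'   correlation and sharpens both axial and lateral estimates.
#' @return A `displacement_field` list: node coordinates `z_mm`, `x_mm`
#'   (vectors), matrices `axial_disp`/`lateral_disp` in mm, `correlation`,
#'   and logical `valid`.
#' @export
track_displacement <- function(pair, kernel = c(91, 5), search = c(8, 3),
                               step = c(30, 2), corr_threshold = 0.6,
                               compand = TRUE) {
  field <- track_displacement_once(pair, kernel, search, step, corr_threshold)
  if (!compand || sum(field$valid) < 6) return(field)
  # global axial strain from the first pass
  zz <- rep(field$z_mm, times = ncol(field$axial_disp))
  uu <- as.vector(field$axial_disp)
  ok <- as.vector(field$valid) & is.finite(uu)
  if (sum(ok) < 6 || stats::var(zz[ok]) == 0) return(field)
  cf <- stats::lm.fit(cbind(1, zz[ok]), uu[ok])$coefficients
  eps_hat <- unname(cf[2])
  if (abs(eps_hat) < 1e-5) return(field)
  # resample post axially about the field center: post'(z) = post(phi(z)),
  # phi(z) = z0 + (1 + eps)(z - z0)
  nz <- nrow(pair$post)
  z0 <- (nz - 1) / 2
  src <- z0 + (1 + eps_hat) * (seq_len(nz) - 1 - z0) + 1
  post2 <- apply(pair$post, 2, function(col) {
    stats::approx(seq_len(nz), col, xout = src, rule = 2)$y
  })
  pair2 <- pair
  pair2$post <- post2
  f2 <- track_displacement_once(pair2, kernel, search, step, corr_threshold)
  # compose: total u = eps*(z - z0) + (1 + eps) * residual u
  z0_mm <- z0 * pair$dz_mm
  f2$axial_disp <- eps_hat * (outer(f2$z_mm - z0_mm, rep(1, length(f2$x_mm)))) +
    (1 + eps_hat) * f2$axial_disp
  f2
}

track_displacement_once <- function(pair, kernel, search, step,
                                    corr_threshold) {
  stopifnot(inherits(pair, "rf_frame_pair"))
  nz <- nrow(pair$pre)
  nx <- ncol(pair$pre)
  hz <- kernel[1] %/% 2
  hx <- kernel[2] %/% 2
  if (2 * (hz + search[1]) + 1 > nz || 2 * (hx + search[2]) + 1 > nx) {
    stop("kernel plus search range does not fit inside the frames", call. = FALSE)
  }
  iz_centers <- seq(1 + hz + search[1], nz - hz - search[1], by = step[1])
  ix_centers <- seq(1 + hx + search[2], nx - hx - search[2], by = step[2])
  n_iz <- length(iz_centers)
  n_ix <- length(ix_centers)
  u_ax <- matrix(NA_real_, n_iz, n_ix)
  u_lat <- matrix(NA_real_, n_iz, n_ix)
  pk <- matrix(NA_real_, n_iz, n_ix)
  ok <- matrix(FALSE, n_iz, n_ix)
  lags_z <- -search[1]:search[1]
  lags_x <- -search[2]:search[2]
  for (a in seq_len(n_iz)) {
    for (b in seq_len(n_ix)) {
      iz <- iz_centers[a]
      ix <- ix_centers[b]
      P <- as.vector(pair$pre[(iz - hz):(iz + hz), (ix - hx):(ix + hx)])
      if (stats::sd(P) == 0) next
      cc <- matrix(NA_real_, length(lags_z), length(lags_x))
      for (i in seq_along(lags_z)) {
        for (j in seq_along(lags_x)) {
          Q <- as.vector(pair$post[(iz + lags_z[i] - hz):(iz + lags_z[i] + hz),
                                   (ix + lags_x[j] - hx):(ix + lags_x[j] + hx)])
          cc[i, j] <- if (stats::sd(Q) == 0) 0 else stats::cor(P, Q)
        }
      }
      m <- arrayInd(which.max(cc), dim(cc))
      i0 <- m[1]
      j0 <- m[2]
      pk[a, b] <- cc[i0, j0]
      on_border <- i0 == 1 || i0 == length(lags_z) ||
        j0 == 1 || j0 == length(lags_x)
      if (!on_border && pk[a, b] >= corr_threshold) {
        dz_sub <- parabolic_peak(cc[i0 - 1, j0], cc[i0, j0], cc[i0 + 1, j0])
        # lateral refinement: maximize NCC against a laterally interpolated
        # post kernel (parabolic refinement is biased low at sub-pitch shifts)
        zr <- (iz + lags_z[i0] - hz):(iz + lags_z[i0] + hz)
        xc <- ix + lags_x[j0]
        ncc_at <- function(s) {
          k <- floor(s)
          w <- s - k
          Q <- (1 - w) * pair$post[zr, (xc + k - hx):(xc + k + hx)] +
            w * pair$post[zr, (xc + k + 1 - hx):(xc + k + 1 + hx)]
          stats::cor(P, as.vector(Q))
        }
        opt <- stats::optimize(ncc_at, interval = c(-1, 1), maximum = TRUE,
                               tol = 1e-3)
        dx_sub <- opt$maximum
        u_ax[a, b] <- (lags_z[i0] + dz_sub) * pair$dz_mm
        u_lat[a, b] <- (lags_x[j0] + dx_sub) * pair$lateral_pitch
        ok[a, b] <- TRUE
      }
    }
  }
  structure(
    list(
      z_mm = (iz_centers - 1) * pair$dz_mm,
      x_mm = (ix_centers - 1) * pair$lateral_pitch,
      axial_disp = u_ax, lateral_disp = u_lat,
      correlation = pk, valid = ok
    ),
    class = "displacement_field"
  )
}

# Sliding-window OLS slope of y on x at each index, using only valid points;
# fewer than 3 valid points in a window yields NA.
sliding_slope <- function(x, y, valid, kernel) {
  n <- length(x)
  h <- kernel %/% 2
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    idx <- max(1, i - h):min(n, i + h)
    idx <- idx[valid[idx] & is.finite(y[idx])]
    if (length(idx) < 3) next
    xv <- x[idx]
    yv <- y[idx]
    out[i] <- sum((xv - mean(xv)) * (yv - mean(yv))) / sum((xv - mean(xv))^2)
  }
  out
}

#' Least-squares strain estimation from a displacement field
#'
#' Strain at each node is the OLS slope of displacement versus position within
#' a sliding kernel of neighbouring nodes, per axis (axial displacement versus
#' depth; lateral displacement versus lateral position). Invalid nodes are
#' excluded from each local regression; kernels with fewer than 3 valid nodes
#' yield `NA`. Exact for affine displacement fields.
#'
#' @param field A `displacement_field`.
#' @param strain_kernel Number of nodes in the sliding kernel (>= 3).
#' @return A `strain_field` list with matrices `axial_strain` and
#'   `lateral_strain` plus the node coordinates and validity mask.
#' @export
ls_strain <- function(field, strain_kernel = 7) {
  stopifnot(inherits(field, "displacement_field"))
  if (strain_kernel < 3) stop("strain kernel must span at least 3 nodes", call. = FALSE)
  n_iz <- length(field$z_mm)
  n_ix <- length(field$x_mm)
  eps_ax <- matrix(NA_real_, n_iz, n_ix)
  eps_lat <- matrix(NA_real_, n_iz, n_ix)
  for (b in seq_len(n_ix)) {
    eps_ax[, b] <- sliding_slope(field$z_mm, field$axial_disp[, b],
                                 field$valid[, b], strain_kernel)
  }
  for (a in seq_len(n_iz)) {
    eps_lat[a, ] <- sliding_slope(field$x_mm, field$lateral_disp[a, ],
                                  field$valid[a, ], strain_kernel)
  }
  structure(
    list(z_mm = field$z_mm, x_mm = field$x_mm,
         axial_strain = eps_ax, lateral_strain = eps_lat,
         valid = field$valid),
    class = "strain_field"
  )
}

#' Rotate beam-aligned strains to tissue-aligned tangential/radial strains
#'
#' Plane strain-tensor rotation by the local surface orientation `theta` (angle
#' of the surface tangent relative to the lateral axis):
#' `eps_t = eps_lat cos^2(theta) + eps_ax sin^2(theta) + 2 shear sin cos` and
#' `eps_r = eps_lat sin^2(theta) + eps_ax cos^2(theta) - 2 shear sin cos`.
#' With zero shear and `theta = 0` (beam normal to the surface) this is the
#' identity mapping radial = axial, tangential = lateral. The trace is
#' preserved: `eps_t + eps_r = eps_ax + eps_lat`.
#'
#' @param axial_strain,lateral_strain Beam-aligned strains (vectorised).
#' @param shear Tensor shear component (default 0).
#' @param orientation Surface-tangent angle in radians.
#' @return A list with `tangential_strain` and `radial_strain`.
#' @export
to_tissue_strains <- function(axial_strain, lateral_strain, shear = 0,
                              orientation = 0) {
  c2 <- cos(orientation)^2
  s2 <- sin(orientation)^2
  sc <- sin(orientation) * cos(orientation)
  list(
    tangential_strain = lateral_strain * c2 + axial_strain * s2 + 2 * shear * sc,
    radial_strain = lateral_strain * s2 + axial_strain * c2 - 2 * shear * sc
  )
}

#' Inverse rotation: tissue-aligned to beam-aligned strains
#'
#' @param tangential_strain,radial_strain Tissue-aligned strains.
#' @param shear Tensor shear in tissue axes (default 0).
#' @param orientation Surface-tangent angle in radians.
#' @return A list with `axial_strain`, `lateral_strain`, `shear`.
#' @export
from_tissue_strains <- function(tangential_strain, radial_strain, shear = 0,
                                orientation = 0) {
  c2 <- cos(orientation)^2
  s2 <- sin(orientation)^2
  sc <- sin(orientation) * cos(orientation)
  list(
    lateral_strain = tangential_strain * c2 + radial_strain * s2 - 2 * shear * sc,
    axial_strain = tangential_strain * s2 + radial_strain * c2 + 2 * shear * sc,
    shear = (radial_strain - tangential_strain) * sc +
      shear * (c2 - s2)
  )
}

#' The inflation pressure schedule
#'
#' Chamber pressures in mmHg: 5 to 20 in 0.5 mmHg steps, 20 to 30 in 2.5 mmHg
#' steps, then 35, 40 and 45 mmHg.
#'
#' @return Numeric vector of pressures including the 5 mmHg baseline.
#' @export
inflation_schedule <- function() {
  c(seq(5, 20, by = 0.5), seq(22.5, 30, by = 2.5), 35, 40, 45)
}

#' Simulate and analyze a full inflation pressure series for one eye
#'
#' The shell truth prescribes tangential and radial strain (referenced to the
#' 5 mmHg baseline) as linear functions of pressure reaching `tangential_15` /
#' `radial_15` at 15 mmHg. RF frames are synthesized from one persistent
#' scatterer field at each pressure step; tracking is *incremental* between
#' consecutive steps (small steps keep the speckle correlated) and the
#' per-step strains are accumulated multiplicatively to cumulative strains
#' referenced to baseline. If more than `max_invalid` of nodes fail at any
#' step the eye is flagged `tracking_failed` and the strain outputs are `NA`.
#'
#' @param truth List with `tangential_15`, `radial_15` (strains at 15 mmHg
#'   from the 5 mmHg baseline) and optional `orientation` (radians, default 0).
#' @param schedule Pressure schedule in mmHg (default [inflation_schedule()]);
#'   must start at the 5 mmHg baseline.
#' @param seed Integer seed for the scatterer field.
#' @param max_invalid Maximum tolerated invalid-node fraction per step.
#' @param strain_kernel Kernel for [ls_strain()].
#' @param ... Further arguments to [simulate_speckle_pair()] (phantom geometry,
#'   PSF, density).
#' @return An `inflation_result` list: `pressure`, cumulative `tangential` and
#'   `radial` strain per step, `tangential_15`, `radial_15`,
#'   `invalid_fraction`, `tracking_failed`.
#' @export
inflation_series <- function(truth, schedule = inflation_schedule(), seed = 1L,
                             max_invalid = 0.2, strain_kernel = 7, ...) {
  stopifnot(is.list(truth), !is.null(truth$tangential_15), !is.null(truth$radial_15))
  orientation <- if (is.null(truth$orientation)) 0 else truth$orientation
  baseline <- schedule[1]
  ref_span <- 15 - baseline
  # cumulative truth strains, linear in pressure above baseline
  tang_cum <- truth$tangential_15 * (schedule - baseline) / ref_span
  rad_cum <- truth$radial_15 * (schedule - baseline) / ref_span
  n_steps <- length(schedule) - 1
  lam_t <- 1 + c(0, rep(NA_real_, n_steps))
  lam_r <- 1 + c(0, rep(NA_real_, n_steps))
  acc_t <- 1
  acc_r <- 1
  invalid_frac <- numeric(n_steps)
  failed <- FALSE
  for (k in seq_len(n_steps)) {
    # incremental stretch between step k and k+1
    inc_t <- (1 + tang_cum[k + 1]) / (1 + tang_cum[k]) - 1
    inc_r <- (1 + rad_cum[k + 1]) / (1 + rad_cum[k]) - 1
    pair <- simulate_speckle_pair(
      tangential_strain = inc_t, radial_strain = inc_r,
      orientation = orientation,
      pressures = schedule[k + 0:1], seed = seed, ...
    )
    field <- track_displacement(pair)
    invalid_frac[k] <- 1 - mean(field$valid)
    if (invalid_frac[k] > max_invalid) {
      failed <- TRUE
      break
    }
    sf <- ls_strain(field, strain_kernel = strain_kernel)
    tis <- to_tissue_strains(sf$axial_strain, sf$lateral_strain,
                             orientation = orientation)
    est_t <- stats::median(tis$tangential_strain, na.rm = TRUE)
    est_r <- stats::median(tis$radial_strain, na.rm = TRUE)
    acc_t <- acc_t * (1 + est_t)
    acc_r <- acc_r * (1 + est_r)
    lam_t[k + 1] <- acc_t
    lam_r[k + 1] <- acc_r
  }
  tangential <- lam_t - 1
  radial <- lam_r - 1
  at15 <- which(abs(schedule - 15) < 1e-9)
  structure(
    list(
      pressure = schedule,
      tangential = if (failed) rep(NA_real_, length(schedule)) else tangential,
      radial = if (failed) rep(NA_real_, length(schedule)) else radial,
      tangential_15 = if (failed || length(at15) == 0) NA_real_ else tangential[at15[1]],
      radial_15 = if (failed || length(at15) == 0) NA_real_ else radial[at15[1]],
      invalid_fraction = invalid_frac,
      tracking_failed = failed
    ),
    class = "inflation_result"
  )
}

#' @export
print.inflation_result <- function(x, ...) {
  cat("Inflation series:", length(x$pressure), "pressure steps,",
      sprintf("%.1f-%.1f mmHg\n", min(x$pressure), max(x$pressure)))
  if (x$tracking_failed) {
    cat("  tracking FAILED (invalid-node fraction exceeded threshold)\n")
  } else {
    cat(sprintf("  tangential strain at 15 mmHg: %.4f\n", x$tangential_15))
    cat(sprintf("  radial strain at 15 mmHg:     %.4f\n", x$radial_15))
  }
  invisible(x)
}
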