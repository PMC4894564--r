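# A-mode ultrasound biometry: time-of-flight to distance and globe volume.

# Assumed sound speeds (m/s) per ocular medium.
SOUND_SPEED_M_S <- c(
  cornea_sclera    = 1605,
  aqueous_vitreous = 1540,
  lens             = 1645
)

#' Convert A-mode round-trip time of flight to distance
#'
#' Pulse-echo convention: the echo travels to the interface and back, so the
#' one-way distance is `c * t / 2` with the sound speed `c` of the traversed
#' medium. At a 500 MHz radiofrequency sampling rate this gives a distance
#' resolution of about 1.5 um per sample in aqueous/vitreous.
#'
#' @param round_trip_time Round-trip echo time in seconds (vectorised, >= 0).
#' @param medium One of `"cornea_sclera"` (1605 m/s), `"aqueous_vitreous"`
#'   (1540 m/s) or `"lens"` (1645 m/s).
#' @return One-way distance in mm.
#' @examples
#' tof_to_distance(20e-6, "lens") # 16.45 mm
#' @export
tof_to_distance <- function(round_trip_time,
                            medium = c("cornea_sclera", "aqueous_vitreous", "lens")) {
  medium <- match.arg(medium)
  if (any(round_trip_time < 0)) stop("round-trip time must be >= 0", call. = FALSE)
  SOUND_SPEED_M_S[[medium]] * round_trip_time / 2 * 1000
}

#' Ellipsoidal ocular volume from the three globe diameters
#'
#' Treats the axial, nasal-temporal and superior-inferior lengths as the full
#' diameters of an ellipsoid: `V = (pi/6) * axial * nt * si`, with mm^3 = uL.
#'
#' @param axial,nt,si Globe diameters in mm (all > 0).
#' @return Volume in uL.
#' @examples
#' ellipsoid_volume(24.9, 22.6, 22.3) # about 6571 uL
#' @export
ellipsoid_volume <- function(axial, nt, si) {
  stop_if_not_positive(axial, "axial")
  stop_if_not_positive(nt, "nt")
  stop_if_not_positive(si, "si")
  (pi / 6) * axial * nt * si
}

#' Globe geometry summary
#'
#' @param axial,nt,si Globe diameters in mm.
#' @return A `globe_geometry` list with the three diameters and `v0`, the
#'   ellipsoidal volume in uL.
#' @export
globe_geometry <- function(axial, nt, si) {
  structure(
    list(axial = axial, nt = nt, si = si, v0 = ellipsoid_volume(axial, nt, si)),
    class = "globe_geometry"
  )
}

#' @export
print.globe_geometry <- function(x, ...) {
  cat(sprintf(
    "Globe geometry: axial %.2f mm, NT %.2f mm, SI %.2f mm; V0 = %.0f uL\n",
    x$axial, x$nt, x$si, x$v0
  ))
  invisible(x)
}
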