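#' Synchronous speed correction for a refractive-index mismatched path
#'
#' In a chamberless SPIM the detection path crosses the clearing medium
#' (refractive index `n`) and air. Keeping the focal plane stationary while
#' the sample stage travels `dz_sample` requires the detection optics to
#' travel `dz_detect = c * dz_sample` with `c = (n - 1)/n`: the focal length
#' is a sum of physical distances divided by their refractive indices, and
#' this factor is the unique ratio that leaves the sum invariant.
#'
#' In practice the correction can deviate from theory (actuator load, PC
#' timing); functions taking a refractive index accept an optional
#' `correction` override holding an empirically calibrated value.
#'
#' @param n refractive index of the immersion/clearing medium, `n >= 1`.
#' @return dimensionless correction factor in `[0, 1)`.
#' @examples
#' speed_correction(1.52)       # 0.342 for CUBIC-R
#' detection_velocity(100, 1.52)  # 34.2 um/s
#' @export
speed_correction <- function(n) {
  n <- as.numeric(n)
  if (any(!is.finite(n)) || any(n < 1))
    stop("refractive index must be >= 1 (non-physical medium)")
  (n - 1) / n
}

#' Detection-stage velocity synchronised to a sample-stage velocity
#'
#' @param v_stage sample-stage velocity, um/s, `>= 0`.
#' @inheritParams speed_correction
#' @param correction optional calibrated correction value overriding
#'   `(n - 1)/n`.
#' @return detection-optics velocity in um/s.
#' @export
detection_velocity <- function(v_stage, n, correction = NULL) {
  v_stage <- as.numeric(v_stage)
  if (any(!is.finite(v_stage)) || any(v_stage < 0))
    stop("'v_stage' must be >= 0")
  c_val <- if (is.null(correction)) speed_correction(n) else as.numeric(correction)
  v_stage * c_val
}

#' Focal-length residual of a synchronisation state
#'
#' Evaluates how far a given pair of stage displacements moves the focal
#' plane: the difference between the focal path length after displacement,
#' `(A - dz_sample)/n + (B + dz_sample - dz_detect)`, and the initial
#' `A/n + B`. The residual is exactly zero when
#' `dz_detect = speed_correction(n) * dz_sample`.
#'
#' @param n medium refractive index.
#' @param A in-medium path length, um.
#' @param B in-air path length, um.
#' @param dz_sample,dz_detect stage displacements, um.
#' @return residual focal shift in um (0 means the focus is held).
#' @export
focal_invariance_residual <- function(n, A, B, dz_sample, dz_detect) {
  if (n < 1) stop("refractive index must be >= 1")
  if (A - dz_sample < 0)
    stop("sample displacement exceeds the in-medium path length A")
  (A - dz_sample) / n + (B + dz_sample - dz_detect) - (A / n + B)
}

#' Plan a synchronised z-stack acquisition
#'
#' The stack is collected as a time-lapse movie while both stages move
#' continuously, so the z-interval equals `v_stage * exposure` and the
#' z-range is `n_frames * z_interval`. The detection velocity follows from
#' the synchronous speed correction (or a calibrated override).
#'
#' @param v_stage sample-stage velocity, um/s (mm/s not accepted; convert
#'   before calling).
#' @param exposure camera exposure per frame, s.
#' @param n_frames number of frames (= slices) to collect.
#' @param n medium refractive index.
#' @param correction optional calibrated speed-correction value.
#' @return an object of class `"acquisition_plan"`: list with `v_stage`,
#'   `v_detect`, `exposure`, `n_frames`, `z_interval` (um), `z_range` (um),
#'   `stage_travel` (um), `detect_travel` (um), `correction`.
#' @examples
#' plan_acquisition(50, 0.2, 900, 1.52)   # 10 um z-interval, 9 mm z-range
#' @export
plan_acquisition <- function(v_stage, exposure, n_frames, n, correction = NULL) {
  vals <- c(v_stage = v_stage, exposure = exposure, n_frames = n_frames, n = n)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all of v_stage, exposure, n_frames, n must be positive")
  if (n_frames != round(n_frames)) stop("'n_frames' must be a whole number")
  c_val <- if (is.null(correction)) speed_correction(n) else as.numeric(correction)
  z_interval <- v_stage * exposure
  z_range <- n_frames * z_interval
  structure(list(
    v_stage = v_stage,
    v_detect = v_stage * c_val,
    exposure = exposure,
    n_frames = as.integer(n_frames),
    z_interval = z_interval,
    z_range = z_range,
    stage_travel = z_range,
    detect_travel = z_range * c_val,
    correction = c_val
  ), class = "acquisition_plan")
}

#' @export
print.acquisition_plan <- function(x, ...) {
  cat("acquisition_plan\n")
  cat(sprintf("  v_stage %.4g um/s, v_detect %.4g um/s (correction %.4g)\n",
              x$v_stage, x$v_detect, x$correction))
  cat(sprintf("  exposure %.4g s, %d frames\n", x$exposure, x$n_frames))
  cat(sprintf("  z-interval %.4g um, z-range %.4g um\n", x$z_interval, x$z_range))
  cat(sprintf("  stage travel %.4g um, detection travel %.4g um\n",
              x$stage_travel, x$detect_travel))
  invisible(x)
}

#' Optical displacement of the sheet focus inside the medium
#'
#' Translating the tiling cylindrical lens by `physical_shift` in air moves
#' the sheet focus by `physical_shift * n` inside a medium of refractive
#' index `n` (e.g. 500 um physical becomes about 760 um in CUBIC-R at
#' n = 1.52).
#'
#' @param physical_shift lens translation in air, um, `>= 0`.
#' @param n medium refractive index.
#' @return in-medium focus displacement, um.
#' @export
tile_displacement_in_medium <- function(physical_shift, n) {
  physical_shift <- as.numeric(physical_shift)
  if (any(physical_shift < 0)) stop("'physical_shift' must be >= 0")
  if (any(n < 1)) stop("refractive index must be >= 1")
  physical_shift * n
}

#' Scale an effective numerical aperture between cylindrical lenses
#'
#' For sheet-forming cylindrical lenses the effective NA ratio equals the
#' focal-length ratio, so a reference NA at focal length `f_ref` maps to
#' `na_ref * f_ref / f_target` at `f_target`.
#'
#' @param na_ref reference effective NA (dimensionless).
#' @param f_ref,f_target focal lengths in consistent units (mm customary).
#' @return scaled effective NA.
#' @examples
#' scale_effective_na(0.033, 150, 500)  # ~0.01
#' @export
scale_effective_na <- function(na_ref, f_ref, f_target) {
  vals <- c(na_ref, f_ref, f_target)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all arguments must be positive (zero focal length is not physical)")
  na_ref * f_ref / f_target
}
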