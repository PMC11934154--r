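#' Acquisition metadata for a D-OCT time series
#'
#' Bundles the sampling and geometry parameters of a repeated-B-scan
#' acquisition: the B-scan repetition (frame) rate, number of repeated frames,
#' pixel pitches, raster size, tissue refractive index, and the y spacing
#' between B-scan positions for volumetric datasets.
#'
#' Defaults reproduce a typical spectral-domain OCT protocol for spheroid
#' imaging: 512 frames at 56 frames/s, 2.53 um isotropic pixels, 660 x 660
#' cropped B-scans, refractive index 1.38.
#'
#' @param frame_rate B-scan repetition rate in Hz. Must be > 0.
#' @param n_frames Number of repeated frames (time points). Must be >= 2.
#' @param pixel_axial Axial (z) pixel pitch in micrometres.
#' @param pixel_lateral Lateral (x) pixel pitch in micrometres.
#' @param n_axial Pixels per A-scan (depth) after any cropping.
#' @param n_lateral A-scans per B-scan (lateral).
#' @param refractive_index Bulk tissue refractive index, >= 1.
#' @param y_spacing Spacing between adjacent B-scan positions in micrometres.
#' @return An object of class `doct_meta`.
#' @examples
#' meta <- acquisition_meta()
#' nyquist_limit(meta)
#' @export
acquisition_meta <- function(frame_rate = 56, n_frames = 512,
                             pixel_axial = 2.53, pixel_lateral = 2.53,
                             n_axial = 660, n_lateral = 660,
                             refractive_index = 1.38, y_spacing = 2.53) {
  stopifnot(is.numeric(frame_rate), length(frame_rate) == 1, frame_rate > 0)
  stopifnot(is.numeric(n_frames), length(n_frames) == 1, n_frames >= 2)
  if (pixel_axial <= 0 || pixel_lateral <= 0)
    stop("pixel sizes must be positive")
  if (refractive_index < 1)
    stop("refractive_index must be >= 1")
  if (n_axial < 1 || n_lateral < 1)
    stop("pixel counts must be positive")
  if (y_spacing <= 0)
    stop("y_spacing must be positive")
  structure(list(frame_rate = as.numeric(frame_rate),
                 n_frames = as.integer(n_frames),
                 pixel_axial = as.numeric(pixel_axial),
                 pixel_lateral = as.numeric(pixel_lateral),
                 n_axial = as.integer(n_axial),
                 n_lateral = as.integer(n_lateral),
                 refractive_index = as.numeric(refractive_index),
                 y_spacing = as.numeric(y_spacing)),
            class = "doct_meta")
}

#' @export
print.doct_meta <- function(x, ...) {
  cat("D-OCT acquisition metadata\n")
  cat(sprintf("  frame rate       : %g Hz (%d frames, %.2f s, Nyquist %g Hz)\n",
              x$frame_rate, x$n_frames, x$n_frames / x$frame_rate,
              nyquist_limit(x)))
  fov <- field_of_view(x)
  cat(sprintf("  raster           : %d (z) x %d (x) px at %g x %g um\n",
              x$n_axial, x$n_lateral, x$pixel_axial, x$pixel_lateral))
  cat(sprintf("  field of view    : %.2f mm (x) x %.2f mm (z)\n",
              fov[["lateral_mm"]], fov[["axial_mm"]]))
  cat(sprintf("  refractive index : %g; y spacing %g um\n",
              x$refractive_index, x$y_spacing))
  invisible(x)
}

#' Nyquist frequency of the acquisition
#'
#' The highest cell-motion frequency measurable without aliasing: half the
#' B-scan frame rate. A 56 frames/s acquisition detects motion in 0-28 Hz.
#'
#' @param meta An [acquisition_meta()] object, or a bare numeric frame rate
#'   in Hz.
#' @return Frequency in Hz.
#' @export
nyquist_limit <- function(meta) {
  fr <- if (inherits(meta, "doct_meta")) meta$frame_rate else as.numeric(meta)
  stopifnot(fr > 0)
  fr / 2
}

#' Minimum sampling rate for a given motion bandwidth
#'
#' The Shannon bound: to resolve motion up to `max_motion_freq`, the frame
#' rate must be at least twice that frequency. Cellular motion below 20 Hz
#' therefore requires at least 40 frames/s.
#'
#' @param max_motion_freq Highest motion frequency of interest, Hz (> 0).
#' @return Minimum frame rate in Hz.
#' @export
required_sampling_rate <- function(max_motion_freq) {
  stopifnot(is.numeric(max_motion_freq), max_motion_freq > 0)
  2 * max_motion_freq
}

#' Axial resolution inside tissue
#'
#' OCT axial resolution is specified in air; inside a medium of refractive
#' index n the optical path is compressed, so the in-tissue resolution is the
#' in-air value divided by n (3.5 um in air at n = 1.38 gives 2.53 um).
#'
#' @param air_resolution Axial resolution measured in air, micrometres (> 0).
#' @param refractive_index Tissue refractive index (> 0).
#' @return Resolution in micrometres.
#' @export
tissue_axial_resolution <- function(air_resolution, refractive_index) {
  stopifnot(air_resolution > 0, refractive_index > 0)
  air_resolution / refractive_index
}

#' Time between consecutive frames
#'
#' @param meta An [acquisition_meta()] object or numeric frame rate in Hz.
#' @return Frame interval in milliseconds.
#' @export
frame_interval_ms <- function(meta) {
  fr <- if (inherits(meta, "doct_meta")) meta$frame_rate else as.numeric(meta)
  stopifnot(fr > 0)
  1000 / fr
}

#' B-scan field of view
#'
#' Physical extent of one B-scan: lateral = A-scans x lateral pitch, axial =
#' A-scan depth pixels x axial pitch, both returned in millimetres.
#'
#' @param meta An [acquisition_meta()] object.
#' @return Named numeric vector `c(lateral_mm, axial_mm)`.
#' @export
field_of_view <- function(meta) {
  stopifnot(inherits(meta, "doct_meta"))
  c(lateral_mm = meta$n_lateral * meta$pixel_lateral / 1000,
    axial_mm = meta$n_axial * meta$pixel_axial / 1000)
}
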