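#' Pseudo-color mapping specification
#'
#' Parameters of the HSV composite: `fmean` in `[f_lo, f_hi]` Hz maps
#' linearly (with clamping) to hue `[0, hue_max]` — red at low frequency
#' through green to blue at high frequency; the reciprocal of the spectral
#' bandwidth `fstd` drives saturation; the temporal amplitude `STD` drives
#' value. Saturation and value are scaled robustly to `[0, 1]` by clipping at
#' a percentile of their positive entries, which resists hot-pixel outliers.
#'
#' @param f_lo Hue range lower frequency, Hz (default 8).
#' @param f_hi Hue range upper frequency, Hz (default 13).
#' @param hue_max Hue at `f_hi`, in (0, 1] (default 0.66, i.e. blue).
#' @param sat_norm Percentile (0, 100] for the 1/fstd scaling (default 99).
#' @param val_norm Percentile (0, 100] for the STD scaling (default 99).
#' @return Object of class `doct_colormap`.
#' @export
colormap_spec <- function(f_lo = 8, f_hi = 13, hue_max = 0.66,
                          sat_norm = 99, val_norm = 99) {
  stopifnot(f_lo < f_hi, hue_max > 0, hue_max <= 1,
            sat_norm > 0, sat_norm <= 100, val_norm > 0, val_norm <= 100)
  structure(list(f_lo = f_lo, f_hi = f_hi, hue_max = hue_max,
                 sat_norm = sat_norm, val_norm = val_norm),
            class = "doct_colormap")
}

#' Hue of a mean frequency
#'
#' Clamps `fmean` to `[f_lo, f_hi]` and maps it linearly to `[0, hue_max]`:
#' 8 Hz -> 0 (red), 13 Hz -> 0.66 (blue) at the defaults.
#'
#' @param fmean Mean frequency (Hz); vectorized.
#' @param spec A [colormap_spec()].
#' @return Hue values in `[0, hue_max]`.
#' @export
hue_of <- function(fmean, spec = colormap_spec()) {
  stopifnot(inherits(spec, "doct_colormap"))
  f <- pmin(pmax(fmean, spec$f_lo), spec$f_hi)
  (f - spec$f_lo) / (spec$f_hi - spec$f_lo) * spec$hue_max
}

.percentile_scale <- function(x, pct) {
  pos <- x[x > 0]
  if (length(pos) == 0) return(x * 0)
  q <- as.numeric(quantile(pos, pct / 100, names = FALSE))
  if (q <= 0) return(x * 0)
  pmin(pmax(x / q, 0), 1)
}

#' Render an HSV pseudo-color image of the dynamics maps
#'
#' Hue encodes the mean frequency ([hue_of()]), saturation the reciprocal
#' spectral bandwidth `1/fstd` (narrowband cellular fluctuation saturates;
#' broadband noise desaturates; degenerate pixels with `fstd = 0` get
#' saturation 0), and value the temporal amplitude `STD`. Saturation and
#' value are percentile-normalized and clipped to `[0, 1]`, then the HSV
#' triple is converted to RGB by the standard hexcone transform. With the
#' default map, highly viable tissue renders red-yellow (low frequency, high
#' amplitude) and necrotic tissue blue-green (high frequency, low amplitude).
#'
#' @param maps A `doct_maps` object.
#' @param spec A [colormap_spec()].
#' @param mask Optional binary raster; pixels outside are set to black.
#' @return Numeric array `(rows, cols, 3)` of RGB values in `[0, 1]`.
#' @export
render_pseudocolor <- function(maps, spec = colormap_spec(), mask = NULL) {
  stopifnot(inherits(maps, "doct_maps"), inherits(spec, "doct_colormap"))
  h <- hue_of(maps$fmean, spec)
  recip <- ifelse(maps$fstd > 0, 1 / maps$fstd, 0)
  s <- .percentile_scale(recip, spec$sat_norm)
  v <- .percentile_scale(maps$std, spec$val_norm)
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(maps$fmean)))
    v[mask == 0] <- 0
  }
  cols <- col2rgb(hsv(as.vector(h), as.vector(s), as.vector(v))) / 255
  rgb <- array(0, c(nrow(maps$fmean), ncol(maps$fmean), 3))
  rgb[, , 1] <- cols[1, ]
  rgb[, , 2] <- cols[2, ]
  rgb[, , 3] <- cols[3, ]
  rgb
}
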