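#' Welch estimator parameters
#'
#' Settings for the per-pixel averaged-periodogram (Welch) power spectral
#' density. Defaults: 256-frame segments with 50% overlap and a Hann taper,
#' giving a frequency resolution of `frame_rate / 256` (about 0.22 Hz at
#' 56 frames/s) and, for a 512-frame series, three averaged segments.
#' `detrend` subtracts each pixel's temporal mean before segmentation, which
#' removes the dominant DC component so the spectral centroid reflects the
#' fluctuation spectrum rather than the static backscatter level.
#'
#' @param segment_length Frames per segment (even, >= 8).
#' @param overlap Fractional overlap between segments, in `[0, 1)`.
#' @param window Taper: "hann", "hamming" or "rectangular".
#' @param detrend Subtract the per-pixel temporal mean first? Default TRUE.
#' @return An object of class `welch_params`.
#' @export
welch_params <- function(segment_length = 256, overlap = 0.5,
                         window = c("hann", "hamming", "rectangular"),
                         detrend = TRUE) {
  window <- match.arg(window)
  stopifnot(segment_length >= 8, segment_length %% 2 == 0,
            overlap >= 0, overlap < 1, is.logical(detrend))
  structure(list(segment_length = as.integer(segment_length),
                 overlap = as.numeric(overlap), window = window,
                 detrend = detrend),
            class = "welch_params")
}

.taper <- function(name, L) {
  n <- 0:(L - 1)
  switch(name,
         hann = 0.5 - 0.5 * cos(2 * pi * n / L),
         hamming = 0.54 - 0.46 * cos(2 * pi * n / L),
         rectangular = rep(1, L))
}

#' Canonical one-sided frequency grid
#' @param frame_rate Sampling rate in Hz.
#' @param segment_length Welch segment length (even).
#' @return Frequencies 0 .. frame_rate/2 with spacing frame_rate/segment_length.
#' @export
welch_freqs <- function(frame_rate, segment_length) {
  seq(0, segment_length / 2) * frame_rate / segment_length
}

# Welch PSD of every column of X (time x pixels), one-sided density scaling.
# Serial accumulation over segments in fixed order keeps results independent
# of how pixels are grouped (bitwise chunking invariance).
.welch_psd_mat <- function(X, fs, params) {
  T_ <- nrow(X)
  L <- params$segment_length
  if (T_ < L)
    stop(sprintf("series length %d shorter than segment_length %d", T_, L))
  if (params$detrend)
    X <- X - rep(colMeans(X), each = T_)
  step <- max(1L, as.integer(round(L * (1 - params$overlap))))
  starts <- seq.int(1L, T_ - L + 1L, by = step)
  w <- .taper(params$window, L)
  U <- sum(w^2)
  M <- L / 2 + 1
  acc <- matrix(0, M, ncol(X))
  for (s in starts) {
    seg <- X[s:(s + L - 1L), , drop = FALSE] * w
    F <- stats::mvfft(seg)
    acc <- acc + Mod(F[seq_len(M), , drop = FALSE])^2
  }
  P <- acc / (length(starts) * fs * U)
  if (M > 2) P[2:(M - 1), ] <- 2 * P[2:(M - 1), ]
  P
}

#' Per-pixel Welch power spectral density
#'
#' Estimates the one-sided PSD of a single pixel's intensity time series on
#' the canonical frequency grid `0 .. frame_rate/2`.
#'
#' @param series Numeric vector of length `meta$n_frames`.
#' @param meta An [acquisition_meta()] object (supplies the frame rate).
#' @param params A [welch_params()] object.
#' @return Object of class `doct_psd`: list with `freqs` (Hz) and `psd`
#'   (intensity^2/Hz), both of length `segment_length/2 + 1`.
#' @export
pixel_psd <- function(series, meta, params = welch_params()) {
  stopifnot(inherits(meta, "doct_meta"), inherits(params, "welch_params"))
  if (length(series) != meta$n_frames)
    stop(sprintf("series length %d != meta$n_frames %d",
                 length(series), meta$n_frames))
  P <- .welch_psd_mat(matrix(series, ncol = 1), meta$frame_rate, params)
  structure(list(freqs = welch_freqs(meta$frame_rate, params$segment_length),
                 psd = as.numeric(P)),
            class = "doct_psd")
}

#' @export
print.doct_psd <- function(x, ...) {
  cat(sprintf("one-sided PSD: %d bins, 0-%g Hz, fmean = %.3f Hz\n",
              length(x$freqs), max(x$freqs), mean_frequency(x)))
  invisible(x)
}

.as_spectrum <- function(spectrum) {
  if (inherits(spectrum, "doct_psd")) return(spectrum)
  stopifnot(is.list(spectrum), !is.null(spectrum$freqs), !is.null(spectrum$psd),
            length(spectrum$freqs) == length(spectrum$psd))
  spectrum
}

#' Mean (centroid) frequency of a power spectrum
#'
#' The PSD-weighted average frequency
#' `sum_i (P_i / sum_j P_j) * f_i` — the quantity mapped per pixel to contrast
#' viable (low `fmean`) against necrotic (high `fmean`) tissue. A spectrum
#' with zero total power returns 0 by convention (degenerate pixel).
#'
#' @param spectrum A `doct_psd` or list with `freqs` and `psd`.
#' @return Frequency in Hz.
#' @export
mean_frequency <- function(spectrum) {
  s <- .as_spectrum(spectrum)
  tot <- sum(s$psd)
  if (tot <= 0) return(0)
  sum(s$psd * s$freqs) / tot
}

#' Spectral bandwidth (PSD-weighted frequency standard deviation)
#'
#' `sqrt( sum w_i f_i^2 - (sum w_i f_i)^2 )` with `w_i = P_i / sum P`. The
#' reciprocal of this bandwidth drives the saturation channel of the
#' pseudo-color rendering: narrowband fluctuation saturates, broadband noise
#' desaturates. Zero total power returns 0. Small negative radicands (to
#' -1e-9) from rounding are clamped to 0; larger ones raise an error.
#'
#' @inheritParams mean_frequency
#' @return Bandwidth in Hz.
#' @export
frequency_std <- function(spectrum) {
  s <- .as_spectrum(spectrum)
  tot <- sum(s$psd)
  if (tot <= 0) return(0)
  w <- s$psd / tot
  m1 <- sum(w * s$freqs)
  rad <- sum(w * s$freqs^2) - m1^2
  if (rad < -1e-9) stop(sprintf("negative spectral variance: %g", rad))
  sqrt(max(rad, 0))
}

#' Per-pixel temporal standard deviation map
#'
#' Population (1/N) standard deviation of each pixel's intensity over time —
#' the fluctuation-amplitude map used as the value channel of the
#' pseudo-color rendering.
#'
#' @param stack A [doct_stack()] (or 3D array, time leading).
#' @return Numeric matrix `(n_axial, n_lateral)`.
#' @export
intensity_std <- function(stack) {
  d <- dim(stack)
  stopifnot(length(d) == 3, d[1] >= 2)
  X <- matrix(stack, d[1], d[2] * d[3])
  mu <- colMeans(X)
  v <- colMeans(X^2) - mu^2
  matrix(sqrt(pmax(v, 0)), d[2], d[3])
}

#' Normalize each frame by its spatial mean intensity
#'
#' Divides every frame by its own spatial mean, suppressing frame-to-frame
#' illumination instability and common-mode motion artifacts; each output
#' frame has spatial mean exactly 1 (to floating tolerance).
#'
#' @param stack A [doct_stack()].
#' @return A normalized [doct_stack()].
#' @export
normalize_frames <- function(stack) {
  stopifnot(inherits(stack, "doct_stack"))
  d <- dim(stack)
  X <- matrix(stack, d[1], d[2] * d[3])
  mu <- rowMeans(X)
  bad <- which(mu <= 0)
  if (length(bad) > 0)
    stop(sprintf("frame %d has non-positive spatial mean (%g)",
                 bad[1], mu[bad[1]]))
  out <- array(X / mu, d)
  doct_stack(out, stack_meta(stack))
}

# 3x3 Gaussian convolution with replicate padding. With sigma = 3 the taps
# are nearly uniform; the heavy truncation is intentional (stated filter).
.gauss3x3 <- function(m, sigma = 3) {
  off <- c(-1, 0, 1)
  k <- outer(off, off, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  ri <- function(i) pmin(pmax(i, 1L), nr)
  ci <- function(j) pmin(pmax(j, 1L), nc)
  out <- matrix(0, nr, nc)
  for (a in 1:3) for (b in 1:3) {
    out <- out + k[a, b] * m[ri(seq_len(nr) + off[a]), ci(seq_len(nc) + off[b])]
  }
  out
}

#' Compute the fmean / fstd / STD dynamics maps of a cross-section
#'
#' Runs the per-pixel Welch PSD over the whole stack and reduces each
#' spectrum to its centroid frequency (`fmean`), spectral bandwidth (`fstd`)
#' and temporal amplitude (`STD`). Optionally the `fmean` raster is smoothed
#' afterwards with a 3x3 Gaussian (sigma = 3, replicate-padded) to suppress
#' aberrant single-pixel values; `fstd` and `STD` are left unsmoothed.
#'
#' `n_chunks` splits the raster spatially (1, 4 = 2x2 or 9 = 3x3 tiles) the
#' way a parallel implementation would; because every pixel is reduced
#' serially and independently, any chunking yields bitwise-identical maps
#' (asserted in the test suite), so it is a contract knob rather than a
#' performance one in this implementation.
#'
#' @param stack A [doct_stack()].
#' @param params A [welch_params()].
#' @param smooth Smooth the fmean map (3x3 Gaussian, sigma = `smooth_sigma`)?
#' @param smooth_sigma Gaussian sigma of the 3x3 kernel, default 3.
#' @param n_chunks Spatial tiling: 1, 4 or 9.
#' @param normalize Apply [normalize_frames()] first? Default TRUE.
#' @return Object of class `doct_maps`: list with matrices `fmean`, `fstd`
#'   (Hz), `std` (intensity), `freqs`, `params`, `meta`.
#' @export
compute_dynamics_maps <- function(stack, params = welch_params(),
                                  smooth = TRUE, smooth_sigma = 3,
                                  n_chunks = 1, normalize = TRUE) {
  stopifnot(inherits(stack, "doct_stack"), inherits(params, "welch_params"))
  if (!n_chunks %in% c(1, 4, 9))
    stop("n_chunks must be 1, 4 or 9")
  if (normalize) stack <- normalize_frames(stack)
  m <- stack_meta(stack)
  d <- dim(stack)
  X <- matrix(stack, d[1], d[2] * d[3])
  freqs <- welch_freqs(m$frame_rate, params$segment_length)

  k <- as.integer(sqrt(n_chunks))
  npix <- d[2] * d[3]
  fmean_v <- numeric(npix); fstd_v <- numeric(npix)
  # tile the (z, x) raster into k x k blocks of columns/rows
  tile <- function(n) {
    if (k == 1) return(list(seq_len(n)))
    unname(split(seq_len(n), ceiling(seq_len(n) / (n / k))))
  }
  zb <- tile(d[2])
  xb <- tile(d[3])
  for (bx in xb) for (bz in zb) {
    idx <- as.vector(outer(bz, (bx - 1L) * d[2], `+`))
    P <- .welch_psd_mat(X[, idx, drop = FALSE], m$frame_rate, params)
    tot <- colSums(P)
    m1 <- colSums(P * freqs)
    m2 <- colSums(P * freqs^2)
    ok <- tot > 0
    fm <- numeric(length(idx)); fs <- numeric(length(idx))
    fm[ok] <- m1[ok] / tot[ok]
    fs[ok] <- sqrt(pmax(m2[ok] / tot[ok] - fm[ok]^2, 0))
    fmean_v[idx] <- fm
    fstd_v[idx] <- fs
  }
  fmean <- matrix(fmean_v, d[2], d[3])
  fstd <- matrix(fstd_v, d[2], d[3])
  std <- intensity_std(stack)
  if (smooth) fmean <- .gauss3x3(fmean, sigma = smooth_sigma)
  structure(list(fmean = fmean, fstd = fstd, std = std,
                 freqs = freqs, params = params, meta = m,
                 smoothed = smooth),
            class = "doct_maps")
}

#' @export
print.doct_maps <- function(x, ...) {
  cat(sprintf("D-OCT dynamics maps (%d x %d px)\n",
              nrow(x$fmean), ncol(x$fmean)))
  cat(sprintf("  fmean: [%.2f, %.2f] Hz%s\n", min(x$fmean), max(x$fmean),
              if (isTRUE(x$smoothed)) " (smoothed)" else ""))
  cat(sprintf("  fstd : [%.2f, %.2f] Hz\n", min(x$fstd), max(x$fstd)))
  cat(sprintf("  STD  : [%.4g, %.4g]\n", min(x$std), max(x$std)))
  invisible(x)
}

#' @export
summary.doct_maps <- function(object, ...) {
  s <- function(m) c(min = min(m), mean = mean(m), max = max(m))
  out <- rbind(fmean = s(object$fmean), fstd = s(object$fstd),
               std = s(object$std))
  class(out) <- c("summary.doct_maps", class(out))
  out
}

#' Plot dynamics maps as a pseudo-color image
#'
#' Renders the HSV pseudo-color composite (see [render_pseudocolor()]).
#'
#' @param x A `doct_maps` object.
#' @param spec A [colormap_spec()].
#' @param mask Optional binary matrix; pixels outside are black.
#' @param ... Unused.
#' @export
plot.doct_maps <- function(x, spec = colormap_spec(), mask = NULL, ...) {
  rgb <- render_pseudocolor(x, spec, mask)
  op <- par(mar = c(0.5, 0.5, 1.5, 0.5))
  on.exit(par(op))
  plot(0, 0, type = "n", xlim = c(0, 1), ylim = c(0, 1), axes = FALSE,
       xlab = "", ylab = "", main = "D-OCT pseudo-color (hue = fmean)",
       asp = ncol(x$fmean) / nrow(x$fmean))
  rasterImage(rgb, 0, 0, 1, 1)
  invisible(rgb)
}
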