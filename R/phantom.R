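#' Temporal process of one phantom layer
#'
#' Statistical model of the intensity fluctuation inside one tissue layer.
#' `band_tones` sums equal-amplitude random-phase cosines at every frequency
#' of the acquisition grid inside `band`, giving an exactly band-limited
#' spectrum whose centroid is the band midpoint — ideal for crisp analytic
#' checks. `ar1_plus_white` is a first-order autoregressive process (a
#' Lorentzian-shaped low-pass spectrum, more speckle-like) with coefficient
#' `ar_coef`. Both can carry an additional flat white component of standard
#' deviation `white_floor`.
#'
#' @param kind "band_tones" or "ar1_plus_white".
#' @param band Length-2 frequency band `[f1, f2]` in Hz (band_tones).
#' @param fluctuation_amplitude Standard deviation of the relative intensity
#'   fluctuation (dimensionless, multiplies the layer reflectivity).
#' @param white_floor Standard deviation of the flat white component.
#' @param ar_coef AR(1) coefficient in (0, 1) (ar1_plus_white).
#' @return Object of class `layer_process`.
#' @export
layer_process <- function(kind = c("band_tones", "ar1_plus_white"),
                          band = c(8, 9.5), fluctuation_amplitude = 0.3,
                          white_floor = 0, ar_coef = 0.6) {
  kind <- match.arg(kind)
  stopifnot(length(band) == 2, band[1] >= 0, band[1] < band[2],
            fluctuation_amplitude >= 0, white_floor >= 0,
            ar_coef > 0, ar_coef < 1)
  structure(list(kind = kind, band = as.numeric(band),
                 fluctuation_amplitude = fluctuation_amplitude,
                 white_floor = white_floor, ar_coef = ar_coef),
            class = "layer_process")
}

#' Analytic expected mean frequency of a layer process
#'
#' Evaluates the closed-form power spectrum of a [layer_process()] on a
#' frequency grid and returns its centroid — the ground-truth `fmean` the
#' pipeline should recover for pixels of that layer. The DC bin carries zero
#' weight, matching the temporal-mean removal applied before spectral
#' estimation. For `band_tones` with a negligible white floor this is the
#' mean of the grid frequencies inside the band (≈ the band midpoint); for
#' `ar1_plus_white` it is the centroid of the AR(1) Lorentzian plus flat
#' floor, computed by direct summation.
#'
#' @param process A [layer_process()].
#' @param frame_rate Sampling rate in Hz.
#' @param grid Frequency grid in Hz; defaults to the acquisition grid of a
#'   512-frame series.
#' @return Expected mean frequency in Hz.
#' @export
expected_fmean <- function(process, frame_rate,
                           grid = welch_freqs(frame_rate, 512)) {
  stopifnot(inherits(process, "layer_process"))
  w <- .process_psd_weights(process, frame_rate, grid)
  if (sum(w) <= 0) return(0)
  sum(w * grid) / sum(w)
}

# Relative one-sided PSD weights of a layer process on `grid` (DC excluded).
.process_psd_weights <- function(process, frame_rate, grid) {
  w <- numeric(length(grid))
  nz <- grid > 0
  amp2 <- process$fluctuation_amplitude^2
  if (process$kind == "band_tones") {
    inband <- nz & grid >= process$band[1] & grid <= process$band[2]
    if (any(inband)) w[inband] <- w[inband] + amp2 / sum(inband)
  } else {
    phi <- process$ar_coef
    lor <- 1 / (1 - 2 * phi * cos(2 * pi * grid[nz] / frame_rate) + phi^2)
    w[nz] <- w[nz] + amp2 * lor / sum(lor)
  }
  wf2 <- process$white_floor^2
  if (wf2 > 0 && any(nz)) w[nz] <- w[nz] + wf2 / sum(nz)
  w
}

#' Synthetic spheroid phantom specification
#'
#' Geometry and temporal statistics of a layered-ellipsoid phantom emulating
#' a D-OCT acquisition of a cell spheroid: a viable shell with strong,
#' narrowband, low-frequency fluctuations; a necrotic core with weaker,
#' higher-frequency fluctuations; dim background with detector noise; and an
#' optional thin specular edge ring carrying broadband fluctuation at the
#' spheroid/medium interface. Defaults mirror a typical acquisition
#' (660 x 660 px at 2.53 um, 512 frames at 56 Hz, 450 um spheroid diameter)
#' and the observed fluctuation bands of fully viable (8-9.5 Hz) and fully
#' necrotic (11.5-13 Hz) spheroids.
#'
#' @param shape Raster size: `c(n_z, n_x)` or `c(n_y, n_z, n_x)` pixels.
#' @param center Ellipsoid center in pixel coordinates (same length as
#'   `shape`); defaults to the raster center.
#' @param outer_radii_um Outer (spheroid) semi-axes in micrometres, recycled
#'   to the number of axes.
#' @param core_radii_um Necrotic-core semi-axes in micrometres (0 = fully
#'   viable), recycled likewise; must fit inside the outer ellipsoid.
#' @param pixel_pitch_um Isotropic pixel pitch in micrometres.
#' @param frame_rate Frame rate in Hz.
#' @param n_frames Number of frames (even, >= 2).
#' @param viable_process,necrotic_process [layer_process()] objects.
#' @param background_noise_sd Additive white detector noise SD (intensity).
#' @param edge_ring List `(enabled, width, amplitude)`: a `width`-pixel shell
#'   at the outer boundary with white broadband fluctuation of SD
#'   `amplitude`.
#' @param base_reflectivity Named vector with entries `background`, `viable`,
#'   `necrotic`, `edge`: mean static reflectivity per layer.
#' @param speckle_sdlog Log-SD of the static multiplicative per-pixel
#'   speckle texture (lognormal, median 1).
#' @param seed Integer RNG seed; fixes the phantom bitwise.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(660, 660), center = NULL,
                         outer_radii_um = 225, core_radii_um = 112.5,
                         pixel_pitch_um = 2.53, frame_rate = 56,
                         n_frames = 512,
                         viable_process = layer_process(
                           "band_tones", band = c(8, 9.5),
                           fluctuation_amplitude = 0.35, white_floor = 0.005),
                         necrotic_process = layer_process(
                           "band_tones", band = c(11.5, 13),
                           fluctuation_amplitude = 0.2, white_floor = 0.005),
                         background_noise_sd = 0.02,
                         edge_ring = list(enabled = TRUE, width = 3,
                                          amplitude = 0.3),
                         base_reflectivity = c(background = 0.02, viable = 1,
                                               necrotic = 0.6, edge = 1),
                         speckle_sdlog = 0.25, seed = 1L) {
  stopifnot(length(shape) %in% c(2, 3), all(shape >= 4),
            n_frames >= 2, n_frames %% 2 == 0, frame_rate > 0,
            pixel_pitch_um > 0,
            inherits(viable_process, "layer_process"),
            inherits(necrotic_process, "layer_process"))
  nax <- length(shape)
  outer_radii_um <- rep_len(outer_radii_um, nax)
  core_radii_um <- rep_len(core_radii_um, nax)
  if (any(core_radii_um > outer_radii_um))
    stop("core radii exceed the outer ellipsoid")
  if (is.null(center)) center <- (shape + 1) / 2
  stopifnot(length(center) == nax)
  er <- modifyList(list(enabled = TRUE, width = 3, amplitude = 0.3),
                   as.list(edge_ring))
  need <- c("background", "viable", "necrotic", "edge")
  stopifnot(all(need %in% names(base_reflectivity)))
  structure(list(shape = as.integer(shape), center = as.numeric(center),
                 outer_radii_um = outer_radii_um,
                 core_radii_um = core_radii_um,
                 pixel_pitch_um = pixel_pitch_um, frame_rate = frame_rate,
                 n_frames = as.integer(n_frames),
                 viable_process = viable_process,
                 necrotic_process = necrotic_process,
                 background_noise_sd = background_noise_sd,
                 edge_ring = er,
                 base_reflectivity = base_reflectivity[need],
                 speckle_sdlog = speckle_sdlog, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Ground-truth label raster for one 2D cross-section.
# 0 background, 1 viable shell, 2 necrotic core, 3 edge ring.
.phantom_labels_2d <- function(n_z, n_x, center_zx, outer_zx_um, core_zx_um,
                               pitch, edge_ring) {
  z <- matrix(seq_len(n_z), n_z, n_x)
  x <- matrix(seq_len(n_x), n_z, n_x, byrow = TRUE)
  dz <- (z - center_zx[1]) * pitch
  dx <- (x - center_zx[2]) * pitch
  inside <- function(rz, rx) {
    if (rz <= 0 || rx <= 0) return(matrix(FALSE, n_z, n_x))
    (dz / rz)^2 + (dx / rx)^2 <= 1
  }
  outer <- inside(outer_zx_um[1], outer_zx_um[2])
  core <- inside(core_zx_um[1], core_zx_um[2])
  lab <- matrix(0L, n_z, n_x)
  lab[outer] <- 1L
  lab[core & outer] <- 2L
  if (isTRUE(edge_ring$enabled)) {
    w_um <- edge_ring$width * pitch
    inner <- inside(outer_zx_um[1] - w_um, outer_zx_um[2] - w_um)
    lab[outer & !inner] <- 3L
  }
  lab
}

# Fluctuation matrix (n_frames x n_pixels) for one layer process.
.layer_fluct <- function(process, n_pix, n_frames, frame_rate) {
  tt <- (0:(n_frames - 1)) / frame_rate
  FL <- matrix(0, n_frames, n_pix)
  amp <- process$fluctuation_amplitude
  if (amp > 0) {
    if (process$kind == "band_tones") {
      grid <- welch_freqs(frame_rate, n_frames)
      fk <- grid[grid > 0 & grid >= process$band[1] & grid <= process$band[2]]
      if (length(fk) == 0)
        stop("band_tones band contains no grid frequency")
      a <- amp * sqrt(2 / length(fk))
      for (f in fk) {
        phi <- runif(n_pix, 0, 2 * pi)
        ang <- 2 * pi * f * tt
        FL <- FL + a * (outer(cos(ang), cos(phi)) - outer(sin(ang), sin(phi)))
      }
    } else {
      burn <- 64L
      phi <- process$ar_coef
      innov_sd <- amp * sqrt(1 - phi^2)
      e <- matrix(rnorm((n_frames + burn) * n_pix, sd = innov_sd),
                  n_frames + burn, n_pix)
      ar <- stats::filter(e, phi, method = "recursive")
      FL <- matrix(ar[(burn + 1):(burn + n_frames), ], n_frames, n_pix)
    }
  }
  if (process$white_floor > 0)
    FL <- FL + matrix(rnorm(n_frames * n_pix, sd = process$white_floor),
                      n_frames, n_pix)
  FL
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.generate_phantom_2d <- function(spec, seed, meta_shape = NULL) {
  n_z <- spec$shape[length(spec$shape) - 1]
  n_x <- spec$shape[length(spec$shape)]
  if (!is.null(meta_shape)) { n_z <- meta_shape[1]; n_x <- meta_shape[2] }
  ctr <- utils::tail(spec$center, 2)
  lab <- .phantom_labels_2d(n_z, n_x, ctr,
                            utils::tail(spec$outer_radii_um, 2),
                            utils::tail(spec$core_radii_um, 2),
                            spec$pixel_pitch_um, spec$edge_ring)
  .generate_from_labels(spec, lab, seed)
}

# Shared generation core: labels -> stack (RNG must already be seeded
# deterministically by the caller via .with_seed).
.generate_from_labels_raw <- function(spec, lab) {
  n_z <- nrow(lab); n_x <- ncol(lab)
  T_ <- spec$n_frames
  npix <- n_z * n_x
  refl <- spec$base_reflectivity
  texture <- rlnorm(npix, meanlog = 0, sdlog = spec$speckle_sdlog)
  base <- refl[c("background", "viable", "necrotic", "edge")][as.vector(lab) + 1L]
  R <- base * texture
  X <- matrix(rep(R, each = T_), T_, npix)
  edge_process <- layer_process("band_tones",
                                fluctuation_amplitude = 0,
                                white_floor = max(spec$edge_ring$amplitude,
                                                  1e-12))
  for (l in 1:3) {
    idx <- which(as.vector(lab) == l)
    if (length(idx) == 0) next
    proc <- switch(l, spec$viable_process, spec$necrotic_process,
                   edge_process)
    FL <- .layer_fluct(proc, length(idx), T_, spec$frame_rate)
    X[, idx] <- X[, idx] * (1 + FL)
  }
  if (spec$background_noise_sd > 0)
    X <- X + matrix(rnorm(T_ * npix, sd = spec$background_noise_sd), T_, npix)
  meta <- acquisition_meta(frame_rate = spec$frame_rate, n_frames = T_,
                           pixel_axial = spec$pixel_pitch_um,
                           pixel_lateral = spec$pixel_pitch_um,
                           n_axial = n_z, n_lateral = n_x,
                           y_spacing = spec$pixel_pitch_um)
  doct_stack(array(X, c(T_, n_z, n_x)), meta)
}

.generate_from_labels <- function(spec, lab, seed) {
  stack <- .with_seed(seed, .generate_from_labels_raw(spec, lab))
  grid <- welch_freqs(spec$frame_rate, spec$n_frames)
  expected <- c(
    viable = expected_fmean(spec$viable_process, spec$frame_rate, grid),
    necrotic = expected_fmean(spec$necrotic_process, spec$frame_rate, grid),
    edge = sum(grid[grid > 0]) / sum(grid > 0))
  structure(list(stack = stack, labels = lab, expected_fmean = expected,
                 spec = spec, seed = seed),
            class = "doct_phantom")
}

#' Generate a synthetic spheroid D-OCT time series
#'
#' Builds the ground-truth label raster from the [phantom_spec()] geometry,
#' then synthesizes each pixel's intensity time series as
#' `reflectivity x (1 + layer fluctuation) + white noise`, where the static
#' reflectivity is the layer base value times a per-pixel lognormal speckle
#' texture. The same seed always reproduces the identical stack.
#'
#' For a 2D `shape` the result holds one cross-section; for a 3D shape, one
#' phantom per y position (the per-slice ellipse radii follow the ellipsoid),
#' with per-slice seeds derived deterministically from the spec seed.
#'
#' @param spec A [phantom_spec()].
#' @return For 2D: object of class `doct_phantom` — list with `stack`
#'   ([doct_stack()]), `labels` (0 background / 1 viable / 2 necrotic /
#'   3 edge ring), `expected_fmean` (analytic per-layer oracle, Hz) and
#'   `spec`. For 3D: class `doct_phantom_volume` — list with `phantoms`
#'   (per-y `doct_phantom` list), `labels` (3D array) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(spec$shape) == 2)
    return(.generate_phantom_2d(spec, spec$seed))
  n_y <- spec$shape[1]
  cy <- spec$center[1]
  ry_out <- spec$outer_radii_um[1]
  ry_core <- spec$core_radii_um[1]
  pitch <- spec$pixel_pitch_um
  phantoms <- vector("list", n_y)
  labels <- array(0L, spec$shape)
  for (y in seq_len(n_y)) {
    dy <- (y - cy) * pitch
    scale_of <- function(r) if (r > 0 && abs(dy) < r) sqrt(1 - (dy / r)^2) else 0
    s_out <- scale_of(ry_out)
    s_core <- scale_of(ry_core)
    slice_spec <- spec
    slice_spec$shape <- spec$shape[2:3]
    slice_spec$center <- spec$center[2:3]
    slice_spec$outer_radii_um <- spec$outer_radii_um[2:3] * s_out
    slice_spec$core_radii_um <- spec$core_radii_um[2:3] * s_core
    phantoms[[y]] <- .generate_phantom_2d(slice_spec,
                                          seed = spec$seed + 131L * y)
    labels[y, , ] <- phantoms[[y]]$labels
  }
  structure(list(phantoms = phantoms, labels = labels, spec = spec),
            class = "doct_phantom_volume")
}

#' @export
print.doct_phantom <- function(x, ...) {
  tb <- table(factor(x$labels, levels = 0:3,
                     labels = c("background", "viable", "necrotic", "edge")))
  cat(sprintf("Synthetic spheroid phantom (%d x %d px, %d frames @ %g Hz, seed %d)\n",
              nrow(x$labels), ncol(x$labels), x$spec$n_frames,
              x$spec$frame_rate, x$seed))
  cat("  pixels:", paste(sprintf("%s %d", names(tb), tb), collapse = ", "), "\n")
  cat(sprintf("  expected fmean: viable %.2f Hz, necrotic %.2f Hz\n",
              x$expected_fmean[["viable"]], x$expected_fmean[["necrotic"]]))
  invisible(x)
}

#' Longitudinal phantom series with a growing necrotic core
#'
#' One phantom per culture day with the core radius following a
#' non-decreasing schedule, emulating the progressive central necrosis of a
#' growing spheroid. Seeds are derived deterministically from the spec seed
#' and the day, so the series is reproducible.
#'
#' @param spec A [phantom_spec()] (2D shape); its `core_radii_um` is
#'   overridden per day.
#' @param days Numeric vector of culture days (non-negative).
#' @param core_radius_schedule Core radius in micrometres per day (same
#'   length as `days`), non-decreasing.
#' @return Named list (by day) of `doct_phantom` objects, each with a `day`
#'   element.
#' @export
growth_series <- function(spec, days, core_radius_schedule) {
  stopifnot(inherits(spec, "phantom_spec"), length(spec$shape) == 2,
            length(days) == length(core_radius_schedule))
  if (length(days) == 0) return(list())
  stopifnot(all(days >= 0), !is.unsorted(days, strictly = TRUE))
  if (is.unsorted(core_radius_schedule))
    stop("core_radius_schedule must be non-decreasing")
  out <- vector("list", length(days))
  for (i in seq_along(days)) {
    sp <- spec
    sp$core_radii_um <- rep_len(core_radius_schedule[i], 2)
    if (any(sp$core_radii_um > sp$outer_radii_um))
      stop("scheduled core radius exceeds the outer ellipsoid")
    ph <- .generate_phantom_2d(sp, seed = spec$seed + 9973L * as.integer(days[i]))
    ph$day <- days[i]
    out[[i]] <- ph
  }
  names(out) <- paste0("day", days)
  out
}
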