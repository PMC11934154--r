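# Shared fixtures and independent oracles for the test suite.

tiny_meta <- function(n_frames = 128, nz = 8, nx = 8, fs = 56) {
  acquisition_meta(frame_rate = fs, n_frames = n_frames,
                   n_axial = nz, n_lateral = nx)
}

rand_stack <- function(seed = 1, n_frames = 128, nz = 8, nx = 8, fs = 56,
                       lo = 0.5, hi = 1.5) {
  set.seed(seed)
  doct_stack(array(runif(n_frames * nz * nx, lo, hi), c(n_frames, nz, nx)),
             tiny_meta(n_frames, nz, nx, fs))
}

jaccard <- function(a, b) {
  a <- a != 0; b <- b != 0
  sum(a & b) / sum(a | b)
}

# Independent direct-DFT one-sided periodogram (density scaling), the oracle
# against which the package's Welch path is checked. Deliberately written
# from the definition, not via the package.
oracle_periodogram <- function(x, fs) {
  n <- length(x)
  X <- fft(x)
  M <- n %/% 2 + 1
  p <- Mod(X[1:M])^2 / (fs * n)
  if (M > 2) p[2:(M - 1)] <- 2 * p[2:(M - 1)]
  list(freqs = (0:(M - 1)) * fs / n, psd = p)
}

# Brute-force spectral moments by explicit loops (independent of the
# vectorized package code).
oracle_moments <- function(freqs, psd) {
  tot <- 0
  for (p in psd) tot <- tot + p
  if (tot == 0) return(c(fmean = 0, fstd = 0))
  m1 <- 0; m2 <- 0
  for (i in seq_along(psd)) {
    m1 <- m1 + psd[i] / tot * freqs[i]
    m2 <- m2 + psd[i] / tot * freqs[i]^2
  }
  c(fmean = m1, fstd = sqrt(max(m2 - m1^2, 0)))
}

# Small two-layer phantom for pipeline tests.
small_phantom <- function(seed = 7, shape = c(64, 64), n_frames = 128,
                          outer = 70, core = 35, edge = FALSE, ...) {
  phantom_spec(shape = shape, outer_radii_um = outer, core_radii_um = core,
               n_frames = n_frames,
               edge_ring = list(enabled = edge, width = 3, amplitude = 0.3),
               seed = seed, ...)
}

# Binary disk raster for constructed segmentation geometry.
disk_mask <- function(nr, nc, cz, cx, r) {
  z <- matrix(seq_len(nr), nr, nc)
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (z - cz)^2 + (x - cx)^2 <= r^2
}
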