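test_that("frame normalization divides each frame by its spatial mean", {
  meta <- tiny_meta(4, 4, 4)
  # constant frames normalize to all ones
  s <- doct_stack(array(7, c(4, 4, 4)), meta)
  expect_equal(as.vector(unclass(normalize_frames(s))), rep(1, 64))
  # same pattern at different overall brightness gives identical frames
  pat <- matrix(runif(16, 1, 2), 4, 4)
  arr <- array(0, c(4, 4, 4))
  for (t in 1:4) arr[t, , ] <- pat * t
  n <- normalize_frames(doct_stack(arr, meta))
  expect_equal(n[1, , ], n[4, , ], tolerance = 1e-13)
  # every output frame has spatial mean exactly 1
  r <- normalize_frames(rand_stack(11, n_frames = 16, nz = 6, nx = 6))
  mus <- apply(unclass(r), 1, mean)
  expect_lt(max(abs(mus - 1)), 1e-12)
})

test_that("a frame with non-positive mean fails naming the frame index", {
  meta <- tiny_meta(3, 2, 2)
  arr <- array(1, c(3, 2, 2))
  arr[2, , ] <- 0
  expect_error(normalize_frames(doct_stack(arr, meta)), "frame 2")
})

test_that("constant series with detrend has an all-zero spectrum", {
  meta <- tiny_meta(128, 2, 2)
  p <- pixel_psd(rep(5, 128), meta, welch_params(segment_length = 128))
  expect_true(all(p$psd == 0))
  expect_equal(mean_frequency(p), 0)
  expect_equal(frequency_std(p), 0)
})

test_that("a sinusoid peaks at the nearest grid frequency", {
  meta <- tiny_meta(512, 2, 2)
  t <- (0:511) / 56
  x <- sin(2 * pi * 10 * t)
  p <- pixel_psd(x, meta, welch_params(segment_length = 256))
  expect_equal(p$freqs[which.max(p$psd)],
               p$freqs[which.min(abs(p$freqs - 10))])
  # and its centroid lands within one bin width of 10 Hz
  expect_lt(abs(mean_frequency(p) - 10), 56 / 256)
})

test_that("full-length rectangular Welch equals the direct periodogram", {
  set.seed(21)
  meta <- tiny_meta(128, 2, 2)
  x <- rnorm(128)
  p <- pixel_psd(x, meta, welch_params(segment_length = 128, overlap = 0,
                                       window = "rectangular"))
  o <- oracle_periodogram(x - mean(x), 56)
  expect_equal(p$freqs, o$freqs)
  expect_equal(p$psd, o$psd, tolerance = 1e-12)
})

test_that("integrated white-noise PSD matches the series variance", {
  set.seed(22)
  meta <- tiny_meta(256, 2, 2)
  x <- rnorm(256, sd = 2)
  for (win in c("rectangular", "hann")) {
    p <- pixel_psd(x, meta, welch_params(segment_length = 256, window = win))
    total <- sum(p$psd) * 56 / 256
    v <- mean((x - mean(x))^2)
    expect_lt(abs(total - v) / v, 0.05)
  }
})

test_that("series shorter than the segment length is rejected", {
  meta <- tiny_meta(64, 2, 2)
  expect_error(pixel_psd(rnorm(64), meta, welch_params(segment_length = 128)),
               "shorter")
})

test_that("spectral moments match brute-force computation on random spectra", {
  set.seed(23)
  freqs <- welch_freqs(56, 64)
  for (i in 1:25) {
    psd <- runif(length(freqs))^2
    s <- list(freqs = freqs, psd = psd)
    o <- oracle_moments(freqs, psd)
    expect_equal(mean_frequency(s), o[["fmean"]], tolerance = 1e-12)
    expect_equal(frequency_std(s), o[["fstd"]], tolerance = 1e-12)
  }
})

test_that("spectral moment edge cases follow the stated conventions", {
  f <- c(0, 8, 10, 12, 28)
  one <- c(0, 0, 3, 0, 0)
  expect_equal(mean_frequency(list(freqs = f, psd = one)), 10)
  expect_equal(frequency_std(list(freqs = f, psd = one)), 0)
  two <- c(0, 1, 0, 1, 0)
  expect_equal(mean_frequency(list(freqs = f, psd = two)), 10)
  expect_equal(frequency_std(list(freqs = f, psd = two)), 2)
  flat <- list(freqs = seq(0, 28, by = 0.5), psd = rep(1, 57))
  expect_equal(mean_frequency(flat), 14)
  expect_equal(mean_frequency(list(freqs = f, psd = rep(0, 5))), 0)
})

test_that("intensity_std is the population temporal standard deviation", {
  meta <- tiny_meta(2, 2, 2)
  arr <- array(0, c(2, 2, 2))
  arr[1, , ] <- 3; arr[2, , ] <- 7  # alternating a, b -> |a - b| / 2
  expect_equal(as.vector(intensity_std(doct_stack(arr, meta))), rep(2, 4))
  s <- rand_stack(31, n_frames = 20, nz = 3, nx = 3)
  got <- intensity_std(s)
  for (z in 1:3) for (x in 1:3) {
    v <- unclass(s)[, z, x]
    expect_equal(got[z, x], sqrt(mean((v - mean(v))^2)), tolerance = 1e-12)
  }
  expect_true(all(intensity_std(doct_stack(array(4, c(3, 2, 2)),
                                           tiny_meta(3, 2, 2))) == 0))
})

test_that("dynamics maps of a constant stack follow the degenerate convention", {
  s <- doct_stack(array(2, c(128, 8, 8)), tiny_meta(128, 8, 8))
  m <- compute_dynamics_maps(s, welch_params(segment_length = 128),
                             smooth = FALSE)
  expect_true(all(m$fmean == 0))
  expect_true(all(m$fstd == 0))
  expect_true(all(m$std == 0))
})

test_that("spatial chunking yields bitwise-identical maps", {
  s <- rand_stack(41, n_frames = 64, nz = 12, nx = 18)
  p <- welch_params(segment_length = 64)
  m1 <- compute_dynamics_maps(s, p, smooth = FALSE, n_chunks = 1)
  m4 <- compute_dynamics_maps(s, p, smooth = FALSE, n_chunks = 4)
  m9 <- compute_dynamics_maps(s, p, smooth = FALSE, n_chunks = 9)
  expect_identical(m1$fmean, m4$fmean)
  expect_identical(m1$fmean, m9$fmean)
  expect_identical(m1$fstd, m4$fstd)
  expect_identical(m1$fstd, m9$fstd)
  expect_error(compute_dynamics_maps(s, p, n_chunks = 5), "1, 4 or 9")
})

test_that("fmean and fstd are invariant to positive rescaling of the stack", {
  s <- rand_stack(42, n_frames = 64, nz = 6, nx = 6)
  p <- welch_params(segment_length = 64)
  m1 <- compute_dynamics_maps(s, p, smooth = FALSE)
  s2 <- doct_stack(unclass(s) * 37.5, stack_meta(s))
  m2 <- compute_dynamics_maps(s2, p, smooth = FALSE)
  expect_equal(m1$fmean, m2$fmean, tolerance = 1e-10)
  expect_equal(m1$fstd, m2$fstd, tolerance = 1e-10)
})

test_that("maps respect the frequency-range invariants", {
  s <- rand_stack(43, n_frames = 64, nz = 10, nx = 10)
  m <- compute_dynamics_maps(s, welch_params(segment_length = 64))
  expect_true(all(m$fmean >= 0 & m$fmean <= 28))
  expect_true(all(m$fstd >= 0 & m$fstd <= 28))
  expect_true(all(m$std >= 0))
})

test_that("fmean smoothing suppresses an isolated hot pixel", {
  s <- rand_stack(44, n_frames = 64, nz = 9, nx = 9)
  p <- welch_params(segment_length = 64)
  raw <- compute_dynamics_maps(s, p, smooth = FALSE)
  sm <- compute_dynamics_maps(s, p, smooth = TRUE)
  # smoothing is a convex average: extremes shrink
  expect_lte(max(sm$fmean), max(raw$fmean))
  expect_gte(min(sm$fmean), min(raw$fmean))
  # and it only touches fmean
  expect_identical(sm$fstd, raw$fstd)
  expect_identical(sm$std, raw$std)
})
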