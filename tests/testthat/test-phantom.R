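test_that("expected fmean of a flat band is the in-band grid centroid", {
  grid <- welch_freqs(56, 256)
  p <- layer_process("band_tones", band = c(8, 9.5),
                     fluctuation_amplitude = 0.3, white_floor = 0)
  expect_equal(expected_fmean(p, 56, grid),
               mean(grid[grid >= 8 & grid <= 9.5]))
  expect_lt(abs(expected_fmean(p, 56, grid) - 8.75), 0.06)
})

test_that("a pure white floor centroids at the grid midpoint", {
  grid <- welch_freqs(56, 256)
  p <- layer_process("band_tones", fluctuation_amplitude = 0,
                     white_floor = 0.1)
  # DC excluded (mean-removal convention)
  expect_equal(expected_fmean(p, 56, grid), mean(grid[grid > 0]))
  expect_lt(abs(expected_fmean(p, 56, grid) - 14), 0.2)
})

test_that("AR(1) expected fmean matches an independent direct summation", {
  grid <- welch_freqs(56, 256)
  phi <- 0.7; amp <- 0.25; wf <- 0.05
  p <- layer_process("ar1_plus_white", fluctuation_amplitude = amp,
                     white_floor = wf, ar_coef = phi)
  # independent oracle: Lorentzian + flat floor, summed term by term
  f <- grid[grid > 0]
  lor <- 1 / (1 - 2 * phi * cos(2 * pi * f / 56) + phi^2)
  w <- amp^2 * lor / sum(lor) + wf^2 / length(f)
  expect_equal(expected_fmean(p, 56, grid), sum(w * f) / sum(w),
               tolerance = 1e-12)
})

test_that("phantom generation is deterministic in the seed", {
  s1 <- generate_phantom(small_phantom(seed = 5, shape = c(32, 32),
                                       n_frames = 32))
  s2 <- generate_phantom(small_phantom(seed = 5, shape = c(32, 32),
                                       n_frames = 32))
  s3 <- generate_phantom(small_phantom(seed = 6, shape = c(32, 32),
                                       n_frames = 32))
  expect_identical(unclass(s1$stack)[], unclass(s2$stack)[])
  expect_identical(s1$labels, s2$labels)
  expect_false(identical(unclass(s1$stack)[], unclass(s3$stack)[]))
  # generation does not disturb the caller's RNG stream
  set.seed(99); a <- rnorm(1)
  set.seed(99); invisible(generate_phantom(small_phantom(seed = 5,
    shape = c(16, 16), n_frames = 32))); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("phantom geometry validates and labels its layers", {
  expect_error(phantom_spec(outer_radii_um = 50, core_radii_um = 60),
               "exceed")
  ph <- generate_phantom(small_phantom(seed = 2, edge = TRUE))
  expect_setequal(unique(as.vector(ph$labels)), 0:3)
  # edge ring sits at the outer boundary: dilating the interior covers it
  expect_true(all(ph$labels[ph$labels == 3] == 3))
  inner <- ph$labels %in% 1:2
  expect_gt(sum(ph$labels == 3), 0)
})

test_that("a zero-radius core gives a fully viable spheroid", {
  ph <- generate_phantom(small_phantom(seed = 8, core = 0))
  expect_false(any(ph$labels == 2))
  res <- doct_process(ph$stack, params = welch_params(segment_length = 128))
  expect_equal(res$viability, 1, tolerance = 1e-3)
})

test_that("generated layer spectra match the closed-form process PSD", {
  ph <- generate_phantom(small_phantom(seed = 12))
  stack <- normalize_frames(ph$stack)
  fs <- stack_meta(stack)$frame_rate
  idx <- which(ph$labels == 1, arr.ind = TRUE)
  set.seed(1)
  idx <- idx[sample(nrow(idx), 150), ]
  acc <- NULL
  for (i in seq_len(nrow(idx))) {
    x <- unclass(stack)[, idx[i, 1], idx[i, 2]]
    o <- oracle_periodogram(x - mean(x), fs)
    acc <- if (is.null(acc)) o$psd else acc + o$psd
  }
  freqs <- oracle_periodogram(rnorm(dim(stack)[1]), fs)$freqs
  inband <- freqs >= 8 & freqs <= 9.5
  # Monte-Carlo check: the averaged sample PSD concentrates in the band
  # and centroids at the analytic expectation
  expect_gt(sum(acc[inband]) / sum(acc), 0.85)
  cent <- sum(acc * freqs) / sum(acc)
  expect_lt(abs(cent - ph$expected_fmean[["viable"]]), 0.3)
})

test_that("growth series follows its schedule deterministically", {
  spec <- small_phantom(seed = 4, shape = c(32, 32), n_frames = 32,
                        outer = 35, core = 0)
  expect_identical(growth_series(spec, numeric(0), numeric(0)), list())
  gs <- growth_series(spec, days = c(1, 5, 9),
                      core_radius_schedule = c(0, 12, 24))
  expect_named(gs, c("day1", "day5", "day9"))
  expect_false(any(gs$day1$labels == 2))
  expect_gt(sum(gs$day9$labels == 2), sum(gs$day5$labels == 2))
  # constant schedule: statistically identical phantoms, same expectation
  gc <- growth_series(spec, days = c(1, 2), core_radius_schedule = c(10, 10))
  expect_identical(gc$day1$labels, gc$day2$labels)
  expect_identical(gc$day1$expected_fmean, gc$day2$expected_fmean)
  expect_error(growth_series(spec, days = c(1, 2),
                             core_radius_schedule = c(12, 8)),
               "non-decreasing")
  expect_error(growth_series(spec, days = 1, core_radius_schedule = 100),
               "exceeds")
})

test_that("volumetric phantoms follow the ellipsoid through y", {
  spec <- phantom_spec(shape = c(7, 24, 24), outer_radii_um = c(7, 25, 25),
                       core_radii_um = c(4, 14, 14), n_frames = 32,
                       edge_ring = list(enabled = FALSE), seed = 11)
  vol <- generate_phantom(spec)
  expect_s3_class(vol, "doct_phantom_volume")
  expect_length(vol$phantoms, 7)
  per_slice <- vapply(vol$phantoms, function(p) sum(p$labels > 0), numeric(1))
  # spheroid cross-section is largest centrally and vanishes outside
  expect_equal(which.max(per_slice), 4)
  expect_equal(per_slice[1], 0)
  core_slices <- vapply(vol$phantoms, function(p) any(p$labels == 2),
                        logical(1))
  expect_true(core_slices[4])
  expect_false(core_slices[1] || core_slices[7])
})
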