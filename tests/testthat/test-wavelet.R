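test_that("Morlet Fourier period follows the closed form", {
  # independent evaluation of lambda = 4 pi s / (omega0 + sqrt(2 + omega0^2))
  lambda1 <- 4 * pi / (6 + sqrt(38))
  spec <- cwt_morlet(rnorm(16), s0 = 1, n_scales = 3)
  expect_equal(spec$periods[1], lambda1, tolerance = 1e-12)
  expect_equal(spec$periods[1], 1.0330, tolerance = 1e-4)
  expect_equal(spec$periods / spec$scales,
               rep(lambda1, 3), tolerance = 1e-12)   # constant ratio
  expect_true(all(diff(spec$periods) > 0))
})

test_that("constant input transforms to zero (mean is removed)", {
  spec <- cwt_morlet(rep(42, 64))
  expect_lt(max(Mod(spec$coefficients)), 1e-10)
  expect_equal(spec$series_mean, 42)
})

test_that("a 24 h cosine puts its power at the 24 h scale", {
  t <- 0:743
  spec <- cwt_morlet(10 * cos(2 * pi * t / 24))
  p <- power_spectrum(spec)
  # brute-force scan of time-averaged power across all scale rows
  peak_row <- which.max(rowMeans(p))
  step <- spec$periods[2] / spec$periods[1]
  expect_lt(abs(log(spec$periods[peak_row] / 24)), log(step) + 1e-12)
})

test_that("power is non-negative and scales quadratically", {
  x <- rnorm(128)
  p1 <- power_spectrum(cwt_morlet(x))
  expect_true(all(p1 >= 0))
  p2 <- power_spectrum(cwt_morlet(3 * x))
  expect_equal(p2, 9 * p1, tolerance = 1e-9)
})

test_that("the transform is linear", {
  set.seed(5)
  x <- rnorm(128); y <- rnorm(128)
  Wx <- cwt_morlet(x)$coefficients
  Wy <- cwt_morlet(y)$coefficients
  Wxy <- cwt_morlet(2 * x - 3 * y)$coefficients
  expect_equal(Wxy, 2 * Wx - 3 * Wy, tolerance = 1e-9)
})

test_that("band reconstructions partition across a split band", {
  set.seed(6)
  spec <- cwt_morlet(rnorm(256) + 5 * cos(2 * pi * (0:255) / 24))
  full <- bandpass_reconstruct(spec, c(4, 32))
  lo <- bandpass_reconstruct(spec, c(4, 12))
  hi <- bandpass_reconstruct(spec, c(12, 32))
  expect_equal(lo + hi, full, tolerance = 1e-10)
})

test_that("band-pass matches an independent DFT brute-force band-pass", {
  t <- 0:255
  x <- 8 * cos(2 * pi * t / 24) + 4 * sin(2 * pi * t / 6)
  spec <- cwt_morlet(x)
  mine <- bandpass_reconstruct(spec, c(4, 32))
  oracle <- dft_bandpass(x, c(4, 32))
  expect_gt(cor(mine, oracle), 0.95)
})

test_that("band handling: empty bands error, out-of-range bands clip", {
  spec <- cwt_morlet(rnorm(64))
  expect_error(bandpass_reconstruct(spec, c(2.1, 2.2)), "empty band")
  expect_error(bandpass_reconstruct(spec, c(32, 4)), "band must be")
  expect_warning(r <- bandpass_reconstruct(spec, c(0.5, 32)), "clipped")
  expect_length(r, 64L)
})

test_that("cone of influence is zero-edged, symmetric, midpoint-maximal", {
  coi <- cone_of_influence(744)
  expect_equal(coi[1], 0)
  expect_equal(coi[744], 0)
  expect_equal(coi, rev(coi))
  expect_equal(which.max(coi), 372L)   # first of the two central maxima
  mid <- cone_of_influence(745)
  expect_equal(which.max(mid), 373L)   # exact midpoint for odd n
})

test_that("reconstruct_series restores the mean onto the RSV scale", {
  s <- make_series(pmin(100, pmax(0, round(
    50 + 20 * cos(2 * pi * ((0:239) - 2) / 24)))))
  rec <- reconstruct_series(s)
  expect_true(rec$is_reconstructed)
  expect_equal(mean(rec$values), mean(s$values), tolerance = 1e-9)
  dev <- reconstruct_series(s, restore_mean = FALSE)
  expect_equal(mean(dev$values), 0, tolerance = 1e-9)
})
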