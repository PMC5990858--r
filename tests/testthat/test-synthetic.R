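test_that("generate_series produces the stated-world dimensions", {
  cfg <- synthetic_config(n_days = 31, terms = depression_terms(), seed = 3)
  gen <- generate_series(cfg)
  expect_length(gen$series, 6L)
  expect_true(all(vapply(gen$series, length, integer(1)) == 744L))
  expect_identical(sum(vapply(gen$series, length, integer(1))), 4464L)
  for (s in gen$series) {
    expect_true(all(s$values >= 0 & s$values <= 100))
    expect_true(all(s$values == round(s$values)))   # quantized
    expect_equal(max(s$values), 100)                # renormalized
  }
})

test_that("degenerate and pure-cosine configs match their analytic truth", {
  flat <- synthetic_config(n_days = 2, baseline = 50, diurnal_amplitude = 0,
                           trend_amplitude = 0, noise_hf_amplitude = 0,
                           white_sd = 0, renormalize = FALSE)
  gen <- generate_series(flat)
  expect_true(all(gen$series[[1]]$values == 50))
  expect_equal(unname(gen$truth$true_pp_difference), 0)

  pure <- synthetic_config(n_days = 4, baseline = 50, diurnal_amplitude = 15,
                           acrophase = 2, trend_amplitude = 0,
                           noise_hf_amplitude = 0, white_sd = 0,
                           renormalize = FALSE, quantize = FALSE)
  gen <- generate_series(pure)
  expect_equal(unname(gen$truth$true_pp_difference), 30)   # 2A
  expect_identical(gen$truth$true_peak_hour, 2L)
  expect_identical(gen$truth$true_trough_hour, 14L)
  prof <- mean_profile(fold_days(gen$series[[1]]))
  expect_identical(prof$peak_hour, 2L)
  expect_equal(prof$pp_difference, 30)
})

test_that("same config and seed give bit-identical output", {
  cfg <- synthetic_config(n_days = 5, terms = c("a", "b"), seed = 99)
  g1 <- generate_series(cfg)
  g2 <- generate_series(cfg)
  expect_identical(g1$series[["a"]]$values, g2$series[["a"]]$values)
  expect_identical(g1$series[["b"]]$values, g2$series[["b"]]$values)
  g3 <- generate_series(synthetic_config(n_days = 5, terms = c("a", "b"),
                                         seed = 100))
  expect_false(identical(g1$series[["a"]]$values, g3$series[["a"]]$values))
})

test_that("residual white noise has the configured SD", {
  cfg <- synthetic_config(n_days = 31, baseline = 55, diurnal_amplitude = 15,
                          acrophase = 2, trend_amplitude = 20,
                          trend_period = 72, noise_hf_amplitude = 0,
                          white_sd = 5, renormalize = FALSE, quantize = FALSE,
                          seed = 17)
  v <- generate_series(cfg)$series[[1]]$values
  t <- 0:743
  deterministic <- 55 + 15 * cos(2 * pi * (t - 2) / 24) +
    20 * cos(2 * pi * t / 72)
  expect_lt(abs(sd(v - deterministic) - 5) / 5, 0.10)
})

test_that("ground truth diurnal component is a zero-mean cosine", {
  gen <- generate_series(synthetic_config(n_days = 3, seed = 1))
  expect_equal(mean(gen$truth$diurnal_component), 0, tolerance = 1e-12)
})

test_that("ground_truth_profile reflects amplitude and acrophase", {
  p <- ground_truth_profile(synthetic_config(diurnal_amplitude = 10,
                                             acrophase = 2))
  expect_identical(p$peak_hour, 2L)
  expect_identical(p$trough_hour, 14L)
  expect_equal(ground_truth_profile(
    synthetic_config(diurnal_amplitude = 15, acrophase = 23))$pp_difference,
    30)
  expect_equal(ground_truth_profile(
    synthetic_config(diurnal_amplitude = 0))$pp_difference, 0)
})

test_that("invalid configurations are rejected naming the invariant", {
  expect_error(synthetic_config(n_days = 1), "n_days")
  expect_error(synthetic_config(trend_period = 30), "trend_period")
  expect_error(synthetic_config(noise_hf_period = 6), "noise_hf_period")
  expect_error(synthetic_config(acrophase = 24), "acrophase")
  expect_error(synthetic_config(white_sd = -1), "white_sd")
})
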