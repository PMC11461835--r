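zero_powers <- list(
  healthy = c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0),
  insomnia = c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0))

test_that("all-zero band powers give an all-zero signal", {
  spec <- cohort_spec(1, 1, duration_s = 2, band_power_map = zero_powers,
                      subject_sd = 0)
  expect_identical(generate_subject(spec, "healthy", 1), numeric(2 * 512))
})

test_that("a planted alpha power is recovered by the measured variance", {
  bp <- zero_powers
  bp$healthy["alpha"] <- 4
  spec <- cohort_spec(1, 1, duration_s = 60, band_power_map = bp,
                      subject_sd = 0, seed = 21)
  for (i in 1:3) {
    v <- var(generate_subject(spec, "healthy", i))
    expect_lt(abs(v - 4), 0.4)     # 4.0 +/- 10% at 60 s, fs 512
  }
})

test_that("generation is bit-identical for a fixed spec and index", {
  spec <- cohort_spec(2, 2, duration_s = 2, seed = 9)
  expect_identical(generate_subject(spec, "insomnia", 2),
                   generate_subject(spec, "insomnia", 2))
  expect_identical(simulate_cohort(spec), simulate_cohort(spec))
})

test_that("cohort has requested composition and latency-consistent metadata", {
  spec <- cohort_spec(6, 6, duration_s = 2, seed = 33)
  co <- simulate_cohort(spec)
  expect_equal(nrow(co), 12)
  expect_equal(sum(co$group == "insomnia"), 6)
  sl <- minutes_between(co$sleep_start, co$sleep_onset)
  expect_true(all(sl[co$group == "healthy"] <= 20))
  expect_true(all(sl[co$group == "insomnia"] > 20))
  # onset lies inside the in-bed interval for every subject
  tib <- minutes_between(co$sleep_start, co$sleep_end)
  expect_true(all(sl <= tib))
  one <- simulate_cohort(cohort_spec(1, 0, duration_s = 2))
  expect_equal(one$group, "insomnia")
})

test_that("distinct band-power maps produce the configured class contrast", {
  spec <- cohort_spec(6, 6, duration_s = 60, seed = 13)
  co <- simulate_cohort(spec)
  alpha_pow <- vapply(seq_len(nrow(co)), function(i) {
    dec <- decompose_bands(co$samples[[i]], co$fs[i])
    mean(dec$bands$alpha^2)
  }, 0)
  gap <- mean(alpha_pow[co$group == "insomnia"]) -
    mean(alpha_pow[co$group == "healthy"])
  cfg_gap <- default_band_powers()$insomnia["alpha"] -
    default_band_powers()$healthy["alpha"]
  # leakage from neighbouring bands cancels in the difference; Monte-Carlo
  # tolerance of +/-10% of the healthy-class alpha power at 60 s
  expect_lt(abs(gap - cfg_gap), 0.1 * default_band_powers()$healthy["alpha"])
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec(1, 1, duration_s = 0), class = "sleepaug_spec_error")
  expect_error(cohort_spec(0, 0), class = "sleepaug_spec_error")
  bad <- list(healthy = c(delta = -1), insomnia = c(delta = 1))
  expect_error(cohort_spec(1, 1, band_power_map = bad),
               class = "sleepaug_spec_error")
})

test_that("artifacts are added when configured", {
  spec <- cohort_spec(1, 1, duration_s = 4, band_power_map = zero_powers,
                      subject_sd = 0, powerline_amp = 2, powerline_hz = 50)
  x <- generate_subject(spec, "healthy", 1)
  expect_equal(mean(x^2), 2, tolerance = 0.01)  # A^2/2 of the 50 Hz sinusoid
})
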