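co <- tiny_cohort(duration_s = 6, epoch_s = 2, seed = 42)
seg <- co$segments[[1]]
raw_recon <- sleepaug:::segments_reconstruct(seg)

test_that("unit scale factor reproduces the raw five-band reconstruction", {
  a <- scale_band_segment(seg, "alpha", 1, 1.0)
  expect_lt(max(abs(a$samples[[1]] - raw_recon)), 1e-9)
  expect_equal(a$cycle, "MCSA1")
  expect_equal(a$op, "addition")
})

test_that("scaling one band-segment scales only that band-segment's power", {
  a <- scale_band_segment(seg, "alpha", 1, 2.0)
  diff <- a$samples[[1]] - raw_recon
  idx1 <- seq_len(seg$seg_len)
  idx2 <- seg$seg_len + seq_len(seg$seg_len)
  # alpha content of the targeted epoch quadruples in power
  alpha_new <- seg$segments$alpha[, 1] + diff[idx1]
  ratio <- mean(alpha_new^2) / mean(seg$segments$alpha[, 1]^2)
  expect_lt(abs(ratio - 4), 0.04)                       # power x 4 +/- 1%
  # the added content is exactly the raw alpha epoch (nothing of delta etc.)
  expect_lt(max(abs(diff[idx1] - seg$segments$alpha[, 1])), 1e-9)
  # every other epoch is untouched
  expect_lt(max(abs(diff[idx2])) / max(abs(raw_recon)), 1e-9)
})

test_that("zero factor silences the targeted band-segment", {
  a <- scale_band_segment(seg, "gamma", 2, 0)
  idx2 <- seg$seg_len + seq_len(seg$seg_len)
  gamma_new <- seg$segments$gamma[, 2] +
    (a$samples[[1]] - raw_recon)[idx2]
  expect_lt(mean(gamma_new^2), 1e-12)
})

test_that("injected noise hits the configured SNR and is reproducible", {
  co30 <- tiny_cohort(duration_s = 30, epoch_s = 30, seed = 2)
  s30 <- co30$segments[[1]]
  expect_gte(s30$seg_len, 15360)
  a <- inject_noise_band_segment(s30, "theta", 1, snr_db = 10, seed = 77)
  noise <- attr(a$samples[[1]], "injected_noise")
  p_sig <- mean(s30$segments$theta[, 1]^2)
  snr_meas <- 10 * log10(p_sig / mean(noise^2))
  expect_lt(abs(snr_meas - 10), 0.5)
  b <- inject_noise_band_segment(s30, "theta", 1, snr_db = 10, seed = 77)
  expect_identical(a$samples[[1]], b$samples[[1]])
  hi <- inject_noise_band_segment(s30, "theta", 1, snr_db = Inf, seed = 1)
  raw30 <- sleepaug:::segments_reconstruct(s30)
  expect_lt(max(abs(hi$samples[[1]] - raw30)) / max(abs(raw30)), 1e-5)
})

test_that("noise injection on a silent segment is rejected", {
  zseg <- seg
  zseg$segments$gamma[, 1] <- 0
  expect_error(inject_noise_band_segment(zseg, "gamma", 1, 10, 1),
               class = "sleepaug_degenerate_snr_error")
  expect_error(scale_band_segment(seg, "sigma", 1, 2),
               class = "sleepaug_index_error")
  expect_error(scale_band_segment(seg, "alpha", 99, 2),
               class = "sleepaug_index_error")
})

test_that("convolution with a unit impulse is the identity", {
  a <- scale_band_segment(seg, "beta", 1, 1.5)
  cv <- convolve_with_raw(a, c(1), fs = seg$fs)
  expect_equal(cv$samples[[1]], a$samples[[1]], tolerance = 1e-9)
  expect_equal(cv$op, "convolution")
})

test_that("convolution preserves length and power for any kernel", {
  a <- scale_band_segment(seg, "beta", 2, 1.5)
  raw <- co$filtered[[1]][seq_along(a$samples[[1]])]
  cv <- convolve_with_raw(a, raw)
  expect_length(cv$samples[[1]], length(a$samples[[1]]))
  expect_lt(abs(mean(cv$samples[[1]]^2) / mean(a$samples[[1]]^2) - 1), 1e-6)
  expect_error(convolve_with_raw(a, raw, fs = 128),
               class = "sleepaug_config_error")
})

test_that("run_mcsa emits 4 signals per subject x band x segment", {
  aug <- run_mcsa(co, mcsa_config(seed = 5))
  S <- nrow(co); G <- seg$n_segments
  expect_equal(nrow(aug), 4 * S * 5 * G)
  expect_equal(sum(aug$cycle == "MCSA1"), 2 * S * 5 * G)
  expect_equal(sum(aug$op == "addition"), 2 * S * 5 * G)
  # labels inherited from source subjects, class balance preserved exactly
  src <- setNames(co$group, co$subject_id)
  expect_identical(aug$label, unname(src[aug$source_subject]))
  expect_equal(sum(aug$label == "insomnia"), nrow(aug) / 2)
  expect_equal(nrow(run_mcsa(co[0, ], mcsa_config())), 0)
})

test_that("addition-set outputs keep untouched band-segments bit-close", {
  aug <- run_mcsa(co[1, ], mcsa_config(seed = 5))
  add_rows <- which(aug$op == "addition" & aug$band == "alpha" &
                      aug$segment_idx == 1)
  for (i in add_rows) {
    x <- aug$samples[[i]]
    # outside the targeted epoch the trace equals the raw reconstruction
    tail_idx <- (seg$seg_len + 1):length(raw_recon)
    expect_lt(max(abs(x[tail_idx] - raw_recon[tail_idx])) /
                max(abs(raw_recon)), 1e-9)
  }
})
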