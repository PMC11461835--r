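test_that("sample entropy matches the exhaustive brute-force oracle", {
  set.seed(31)
  cases <- c(
    list(rep(c(1, -1), 10)),                       # strictly periodic
    lapply(1:8, function(i) rnorm(sample(10:30, 1))),
    lapply(1:4, function(i) round(rnorm(25), 1)))  # heavy ties
  for (x in cases) {
    expect_equal(sample_entropy(x), sampen_brute(x), tolerance = 1e-12)
  }
})

test_that("sample entropy is 0 for constants and ranks noise above tones", {
  expect_identical(sample_entropy(rep(3.7, 50)), 0)
  set.seed(32)
  noise <- rnorm(2000)
  tone <- sin(2 * pi * 5 * seq(0, 4, length.out = 2000))
  tone <- tone * sd(noise) / sd(tone)
  expect_gt(sample_entropy(noise), sample_entropy(tone))
  expect_error(sample_entropy(1:3), class = "sleepaug_input_error")
})

test_that("sample entropy agrees with an independent library implementation", {
  set.seed(33)
  for (rep in 1:3) {
    x <- rnorm(150)
    expect_equal(sample_entropy(x),
                 pracma::sample_entropy(x, edim = 2,
                                        r = 0.2 * sqrt(mean((x - mean(x))^2))),
                 tolerance = 1e-8)
  }
})

test_that("spectral entropy separates tones from noise and ignores scale", {
  t <- seq(0, 16, length.out = 8192)
  tone <- sin(2 * pi * 10 * t)
  expect_lt(spectral_entropy(tone, 512), 0.2)
  set.seed(34)
  noise <- rnorm(8192)
  expect_gt(spectral_entropy(noise, 512), 0.9)
  expect_equal(spectral_entropy(noise * 1000, 512),
               spectral_entropy(noise, 512), tolerance = 1e-12)
  expect_identical(spectral_entropy(numeric(100), 512), 0)
})

test_that("histogram Shannon entropy hits exact constructed values", {
  x8 <- (0:7) + 0.5
  expect_equal(shannon_entropy(x8, bins = 8), 3.0, tolerance = 1e-12)
  expect_identical(shannon_entropy(rep(2, 100)), 0)
  set.seed(35)
  for (rep in 1:5) {
    h <- shannon_entropy(rnorm(400), bins = 64)
    expect_gte(h, 0); expect_lte(h, log2(64))
  }
  # invariance under affine amplitude maps
  y <- rnorm(500)
  expect_equal(shannon_entropy(3 * y - 7), shannon_entropy(y),
               tolerance = 1e-12)
})

test_that("log-energy entropy obeys its algebraic identities", {
  expect_lt(abs(log_energy_entropy(c(1, 1, 1, 1))), 5e-12)
  expect_equal(log_energy_entropy(c(exp(1), exp(1))), 4, tolerance = 1e-9)
  set.seed(36)
  x <- rnorm(100) + 2
  expect_equal(log_energy_entropy(2 * x) - log_energy_entropy(x),
               100 * log(4), tolerance = 1e-6)
})

test_that("band power is the mean square", {
  t <- seq(0, 2, length.out = 4096)
  expect_equal(band_power(sin(2 * pi * 12 * t)), 0.5, tolerance = 0.005)
  expect_identical(band_power(numeric(10)), 0)
  x <- rnorm(100)
  expect_equal(band_power(3 * x), 9 * band_power(x), tolerance = 1e-12)
})

test_that("moments: symmetry, Gaussian kurtosis, degenerate cases", {
  expect_equal(stat_moments(c(-2, -1, 1, 2))[["skewness"]], 0)
  set.seed(37)
  mk <- stat_moments(rnorm(100000))
  expect_lt(abs(mk[["kurtosis"]]), 0.05)
  expect_equal(stat_moments(rep(5, 10)),
               c(mean = 5, std = 0, skewness = 0, kurtosis = 0))
  expect_error(stat_moments(1:3), class = "sleepaug_input_error")
})

test_that("feature table has the fixed 45-column schema with no gaps", {
  co <- tiny_cohort(duration_s = 4, epoch_s = 2, seed = 6)
  aug <- run_mcsa(co, mcsa_config(seed = 3))
  f <- extract_features(aug)
  expect_equal(nrow(f), nrow(aug))
  expect_identical(names(f), c(feature_columns(), "label", "subject_id",
                               "provenance"))
  expect_false(anyNA(f))
  # identical signals give identical rows
  two <- aug[c(1, 1), ]
  ff <- extract_features(two)
  expect_identical(ff[1, ], ff[2, ])
})

test_that("a planted alpha class gap survives into the feature table", {
  spec <- planted_alpha_spec(gap_sd = 4, duration_s = 10, seed = 19,
                             n_insomnia = 3, n_healthy = 3)
  co <- preprocess_cohort(simulate_cohort(spec), epoch_s = 5)
  f <- extract_features(co)
  m_ins <- mean(f$alpha_band_power[f$label == "insomnia"])
  m_h <- mean(f$alpha_band_power[f$label == "healthy"])
  expect_gt(m_ins, m_h)
})

test_that("band_subset slices one band's nine columns", {
  co <- tiny_cohort(duration_s = 4, epoch_s = 2, seed = 6)
  f <- extract_features(co)
  a <- band_subset(f, "alpha")
  expect_equal(sum(vapply(a, is.numeric, TRUE)), 9)
  expect_true(all(startsWith(setdiff(names(a), c("label", "subject_id",
                                                 "provenance")), "alpha_")))
  expect_equal(ncol(band_subset(f, "combined")), ncol(f))
})
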