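make_toy <- function(n = 200, seed = 50, p_ins = 0.7) {
  set.seed(seed)
  tibble::tibble(
    value = rnorm(n, mean = 5, sd = 2),
    label = sample(c("insomnia", "healthy"), n, TRUE, prob = c(p_ins, 1 - p_ins)))
}

test_that("normalizer recovers a single Gaussian mode", {
  set.seed(51)
  tab <- tibble::tibble(value = rnorm(2000, 5, 1),
                        label = rep(c("insomnia", "healthy"), 1000))
  norm <- fit_mode_normalizer(tab)
  col <- norm$columns$value
  k <- which.max(col$weights)
  expect_lt(abs(col$means[k] - 5), 0.1)
  expect_gte(col$weights[k], 0.9)
})

test_that("normalizer recovers two well-separated modes", {
  set.seed(52)
  tab <- tibble::tibble(
    value = c(rnorm(1000, 0, 0.1), rnorm(1000, 10, 0.1)),
    label = rep(c("insomnia", "healthy"), 1000))
  norm <- fit_mode_normalizer(tab)
  mus <- sort(norm$columns$value$means)
  expect_equal(length(mus), 2)
  expect_lt(abs(mus[1] - 0), 0.2)
  expect_lt(abs(mus[2] - 10), 0.2)
})

test_that("encode/decode round-trips any value", {
  tab <- make_toy(300, seed = 53)
  norm <- fit_mode_normalizer(tab)
  v <- c(tab$value, -50, 0, 50)   # include far outliers
  enc <- normalizer_encode(norm, "value", v)
  back <- normalizer_decode(norm, "value", enc$alpha, enc$mode)
  expect_lt(max(abs(back - v)), 1e-6)
  expect_error(normalizer_encode(norm, "nope", 1),
               class = "sleepaug_input_error")
})

test_that("constant columns degenerate to a single floored mode", {
  tab <- tibble::tibble(value = rep(3, 50),
                        label = rep(c("insomnia", "healthy"), 25))
  norm <- fit_mode_normalizer(tab)
  expect_equal(norm$columns$value$means, 3)
  expect_gt(norm$columns$value$sds, 0)
})

test_that("a briefly trained GAN recovers category frequency and mean", {
  toy <- make_toy(500, seed = 54)
  m <- ctgan_fit(toy, epochs = 300, batch = 100, seed = 11)
  s <- ctgan_sample(m, n = 1000, seed = 12)
  expect_equal(nrow(s), 1000)
  expect_lt(abs(mean(s$label == "insomnia") - mean(toy$label == "insomnia")),
            0.05)
  expect_lt(abs(mean(s$value) - mean(toy$value)), 0.25 * sd(toy$value))
})

test_that("training is deterministic and records finite loss histories", {
  toy <- make_toy(120, seed = 55)
  m1 <- ctgan_fit(toy, epochs = 15, batch = 60, seed = 7)
  m2 <- ctgan_fit(toy, epochs = 15, batch = 60, seed = 7)
  expect_identical(m1$loss, m2$loss)
  expect_true(all(is.finite(m1$loss$d_loss)))
  expect_equal(nrow(tidy(m1)), 15)
  expect_equal(glance(m1)$epochs, 15)
})

test_that("an untrained model still emits schema-valid rows", {
  toy <- make_toy(60, seed = 56)
  m <- ctgan_fit(toy, epochs = 0, batch = 30, seed = 3)
  s <- ctgan_sample(m, n = 5, seed = 4)
  expect_equal(names(s), names(toy))
  expect_true(all(s$label %in% c("insomnia", "healthy")))
  s1 <- ctgan_sample(m, n = 1, seed = 5)
  expect_equal(nrow(s1), 1)
})

test_that("conditional sampling is 100% condition-compliant", {
  toy <- make_toy(150, seed = 57)
  m <- ctgan_fit(toy, epochs = 30, batch = 50, seed = 8)
  s <- ctgan_sample(m, n = 300, condition = "insomnia", seed = 9)
  expect_true(all(s$label == "insomnia"))
  expect_error(ctgan_sample(m, n = 5, condition = "narcolepsy"),
               class = "sleepaug_input_error")
})

test_that("sampled tables always conserve the training schema", {
  co <- tiny_cohort(duration_s = 4, epoch_s = 2, seed = 58)
  f <- extract_features(co)
  m <- ctgan_fit(f, epochs = 5, batch = 2, seed = 2)
  s <- ctgan_sample(m, n = 7, seed = 3)
  expect_identical(names(s), names(f))
  expect_true(all(is.na(s$subject_id)))
  expect_true(all(s$provenance == "ctgan"))
})

test_that("validation report: identity gives zero diffs, shifts are flagged", {
  toy <- make_toy(400, seed = 59)
  v <- validate_synthetic(toy, toy)
  expect_true(all(v$columns$mean_abs_diff == 0))
  expect_equal(v$corr_frobenius, 0)
  expect_true(v$pass)
  shifted <- toy
  shifted$value <- shifted$value + 10 * sd(toy$value)
  v2 <- validate_synthetic(toy, shifted)
  expect_false(v2$columns$pass[v2$columns$column == "value"])
  wrong <- toy
  names(wrong)[1] <- "other"
  expect_error(validate_synthetic(toy, wrong), class = "sleepaug_input_error")
})

test_that("model archive save/load round-trips", {
  toy <- make_toy(60, seed = 60)
  m <- ctgan_fit(toy, epochs = 2, batch = 30, seed = 1)
  p <- withr::local_tempfile(fileext = ".rds")
  ctgan_save(m, p)
  m2 <- ctgan_load(p)
  expect_identical(ctgan_sample(m, 10, seed = 5), ctgan_sample(m2, 10, seed = 5))
})
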