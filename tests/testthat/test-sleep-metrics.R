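test_that("minutes_between handles ordinary gaps, wrap, and identity", {
  expect_equal(minutes_between("22:19:06", "6:38:36"), 499.5)
  expect_equal(minutes_between("12:00:00", "12:00:00"), 0)
  expect_equal(minutes_between("23:59:59", "00:00:01"), 0.03)
  expect_error(minutes_between("25:00:00", "01:00:00"),
               class = "sleepaug_parse_error")
  expect_error(minutes_between("not a time", "01:00:00"),
               class = "sleepaug_parse_error")
})

test_that("minutes_between is antisymmetric up to the 24 h wrap", {
  set.seed(41)
  for (rep in 1:20) {
    a <- sprintf("%02d:%02d:%02d", sample(0:23, 1), sample(0:59, 1),
                 sample(0:59, 1))
    b <- sprintf("%02d:%02d:%02d", sample(0:23, 1), sample(0:59, 1),
                 sample(0:59, 1))
    s <- minutes_between(a, b) + minutes_between(b, a)
    expect_lt(min(abs(s - c(0, 1440))), 0.011)
  }
})

test_that("summary reproduces the published 12-subject cohort table", {
  s <- sleep_summary(cap_sleep_times())
  expected <- tibble::tribble(
    ~subject_id, ~tib, ~sl, ~tst,
    "INS2", 837.02, 286.02, 551.00,
    "INS4", 366.00,  13.50, 352.50,
    "INS5", 859.50, 331.50, 528.00,
    "INS6", 528.00,  19.50, 508.50,
    "INS7", 741.00, 116.50, 624.50,
    "INS8", 419.50,  31.50, 388.00,
    "n1",   573.00,   5.50, 567.50,
    "n2",   499.50,   4.00, 495.50,
    "n3",   500.00,   1.00, 499.00,
    "n5",   503.50,   2.00, 501.50,
    "n10",  429.50,  31.50, 398.00,
    "n11",  526.00,  18.00, 508.00)
  for (i in seq_len(nrow(expected))) {
    j <- match(expected$subject_id[i], s$subject_id)
    expect_equal(s$time_in_bed_min[j], expected$tib[i])
    expect_equal(s$sleep_latency_min[j], expected$sl[i])
    expect_equal(s$tst_min[j], expected$tst[i])
  }
  # the stated identity holds exactly on every row
  expect_identical(s$time_in_bed_min, s$sleep_latency_min + s$tst_min)
})

test_that("latency flag uses the 20-minute cutoff", {
  s <- sleep_summary(cap_sleep_times())
  expect_identical(s$latency_flag[s$subject_id == "INS2"], "prolonged")
  expect_identical(s$latency_flag[s$subject_id == "n5"], "normal")
  z <- sleep_summary(data.frame(sleep_start = "22:00:00",
                                sleep_onset = "22:00:00",
                                sleep_end = "06:00:00"))
  expect_equal(z$sleep_latency_min, 0)
  expect_equal(z$tst_min, z$time_in_bed_min)
})

test_that("onset outside the in-bed interval is a consistency error", {
  expect_error(
    sleep_summary(data.frame(sleep_start = "22:00:00",
                             sleep_onset = "09:00:00",
                             sleep_end = "06:00:00")),
    class = "sleepaug_consistency_error")
})
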