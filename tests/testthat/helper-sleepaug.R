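# Independent brute-force oracles and tiny fixtures built in code.

# Exhaustive-enumeration sample entropy (Richman-Moorman convention), kept
# deliberately naive and independent of the package implementation.
sampen_brute <- function(x, m = 2, r = 0.2) {
  n <- length(x)
  sdx <- sqrt(mean((x - mean(x))^2))
  if (sdx == 0) return(0)
  tol <- r * sdx
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in seq(i + 1, nt)) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= tol) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= tol) A <- A + 1
      }
    }
  }
  cap <- log(nt * (nt - 1))
  if (A == 0 || B == 0) return(cap)
  min(-log(A / B), cap)
}

# Small preprocessed cohort reused across MCSA/feature tests.
tiny_cohort <- function(n_per_class = 1, duration_s = 6, epoch_s = 2,
                        seed = 42) {
  spec <- cohort_spec(n_insomnia = n_per_class, n_healthy = n_per_class,
                      duration_s = duration_s, seed = seed)
  preprocess_cohort(simulate_cohort(spec), epoch_s = epoch_s)
}

expect_rel_close <- function(actual, expected, rel_tol) {
  expect_lt(abs(actual - expected), rel_tol * abs(expected))
}
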