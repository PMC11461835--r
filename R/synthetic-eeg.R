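#' Specification of a synthetic two-class EEG cohort
#'
#' Describes a cohort of single-channel EEG recordings with class-dependent
#' band powers, so that every downstream stage (decomposition, augmentation,
#' features, classification) can be exercised without any external recordings.
#' Each subject's trace is a sum of five independent band-limited Gaussian
#' noise processes (flat spectrum inside the band, synthesized in the
#' frequency domain, with edges on the dyadic analysis bands) at the class's
#' target band powers, plus optional powerline and baseline-drift artifacts.
#'
#' Default band powers (uV^2) follow the usual sleep-EEG ordering
#' (delta-dominant) with a hyperarousal-like profile for the insomnia class:
#' elevated alpha/beta, reduced delta. A per-subject log-normal power factor
#' (`subject_sd` on the log scale) models between-subject amplitude
#' variability.
#'
#' @param n_insomnia,n_healthy Subjects per class.
#' @param fs Sampling rate in Hz (power of two; default 512).
#' @param duration_s Recording length in seconds.
#' @param band_power_map Named list `list(insomnia =, healthy =)` of named
#'   numeric vectors (delta, theta, alpha, beta, gamma) of target band powers
#'   in uV^2.
#' @param subject_sd Log-scale SD of the per-subject power factor (applied to
#'   all bands of a subject; 0 disables it).
#' @param powerline_amp,powerline_hz Powerline artifact amplitude (uV) and
#'   frequency; amplitude 0 disables.
#' @param drift_amp Baseline-drift amplitude (uV, slow sinusoid below 0.3 Hz);
#'   0 disables.
#' @param channel Channel label written to metadata and EDF headers.
#' @param seed Integer seed; the whole cohort is a pure function of the spec.
#' @return A list of class `sleepaug_cohort_spec`.
#' @export
cohort_spec <- function(n_insomnia = 6, n_healthy = 6, fs = 512,
                        duration_s = 60,
                        band_power_map = default_band_powers(),
                        subject_sd = 0.1,
                        powerline_amp = 0, powerline_hz = 50,
                        drift_amp = 0, channel = "C4-A1", seed = 1L) {
  if (duration_s <= 0) abort("duration_s must be positive.",
                             class = "sleepaug_spec_error")
  if (n_insomnia < 0 || n_healthy < 0 || n_insomnia + n_healthy < 1) {
    abort("Cohort must contain at least one subject.",
          class = "sleepaug_spec_error")
  }
  for (g in c("insomnia", "healthy")) {
    bp <- band_power_map[[g]]
    if (is.null(bp) || !all(BAND_NAMES %in% names(bp)) || any(bp < 0)) {
      abort("band_power_map needs non-negative powers for all five bands and both classes.",
            class = "sleepaug_spec_error")
    }
  }
  structure(list(
    n_insomnia = as.integer(n_insomnia), n_healthy = as.integer(n_healthy),
    fs = fs, duration_s = duration_s, band_power_map = band_power_map,
    subject_sd = subject_sd, powerline_amp = powerline_amp,
    powerline_hz = powerline_hz, drift_amp = drift_amp,
    channel = channel, seed = as.integer(seed)),
    class = "sleepaug_cohort_spec")
}

#' Default class-dependent band-power targets (uV^2)
#'
#' Delta-dominant profile typical of overnight EEG, with the insomnia class
#' showing the hyperarousal pattern reported across the insomnia literature:
#' reduced delta, elevated alpha and beta.
#' @return Named list with `insomnia` and `healthy` band-power vectors.
#' @export
default_band_powers <- function() {
  list(
    healthy  = c(delta = 40, theta = 12, alpha = 4.0, beta = 2.0, gamma = 0.5),
    insomnia = c(delta = 30, theta = 10, alpha = 5.5, beta = 3.0, gamma = 0.7))
}

#' Cohort spec with a calibrated alpha band-power class gap
#'
#' Builds a [cohort_spec()] whose only class difference is alpha band power,
#' planted so that the per-subject alpha power *as measured by the analysis
#' chain* (bandpass + db8 decomposition + mean square) separates the class
#' means by `gap_sd` within-class standard deviations. With class-level band
#' powers (the default, `subject_sd = 0`) the within-class SD is the
#' band-power estimation noise of a finite recording, relative SD
#' `1 / sqrt(BW * T)` for dyadic alpha bandwidth `BW = fs/64` Hz and duration
#' `T`; configured between-subject variability is added in quadrature.
#'
#' Because the dyadic wavelet analyzer captures only part of the planted
#' alpha power and adds leakage from neighbouring bands, the helper measures
#' the planted-to-measured slope and the measured baseline directly, by
#' analysing two probe recordings generated with common random numbers
#' (identical draws, alpha power differing by 1 uV^2), and converts the
#' target measured gap back into generator units.
#'
#' @param gap_sd Class separation in pooled-SD units (default 2).
#' @param alpha_healthy Healthy-class planted alpha power (uV^2).
#' @inheritParams cohort_spec
#' @param ... Passed on to [cohort_spec()].
#' @return A `sleepaug_cohort_spec`.
#' @export
planted_alpha_spec <- function(gap_sd = 2, alpha_healthy = 4,
                               fs = 512, duration_s = 60, subject_sd = 0,
                               ...) {
  base <- c(delta = 40, theta = 12, alpha = alpha_healthy,
            beta = 2.0, gamma = 0.5)
  measure_alpha <- function(alpha_power) {
    bp <- base
    bp["alpha"] <- alpha_power
    probe <- cohort_spec(1, 1, fs = fs, duration_s = duration_s,
                         band_power_map = list(healthy = bp, insomnia = bp),
                         subject_sd = 0, seed = 240000L)
    x <- generate_subject(probe, "healthy", 1)
    mean(decompose_bands(bandpass_filter(x, fs), fs)$bands$alpha^2)
  }
  m0 <- measure_alpha(alpha_healthy)
  slope <- measure_alpha(alpha_healthy + 1) - m0   # common random numbers
  bw <- fs / 64
  rel_sd <- sqrt(subject_sd^2 + 1 / (bw * duration_s))
  delta_alpha <- gap_sd * rel_sd * m0 / slope
  ins <- base
  ins["alpha"] <- alpha_healthy + delta_alpha
  cohort_spec(fs = fs, duration_s = duration_s, subject_sd = subject_sd,
              band_power_map = list(healthy = base, insomnia = ins), ...)
}

# Band-limited Gaussian noise synthesized in the frequency domain: complex
# Gaussian weights on the FFT bins inside [lo, hi), zero elsewhere, scaled so
# the expected time-domain variance equals `power`. The realized variance
# fluctuates like chi^2 with 2*BW*T degrees of freedom (relative SD about
# 1/sqrt(BW*T)), the natural estimation noise of a finite recording.
band_noise <- function(n, fs, lo, hi, power) {
  freqs <- (seq_len(n %/% 2)) * fs / n      # positive-frequency bins 1..n/2
  in_band <- which(freqs >= lo & freqs < hi)
  m <- length(in_band)
  if (m == 0 || power <= 0) return(numeric(n))
  sigma <- n * sqrt(power / (2 * m))
  z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m)) *
    (sigma / sqrt(2))
  spec <- complex(real = numeric(n), imaginary = numeric(n))
  spec[in_band + 1L] <- z
  spec[n - in_band + 1L] <- Conj(z)
  Re(stats::fft(spec, inverse = TRUE)) / n
}

# Dyadic synthesis band edges aligned with band_level_map(); gamma is capped
# at the 45 Hz analysis bandpass edge.
synthesis_band_edges <- function(fs) {
  e <- fs / 64
  list(delta = c(0.5, e / 2), theta = c(e / 2, e), alpha = c(e, 2 * e),
       beta = c(2 * e, 4 * e), gamma = c(4 * e, min(8 * e, 45)))
}

subject_seed <- function(seed, group, subject_index) {
  g <- if (group == "insomnia") 1L else 2L
  as.integer((as.double(seed) * 10007 + g * 524287 + subject_index * 7919) %% 2147483647)
}

#' Generate one synthetic EEG recording
#'
#' Draws a single subject's trace under a cohort spec: five independent
#' band-limited Gaussian processes at the class's target band powers
#' (multiplied by the subject's log-normal power factor), plus any configured
#' artifacts. Deterministic for a fixed spec seed and subject index.
#'
#' @param spec A [cohort_spec()].
#' @param group `"insomnia"` or `"healthy"`.
#' @param subject_index Positive integer identifying the subject within its
#'   class.
#' @return Numeric vector of samples (uV), length `duration_s * fs`.
#' @export
generate_subject <- function(spec, group, subject_index) {
  stopifnot(inherits(spec, "sleepaug_cohort_spec"))
  group <- match.arg(group, c("insomnia", "healthy"))
  n <- as.integer(round(spec$duration_s * spec$fs))
  withr_seed <- subject_seed(spec$seed, group, subject_index)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(withr_seed)
  powers <- spec$band_power_map[[group]]
  subj_factor <- if (spec$subject_sd > 0) exp(stats::rnorm(1, 0, spec$subject_sd)) else 1
  edges <- synthesis_band_edges(spec$fs)
  x <- numeric(n)
  for (b in BAND_NAMES) {
    p <- powers[[b]] * subj_factor
    if (p <= 0) next
    x <- x + band_noise(n, spec$fs, edges[[b]][1], edges[[b]][2], p)
  }
  tt <- seq_len(n) / spec$fs
  if (spec$powerline_amp > 0) {
    x <- x + spec$powerline_amp * sin(2 * pi * spec$powerline_hz * tt)
  }
  if (spec$drift_amp > 0) {
    f0 <- stats::runif(1, 0.05, 0.3)
    x <- x + spec$drift_amp * sin(2 * pi * f0 * tt + stats::runif(1, 0, 2 * pi))
  }
  x
}

.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

sec_to_clock <- function(s) {
  s <- as.integer(round(s)) %% 86400L
  sprintf("%02d:%02d:%02d", s %/% 3600L, (s %/% 60L) %% 60L, s %% 60L)
}

# Draw in-bed / onset / out-of-bed clock times for one subject. Insomnia
# subjects get sleep latency > 20 min, healthy subjects <= 20 min (the usual
# clinical cutoff). Midnight wrap allowed (end clock < start clock).
draw_clock_times <- function(group) {
  start <- round(stats::runif(1, 21 * 3600, 24 * 3600))
  if (group == "insomnia") {
    sl_min <- stats::runif(1, 25, 300)
    tib_min <- stats::runif(1, 6 * 60, 14 * 60)
    waso <- round(stats::runif(1, 30, 460))
  } else {
    sl_min <- stats::runif(1, 1, 20)
    tib_min <- stats::runif(1, 6 * 60, 9 * 60)
    waso <- round(stats::runif(1, 0, 140))
  }
  tib_min <- max(tib_min, sl_min + 30)
  list(sleep_start = sec_to_clock(start),
       sleep_onset = sec_to_clock(start + round(sl_min * 60)),
       sleep_end   = sec_to_clock(start + round(tib_min * 60)),
       waso_min    = waso)
}

#' Simulate a full two-class EEG cohort
#'
#' Generates all subjects of a [cohort_spec()] together with per-subject
#' recording metadata (clock times drawn so that insomnia subjects have sleep
#' latency > 20 min and healthy subjects <= 20 min). The result is a tibble
#' with one row per recording; signals live in the `samples` list-column.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `subject_id`, `group`, `fs`, `channel`,
#'   `sleep_start`, `sleep_onset`, `sleep_end`, `waso_min` and the `samples`
#'   list-column.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_insomnia = 1, n_healthy = 1,
#'                                       duration_s = 4, fs = 512))
#' cohort$group
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sleepaug_cohort_spec"))
  rows <- list()
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  for (group in c("insomnia", "healthy")) {
    n_g <- if (group == "insomnia") spec$n_insomnia else spec$n_healthy
    prefix <- if (group == "insomnia") "INS" else "H"
    for (i in seq_len(n_g)) {
      x <- generate_subject(spec, group, i)
      set.seed(subject_seed(spec$seed, group, i) %% 2147483000L + 17L)
      ct <- draw_clock_times(group)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = paste0(prefix, i), group = group,
        fs = spec$fs, channel = spec$channel,
        sleep_start = ct$sleep_start, sleep_onset = ct$sleep_onset,
        sleep_end = ct$sleep_end, waso_min = ct$waso_min,
        samples = list(x))
    }
  }
  dplyr::bind_rows(rows)
}
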