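#' Configuration for signal-level (layer 1) augmentation
#'
#' Layer 1 generates Scaled Synthetic Signals (cycle MCSA-1, per-band-segment
#' amplitude scaling) and Noise-Injected Synthetic Signals (cycle MCSA-2,
#' per-band-segment additive white Gaussian noise), each with an addition set
#' and a convolution set (convolved with the filtered raw trace and
#' power-renormalized).
#'
#' @param scale_factor Amplitude factor for MCSA-1 (default 1.5;
#'   amplification, i.e. > 1, is the intended regime - attenuation discards
#'   signal content).
#' @param snr_db Signal-to-noise ratio (dB) of the injected noise relative to
#'   the targeted band-segment's power (default 10).
#' @param convolution_mode Only `"same-normalized"`: same-length convolution
#'   with the spectrum-normalized (all-pass) kernel, output rescaled to the
#'   input's power, so every band's power is carried through intact.
#' @param seed Integer seed for the noise realizations.
#' @return A list of class `sleepaug_mcsa_config`.
#' @export
mcsa_config <- function(scale_factor = 1.5, snr_db = 10,
                        convolution_mode = "same-normalized", seed = 1L) {
  convolution_mode <- match.arg(convolution_mode, "same-normalized")
  if (scale_factor < 0) abort("scale_factor must be non-negative.",
                              class = "sleepaug_spec_error")
  if (!is.finite(snr_db)) snr_db <- 120
  structure(list(scale_factor = scale_factor, snr_db = min(snr_db, 120),
                 convolution_mode = convolution_mode, seed = as.integer(seed)),
            class = "sleepaug_mcsa_config")
}

aug_row <- function(samples, fs, label, cycle, op, band, segment_idx, param,
                    seed, source_subject) {
  tibble::tibble(
    samples = list(samples), fs = fs, label = label, cycle = cycle, op = op,
    band = band, segment_idx = segment_idx, param = param, seed = seed,
    source_subject = source_subject)
}

check_band_segment <- function(seg, band, segment_idx) {
  stopifnot(inherits(seg, "sleepaug_segments"))
  if (!band %in% BAND_NAMES) {
    abort(sprintf("Unknown band '%s'.", band), class = "sleepaug_index_error")
  }
  if (segment_idx < 1 || segment_idx > seg$n_segments) {
    abort(sprintf("Segment index %d out of range (1..%d).",
                  segment_idx, seg$n_segments),
          class = "sleepaug_index_error")
  }
}

#' Scale one band-segment and recombine (MCSA-1 addition set)
#'
#' Multiplies the chosen band's chosen epoch by `factor` and adds back the
#' untouched epochs of that band plus all epochs of the other four bands,
#' giving a full-length synthetic trace that differs from the raw
#' reconstruction only inside the targeted band-segment.
#'
#' @param seg A `sleepaug_segments` object.
#' @param band Band name (`"delta"`, ..., `"gamma"`).
#' @param segment_idx Epoch index (1-based).
#' @param factor Non-negative amplitude factor.
#' @param label,source_subject Optional provenance carried into the result.
#' @return One-row augmented-signal tibble (samples, fs, label, cycle, op,
#'   band, segment_idx, param, seed, source_subject).
#' @export
scale_band_segment <- function(seg, band, segment_idx, factor,
                               label = NA_character_,
                               source_subject = NA_character_) {
  check_band_segment(seg, band, segment_idx)
  if (factor < 0) abort("factor must be non-negative.",
                        class = "sleepaug_index_error")
  segs <- seg$segments
  segs[[band]][, segment_idx] <- segs[[band]][, segment_idx] * factor
  out <- as.numeric(Reduce(`+`, segs))
  aug_row(out, seg$fs, label, "MCSA1", "addition", band, segment_idx,
          factor, NA_integer_, source_subject)
}

#' Inject white Gaussian noise into one band-segment (MCSA-2 addition set)
#'
#' Adds white Gaussian noise with power `P_segment / 10^(snr_db/10)` to the
#' chosen band-segment only, then recombines as in [scale_band_segment()].
#' The realized noise vector is attached to the samples as attribute
#' `injected_noise` so the achieved SNR can be measured directly.
#'
#' @inheritParams scale_band_segment
#' @param snr_db Target signal-to-noise ratio in dB (capped at 120).
#' @param seed Integer seed; identical seeds give identical realizations.
#' @return One-row augmented-signal tibble.
#' @export
inject_noise_band_segment <- function(seg, band, segment_idx, snr_db, seed,
                                      label = NA_character_,
                                      source_subject = NA_character_) {
  check_band_segment(seg, band, segment_idx)
  snr_db <- min(snr_db, 120)
  p_sig <- mean(seg$segments[[band]][, segment_idx]^2)
  if (p_sig <= 0) {
    abort("Targeted band-segment has zero power: SNR undefined.",
          class = "sleepaug_degenerate_snr_error")
  }
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  noise <- stats::rnorm(seg$seg_len, sd = sqrt(p_sig / 10^(snr_db / 10)))
  segs <- seg$segments
  segs[[band]][, segment_idx] <- segs[[band]][, segment_idx] + noise
  out <- as.numeric(Reduce(`+`, segs))
  attr(out, "injected_noise") <- noise
  aug_row(out, seg$fs, label, "MCSA2", "addition", band, segment_idx,
          snr_db, as.integer(seed), source_subject)
}

# Same-length convolution with the spectrum-normalized (all-pass) kernel,
# rescaled to the input's power. Normalizing the kernel's magnitude spectrum
# to 1 keeps every band's power intact - convolving with the raw broadband
# spectrum itself would square the spectrum and collapse the band structure
# the downstream features are built on - while the kernel's phase still
# produces a genuinely different waveform.
conv_same_norm <- function(x, kernel) {
  n <- length(x); m <- length(kernel)
  nfft <- 2^ceiling(log2(n + m - 1))
  K <- stats::fft(c(kernel, numeric(nfft - m)))
  mag <- Mod(K)
  K <- ifelse(mag > 1e-300, K / mag, 1 + 0i)
  y_full <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) * K,
                          inverse = TRUE)) / nfft
  start <- (m - 1) %/% 2
  y <- y_full[start + seq_len(n)]
  p_in <- mean(x^2); p_out <- mean(y^2)
  if (p_out > 0) y <- y * sqrt(p_in / p_out)
  y
}

#' Convolve an augmented signal with the filtered raw trace (convolution set)
#'
#' Convolution of the augmented trace with the subject's filtered raw EEG,
#' truncated to the input length ("same" alignment) and rescaled so the
#' output power equals the augmented input's power. The kernel's magnitude
#' spectrum is normalized to 1 (all-pass) first: the augmentation is then
#' carried by the raw trace's phase structure and produces a genuinely
#' different waveform while leaving every band's power - the substrate of the
#' downstream features - unchanged. (Convolving with the raw broadband
#' spectrum itself would square the spectrum and collapse the band
#' structure, changing exactly the signal characteristics augmentation is
#' meant to preserve.) Produces the second signal set of each MCSA cycle.
#'
#' @param aug One-row augmented-signal tibble (from [scale_band_segment()] or
#'   [inject_noise_band_segment()]).
#' @param raw_filtered Numeric vector: the subject's denoised + bandpassed
#'   trace, at the same sampling rate.
#' @param fs Sampling rate of `raw_filtered`; must match `aug$fs`.
#' @return One-row augmented-signal tibble with `op = "convolution"`.
#' @export
convolve_with_raw <- function(aug, raw_filtered, fs = aug$fs[1]) {
  stopifnot(is.data.frame(aug), nrow(aug) == 1)
  if (!isTRUE(all.equal(fs, aug$fs[1]))) {
    abort("Sampling-rate mismatch between augmented signal and raw trace.",
          class = "sleepaug_config_error")
  }
  x <- as.numeric(aug$samples[[1]])
  out <- aug
  out$samples <- list(conv_same_norm(x, as.numeric(raw_filtered)))
  out$op <- "convolution"
  out
}

#' Run full layer-1 augmentation over a preprocessed cohort
#'
#' For every subject, band and epoch, emits four synthetic signals: MCSA-1
#' addition (scaled band-segment), MCSA-1 convolution, MCSA-2 addition
#' (noise-injected band-segment) and MCSA-2 convolution - in total
#' `4 * subjects * 5 bands * epochs` rows, labels inherited from the source
#' subject.
#'
#' @param cohort Preprocessed cohort tibble ([preprocess_cohort()] output:
#'   needs `subject_id`, `group`, `segments`, `filtered`).
#' @param cfg An [mcsa_config()].
#' @return Augmented-signal tibble, one row per synthetic signal.
#' @export
run_mcsa <- function(cohort, cfg = mcsa_config()) {
  stopifnot(inherits(cfg, "sleepaug_mcsa_config"),
            is.data.frame(cohort),
            all(c("subject_id", "group", "segments", "filtered") %in% names(cohort)))
  out <- vector("list", 0L)
  for (i in seq_len(nrow(cohort))) {
    seg <- cohort$segments[[i]]
    raw <- cohort$filtered[[i]][seq_len(seg$seg_len * seg$n_segments)]
    lab <- cohort$group[i]
    sid <- cohort$subject_id[i]
    for (b in BAND_NAMES) {
      for (g in seq_len(seg$n_segments)) {
        tuple_seed <- as.integer(
          (as.double(cfg$seed) * 48271 + i * 65537 +
             match(b, BAND_NAMES) * 8191 + g * 127) %% 2147483647)
        a1 <- scale_band_segment(seg, b, g, cfg$scale_factor,
                                 label = lab, source_subject = sid)
        a2 <- inject_noise_band_segment(seg, b, g, cfg$snr_db, tuple_seed,
                                        label = lab, source_subject = sid)
        out[[length(out) + 1L]] <- a1
        out[[length(out) + 1L]] <- convolve_with_raw(a1, raw)
        out[[length(out) + 1L]] <- a2
        out[[length(out) + 1L]] <- convolve_with_raw(a2, raw)
      }
    }
  }
  if (!length(out)) {
    return(aug_row(numeric(), NA_real_, NA_character_, NA_character_,
                   NA_character_, NA_character_, NA_integer_, NA_real_,
                   NA_integer_, NA_character_)[0, ])
  }
  dplyr::bind_rows(out)
}
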