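#' Wavelet denoising of an EEG trace
#'
#' Removes sparse artifacts by soft-thresholding the detail coefficients of a
#' db8 wavelet decomposition with the universal threshold
#' \eqn{\sigma \sqrt{2 \log n}}, where \eqn{\sigma} is estimated from the
#' finest detail level by the median absolute deviation. The approximation
#' coefficients are left untouched, so slow physiological content passes
#' through unchanged.
#'
#' @param x Numeric EEG samples (microvolts).
#' @param level Decomposition depth (default 5).
#' @param rule Thresholding rule; only `"universal-soft"` is implemented.
#' @return Denoised signal, same length as `x`.
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 1, by = 1 / 256))
#' x[50] <- x[50] + 25          # impulse artifact
#' y <- denoise_wavelet(x)
denoise_wavelet <- function(x, level = 5, rule = "universal-soft") {
  rule <- match.arg(rule, "universal-soft")
  if (length(x) < 2^level) {
    abort("Signal too short for the requested denoising depth.",
          class = "sleepaug_input_error")
  }
  cf <- dwt_forward(x, level)
  sigma <- stats::median(abs(cf$d[[1]])) / 0.6745
  thr <- sigma * sqrt(2 * log(cf$n_pad))
  cf$d <- lapply(cf$d, function(d) sign(d) * pmax(abs(d) - thr, 0))
  dwt_inverse(cf)
}

#' Zero-phase Butterworth bandpass filter
#'
#' Band-limits an EEG trace to the clinical range of interest (default
#' 0.5-45 Hz) with an order-`order` Butterworth design applied
#' forward-backward (zero phase), so waveform timing is preserved for later
#' segment alignment.
#'
#' @param x Numeric samples.
#' @param fs Sampling rate (Hz).
#' @param lo,hi Band edges in Hz; must satisfy `0 < lo < hi < fs/2`.
#' @param order Filter order (default 4; effective order doubles under the
#'   forward-backward pass).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, lo = 0.5, hi = 45, order = 4) {
  if (!(lo > 0 && lo < hi && hi < fs / 2)) {
    abort("Band edges must satisfy 0 < lo < hi < fs/2.",
          class = "sleepaug_band_error")
  }
  # Cascaded high/low-pass (better conditioned than one order-2n bandpass
  # polynomial with a sub-hertz corner), each applied forward-backward over
  # an odd-reflection extension long enough for the slow highpass transient.
  hp <- signal::butter(order, lo / (fs / 2), type = "high")
  lp <- signal::butter(order, hi / (fs / 2), type = "low")
  pad_filtfilt(lp, pad_filtfilt(hp, x, fs), fs)
}

pad_filtfilt <- function(flt, x, fs) {
  n <- length(x)
  p <- min(n - 1, as.integer(3 * fs))
  pre <- 2 * x[1] - x[(p + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - p)]
  y <- signal::filtfilt(flt, c(pre, x, post))
  as.numeric(y[(p + 1):(p + n)])
}

#' Five-band wavelet decomposition of an EEG trace
#'
#' Runs a multilevel db8 DWT (7 levels at 512 Hz; see [band_level_map()]) and
#' reconstructs each clinical band (delta, theta, alpha, beta, gamma) in the
#' time domain by inverting the transform with all other coefficient subsets
#' zeroed. By linearity and orthogonality of the transform, the five bands
#' plus the residual (content above the gamma edge) sum exactly back to the
#' input.
#'
#' @param x Numeric samples.
#' @param fs Sampling rate in Hz (power of two >= 128, or supply `map`).
#' @param map Optional explicit band/level map as returned by
#'   [band_level_map()], for sampling rates without a dyadic default.
#' @return A list of class `sleepaug_bands`: `bands` (named list of five
#'   numeric vectors, each the length of `x`), `residual`, `fs`.
#' @export
#' @examples
#' fs <- 512
#' x <- sin(2 * pi * 10 * seq(0, 2, by = 1 / fs))
#' dec <- decompose_bands(x, fs)
#' sapply(dec$bands, function(b) mean(b^2))
decompose_bands <- function(x, fs, map = NULL) {
  if (is.null(map)) map <- band_level_map(fs)
  if (length(x) < 2^7) {
    abort("Signal too short for a five-band decomposition.",
          class = "sleepaug_input_error")
  }
  cf <- dwt_forward(x, map$level)
  bands <- lapply(map$map[BAND_NAMES], function(keep) dwt_inverse(dwt_keep(cf, keep)))
  residual <- if (length(map$map$residual)) {
    dwt_inverse(dwt_keep(cf, map$map$residual))
  } else {
    numeric(length(x))
  }
  structure(list(bands = bands, residual = residual, fs = fs),
            class = "sleepaug_bands")
}

#' Cut a band decomposition into aligned fixed-length epochs
#'
#' Each of the five band signals is cut into identical, non-overlapping
#' `epoch_s`-second segments; a trailing partial epoch is dropped. Segments of
#' different bands stay sample-aligned, which the signal-level augmentation
#' relies on.
#'
#' @param dec A `sleepaug_bands` object from [decompose_bands()].
#' @param epoch_s Epoch length in seconds (default 30).
#' @return A list of class `sleepaug_segments`: `segments` (named list, one
#'   `seg_len x n_segments` matrix per band; columns are epochs), `fs`,
#'   `epoch_s`, `n_segments`, `seg_len`.
#' @export
segment_bands <- function(dec, epoch_s = 30) {
  stopifnot(inherits(dec, "sleepaug_bands"))
  seg_len <- as.integer(floor(epoch_s * dec$fs))
  if (seg_len < 1) abort("Epoch must span at least one sample.",
                         class = "sleepaug_input_error")
  n <- length(dec$bands[[1]])
  n_seg <- n %/% seg_len
  if (n_seg < 1) {
    abort("Epoch longer than the signal: nothing to segment.",
          class = "sleepaug_empty_segmentation_error")
  }
  used <- seg_len * n_seg
  segs <- lapply(dec$bands, function(b) matrix(b[seq_len(used)], nrow = seg_len))
  structure(list(segments = segs, fs = dec$fs, epoch_s = epoch_s,
                 n_segments = n_seg, seg_len = seg_len),
            class = "sleepaug_segments")
}

# Full-length reconstruction from segments: sum of the five band matrices,
# flattened back to a single trace of length seg_len * n_segments.
segments_reconstruct <- function(seg) {
  as.numeric(Reduce(`+`, seg$segments))
}

#' Preprocess every recording of a cohort
#'
#' Applies the full preprocessing chain - wavelet denoising, 0.5-45 Hz
#' zero-phase Butterworth bandpass, five-band db8 decomposition, epoch
#' segmentation - to each row of a cohort tibble (as produced by
#' [simulate_cohort()] or [read_edf()]).
#'
#' @param cohort A cohort tibble with at least `subject_id`, `group`, `fs`
#'   and a `samples` list-column.
#' @param lo,hi,order Bandpass parameters, see [bandpass_filter()].
#' @param denoise_level Wavelet denoising depth; `0` skips denoising.
#' @param epoch_s Segmentation epoch in seconds.
#' @return The cohort tibble with added list-columns `filtered` (numeric
#'   vectors) and `segments` (`sleepaug_segments` objects).
#' @export
preprocess_cohort <- function(cohort, lo = 0.5, hi = 45, order = 4,
                              denoise_level = 5, epoch_s = 30) {
  stopifnot(is.data.frame(cohort), all(c("fs", "samples") %in% names(cohort)))
  filtered <- purrr::map2(cohort$samples, cohort$fs, function(x, fs) {
    if (denoise_level > 0) x <- denoise_wavelet(x, level = denoise_level)
    bandpass_filter(x, fs, lo = lo, hi = hi, order = order)
  })
  segments <- purrr::map2(filtered, cohort$fs, function(x, fs) {
    segment_bands(decompose_bands(x, fs), epoch_s = epoch_s)
  })
  cohort$filtered <- filtered
  cohort$segments <- segments
  cohort
}
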