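FEATURE_NAMES <- c("sample_entropy", "spectral_entropy", "shannon_entropy",
                   "log_energy_entropy", "band_power", "mean", "std",
                   "skewness", "kurtosis")

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A/B), where B counts pairs of length-`m` templates and A
#' pairs of length-`m+1` templates lying within Chebyshev distance
#' `r * sd(x)` of each other (population SD), self-matches excluded, both
#' template sets taken over start indices `1..n-m` (Richman-Moorman
#' convention). Lower values indicate a more regular signal.
#'
#' If no templates match at either length the estimator is undefined; a cap
#' of `ln(B_pairs * (B_pairs - 1))` (total comparable pair count) is returned
#' instead of infinity so downstream feature tables stay finite.
#'
#' @param x Numeric sequence, length > `m + 1`.
#' @param m Template length (default 2).
#' @param r Tolerance as a fraction of the SD of `x` (default 0.2).
#' @return Dimensionless non-negative value.
#' @export
#' @examples
#' sample_entropy(sin(seq(0, 20, by = 0.1)))
#' sample_entropy(rnorm(500))
sample_entropy <- function(x, m = 2, r = 0.2) {
  n <- length(x)
  if (n <= m + 1) abort("Sequence too short for sample entropy.",
                        class = "sleepaug_input_error")
  sdx <- sqrt(mean((x - mean(x))^2))
  if (sdx == 0) return(0)
  cnt <- sampen_counts(as.numeric(x), as.integer(m), r * sdx)
  nt <- n - m
  cap <- log(nt * (nt - 1))
  if (cnt$B == 0 || cnt$A == 0) return(cap)
  min(-log(cnt$A / cnt$B), cap)
}

# Welch power spectral density: Hann-windowed overlapping segments,
# averaged periodograms. Returns one-sided PSD (unnormalized scale).
welch_psd <- function(x, n_seg = 256, overlap = 0.5) {
  n <- length(x)
  n_seg <- min(n_seg, n)
  step <- max(1L, as.integer(round(n_seg * (1 - overlap))))
  starts <- seq.int(1L, n - n_seg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_seg) / (n_seg + 1))
  nh <- n_seg %/% 2 + 1L
  acc <- numeric(nh)
  for (s in starts) {
    seg <- x[s:(s + n_seg - 1L)] * w
    p <- Mod(stats::fft(seg))^2
    acc <- acc + p[seq_len(nh)]
  }
  acc / length(starts)
}

#' Normalized spectral entropy
#'
#' Shannon entropy of the Welch power spectral density (Hann windows, 50%
#' overlap) normalized to a probability distribution over frequency bins,
#' divided by `log2` of the bin count - so a pure tone approaches 0 and white
#' noise approaches 1. Invariant to amplitude scaling.
#'
#' @param x Numeric sequence, length >= 64.
#' @param fs Sampling rate in Hz (bin layout only; the value is
#'   scale-invariant in `fs`).
#' @return Value in \[0, 1\]; 0 for an all-zero signal.
#' @export
spectral_entropy <- function(x, fs = 1) {
  if (length(x) < 64) abort("Need at least 64 samples for spectral entropy.",
                            class = "sleepaug_input_error")
  psd <- welch_psd(x)
  tot <- sum(psd)
  if (tot <= 0) return(0)
  p <- psd / tot
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(length(psd))
}

#' Histogram Shannon entropy (bits)
#'
#' Amplitude-distribution entropy: the samples are binned into `bins`
#' equal-width cells spanning the observed range, and
#' \eqn{H = -\sum p \log_2 p} is computed over non-empty cells. Invariant to
#' affine amplitude maps (the bin grid follows the observed range).
#'
#' @param x Numeric sequence.
#' @param bins Number of histogram cells (default 256).
#' @return Entropy in bits, in `[0, log2(bins)]`; 0 for a constant signal.
#' @export
shannon_entropy <- function(x, bins = 256) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  cuts <- seq(rng[1], rng[2], length.out = bins + 1)
  cnt <- tabulate(pmin(findInterval(x, cuts, rightmost.closed = TRUE), bins),
                  nbins = bins)
  p <- cnt[cnt > 0] / length(x)
  -sum(p * log2(p))
}

#' Log-energy entropy
#'
#' \eqn{\sum_i \log(x_i^2 + \epsilon)} with \eqn{\epsilon = 10^{-12}}
#' guarding zero samples; a wavelet-packet-style energy measure.
#'
#' @param x Numeric sequence.
#' @return Unbounded real value.
#' @export
log_energy_entropy <- function(x) {
  sum(log(x^2 + 1e-12))
}

#' Band power
#'
#' Mean squared amplitude (uV^2) of a band-limited time series.
#'
#' @param x Numeric sequence (typically one band of [decompose_bands()]).
#' @return Non-negative value.
#' @export
band_power <- function(x) mean(x^2)

#' First four statistical moments
#'
#' Mean, population standard deviation, standardized skewness and *excess*
#' kurtosis (0 for a Gaussian). Skewness and kurtosis are defined as 0 for a
#' zero-variance sequence.
#'
#' @param x Numeric sequence, length >= 4.
#' @return Named numeric vector `(mean, std, skewness, kurtosis)`.
#' @export
stat_moments <- function(x) {
  if (length(x) < 4) abort("Need at least 4 samples for moments.",
                           class = "sleepaug_input_error")
  mu <- mean(x)
  v <- mean((x - mu)^2)
  if (v == 0) return(c(mean = mu, std = 0, skewness = 0, kurtosis = 0))
  s <- sqrt(v)
  c(mean = mu, std = s,
    skewness = mean((x - mu)^3) / s^3,
    kurtosis = mean((x - mu)^4) / v^2 - 3)
}

band_feature_vector <- function(band_signal, fs, sampen_max_n) {
  xs <- band_signal[seq_len(min(length(band_signal), sampen_max_n))]
  mom <- stat_moments(band_signal)
  c(sample_entropy = sample_entropy(xs),
    spectral_entropy = spectral_entropy(band_signal, fs),
    shannon_entropy = shannon_entropy(band_signal),
    log_energy_entropy = log_energy_entropy(band_signal),
    band_power = band_power(band_signal),
    mom)
}

#' Feature-table column names (45 band-wise features)
#'
#' @return Character vector: 9 features for each of the five bands, band-major
#'   order (`delta_sample_entropy`, ..., `gamma_kurtosis`).
#' @export
feature_columns <- function() {
  as.vector(vapply(BAND_NAMES,
                   function(b) paste(b, FEATURE_NAMES, sep = "_"),
                   character(length(FEATURE_NAMES))))
}

#' Extract the band-wise feature table from signals
#'
#' Decomposes each signal into the five clinical bands and computes 9
#' features per band (sample, spectral, Shannon and log-energy entropy, band
#' power, mean, SD, skewness, excess kurtosis) on the full-length band
#' reconstructions: 45 numeric columns per row, plus label, subject id and
#' provenance. Accepts either an augmented-signal tibble (from [run_mcsa()])
#' or a raw cohort tibble; raw rows get `provenance = "real"`.
#'
#' Sample entropy (quadratic cost) is evaluated on the first `sampen_max_n`
#' samples of each band; all other features use the full band signal.
#'
#' @param signals Tibble with `samples` list-column, `fs`, and either
#'   `label`/`source_subject` (augmented) or `group`/`subject_id` (cohort)
#'   columns.
#' @param sampen_max_n Sample-entropy window cap (default 2048).
#' @return Tibble: 45 feature columns + `label`, `subject_id`, `provenance`;
#'   no missing values.
#' @export
extract_features <- function(signals, sampen_max_n = 2048) {
  stopifnot(is.data.frame(signals), "samples" %in% names(signals))
  is_aug <- "cycle" %in% names(signals)
  label <- if ("label" %in% names(signals)) signals$label else signals$group
  subject <- if ("source_subject" %in% names(signals)) signals$source_subject
             else signals$subject_id
  prov <- if (is_aug) paste(signals$cycle, signals$op, sep = "_")
          else rep("real", nrow(signals))
  rows <- vector("list", nrow(signals))
  for (i in seq_len(nrow(signals))) {
    fs <- signals$fs[i]
    dec <- decompose_bands(as.numeric(signals$samples[[i]]), fs)
    feats <- unlist(lapply(BAND_NAMES, function(b) {
      v <- band_feature_vector(dec$bands[[b]], fs, sampen_max_n)
      names(v) <- paste(b, FEATURE_NAMES, sep = "_")
      v
    }))
    rows[[i]] <- tibble::as_tibble_row(as.list(feats))
  }
  out <- dplyr::bind_rows(rows)
  out <- out[, feature_columns()]
  out$label <- label
  out$subject_id <- subject
  out$provenance <- prov
  stopifnot(!anyNA(out[feature_columns()]))
  out
}

#' Select one band's feature columns (or all)
#'
#' @param features A feature tibble from [extract_features()].
#' @param band One of the five band names or `"combined"` (all 45 columns).
#' @return The feature tibble restricted to the chosen numeric columns, with
#'   label/subject/provenance kept.
#' @export
band_subset <- function(features, band = "combined") {
  band <- match.arg(band, c("combined", BAND_NAMES))
  keep <- if (band == "combined") feature_columns() else
    paste(band, FEATURE_NAMES, sep = "_")
  extra <- intersect(c("label", "subject_id", "provenance"), names(features))
  features[, c(keep, extra)]
}
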