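#' @useDynLib sleepaug, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort %||% .data
#' @import tibble
NULL

# Orthonormal Daubechies scaling filter with 8 vanishing moments (16 taps),
# ascending-index synthesis/lowpass convention; sums to sqrt(2).
DB8_H <- c(
   0.05441584224310401,   0.31287159091429995,   0.67563073629728980,
   0.58535468365420670,  -0.01582910525634931,  -0.28401554296154690,
   0.00047248457391328,   0.12874742662047847,  -0.01736930100180755,
  -0.04408825393079476,   0.01398102791739828,   0.00874609404740578,
  -0.00487035299345157,  -0.00039174037337695,   0.00067544940645057,
  -0.00011747678412477)

# Quadrature-mirror highpass of DB8_H.
db_qmf <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1)
}
DB8_G <- db_qmf(DB8_H)

# One analysis step of the periodized orthogonal DWT. Requires even length.
# Returns list(a = approximation, d = detail), each of length n/2.
dwt_step <- function(x, h = DB8_H, g = DB8_G) {
  n <- length(x)
  if (n %% 2L != 0L) abort("dwt_step() requires an even-length input.")
  half <- n / 2L
  k2 <- seq.int(0L, n - 2L, by = 2L)
  a <- numeric(half)
  d <- numeric(half)
  for (l in seq_along(h)) {
    idx <- (k2 + (l - 1L)) %% n + 1L
    xl <- x[idx]
    a <- a + h[l] * xl
    d <- d + g[l] * xl
  }
  list(a = a, d = d)
}

# Inverse of dwt_step() (exact, by orthogonality of the periodized transform).
idwt_step <- function(a, d, h = DB8_H, g = DB8_G) {
  half <- length(a)
  n <- 2L * half
  x <- numeric(n)
  k2 <- seq.int(0L, n - 2L, by = 2L)
  for (l in seq_along(h)) {
    idx <- (k2 + (l - 1L)) %% n + 1L
    x[idx] <- x[idx] + h[l] * a + g[l] * d
  }
  x
}

#' Multilevel periodized db8 wavelet analysis
#'
#' Decomposes a signal into `level` detail coefficient vectors plus the final
#' approximation, using the orthonormal 16-tap Daubechies (db8) filter pair
#' and periodized boundary handling. Inputs whose length is not a multiple of
#' `2^level` are first extended by symmetric (half-sample reflection) padding;
#' [dwt_inverse()] trims back to the original length, so analysis followed by
#' synthesis is the identity on the original samples.
#'
#' @param x Numeric signal.
#' @param level Number of decomposition levels.
#' @return A list with elements `d` (list of detail vectors, level 1 first),
#'   `a` (final approximation), `n` (original length) and `n_pad` (padded
#'   length used by the transform).
#' @keywords internal
dwt_forward <- function(x, level) {
  if (!is.numeric(x) || length(x) < 2L) abort("Signal must be numeric, length >= 2.")
  n <- length(x)
  block <- 2L^level
  n_pad <- as.integer(ceiling(n / block) * block)
  if (n_pad > n) {
    # symmetric half-sample extension of the tail
    extra <- n_pad - n
    refl <- x[n - seq_len(extra) + 1L]
    x <- c(x, refl)
  }
  d <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    st <- dwt_step(a)
    d[[j]] <- st$d
    a <- st$a
  }
  list(d = d, a = a, n = n, n_pad = n_pad)
}

#' Multilevel periodized db8 wavelet synthesis
#'
#' Inverse of [dwt_forward()]; reconstructs the time-domain signal (trimmed to
#' the original length) from a coefficient structure. Zeroing coefficient
#' subsets before calling this yields band-limited reconstructions.
#'
#' @param cf Coefficient structure from [dwt_forward()].
#' @return Numeric signal of length `cf$n`.
#' @keywords internal
dwt_inverse <- function(cf) {
  a <- cf$a
  for (j in rev(seq_along(cf$d))) {
    a <- idwt_step(a, cf$d[[j]])
  }
  a[seq_len(cf$n)]
}

# Zero all coefficient subsets except those named in `keep`.
# Subset names: "d1".."d<level>", "a".
dwt_keep <- function(cf, keep) {
  out <- cf
  for (j in seq_along(cf$d)) {
    if (!(paste0("d", j) %in% keep)) out$d[[j]] <- numeric(length(cf$d[[j]]))
  }
  if (!("a" %in% keep)) out$a <- numeric(length(cf$a))
  out
}

#' Dyadic band/level map for five-band EEG decomposition
#'
#' For a sampling rate `fs` (a power of two, >= 128 Hz) returns the map from
#' each clinical EEG band to the db8 DWT coefficient subsets whose dyadic
#' frequency support approximates it. At 512 Hz this is a 7-level transform
#' with gamma = D3 (32-64 Hz), beta = D4 (16-32 Hz), alpha = D5 (8-16 Hz),
#' theta = D6 (4-8 Hz), delta = D7 + A7 (0-4 Hz); D1-D2 (> 64 Hz) form the
#' residual. Clinical band edges at 12 and 30 Hz cannot fall on dyadic
#' boundaries, so the nearest dyadic assignment is used; the 0.5-45 Hz
#' bandpass applied upstream suppresses out-of-band content.
#'
#' @param fs Sampling rate in Hz.
#' @return A list with `level` (total DWT levels) and `map` (named list of
#'   coefficient-subset name vectors for delta, theta, alpha, beta, gamma and
#'   residual).
#' @export
#' @examples
#' band_level_map(512)
band_level_map <- function(fs) {
  lg <- log2(fs)
  if (fs < 128 || abs(lg - round(lg)) > 1e-9) {
    abort(
      "No dyadic band/level map for this sampling rate; supply an explicit map.",
      class = "sleepaug_config_error")
  }
  lg <- as.integer(round(lg))
  # detail level j spans fs/2^(j+1) .. fs/2^j; want delta bottom edge at 2 Hz
  level <- lg - 1L                       # fs = 512 -> 8? keep A at 0-2 Hz: lg - 1
  # level j upper edge = fs / 2^j; gamma upper edge 64 Hz -> j_gamma = lg - 6
  j_gamma <- lg - 6L
  level <- j_gamma + 4L                  # delta = D(level) + A(level), 0-4 Hz bottom split
  map <- list(
    gamma = paste0("d", j_gamma),
    beta  = paste0("d", j_gamma + 1L),
    alpha = paste0("d", j_gamma + 2L),
    theta = paste0("d", j_gamma + 3L),
    delta = c(paste0("d", j_gamma + 4L), "a"),
    residual = if (j_gamma > 1L) paste0("d", seq_len(j_gamma - 1L)) else character())
  list(level = level, map = map)
}

BAND_NAMES <- c("delta", "theta", "alpha", "beta", "gamma")
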