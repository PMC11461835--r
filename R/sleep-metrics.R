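parse_clock <- function(t) {
  ok <- grepl("^\\d{1,2}:\\d{2}:\\d{2}$", t)
  if (any(!ok | is.na(t))) {
    abort(sprintf("Malformed clock time '%s' (expected hh:mm:ss).",
                  t[!ok | is.na(t)][1]),
          class = "sleepaug_parse_error")
  }
  p <- do.call(rbind, lapply(strsplit(t, ":"), as.numeric))
  if (any(p[, 1] > 23 | p[, 2] > 59 | p[, 3] > 59)) {
    abort("Clock time out of range.", class = "sleepaug_parse_error")
  }
  p[, 1] * 3600 + p[, 2] * 60 + p[, 3]
}

#' Minutes elapsed between two clock times
#'
#' Second-resolution difference `t2 - t1` in minutes, rounded to 2 decimals.
#' If `t2` is earlier than `t1` on the clock, the interval is assumed to span
#' midnight and 24 h is added (overnight recordings routinely wrap).
#'
#' @param t1,t2 Clock strings `"hh:mm:ss"` (vectorized).
#' @return Minutes in `[0, 1440)`.
#' @export
#' @examples
#' minutes_between("22:19:06", "6:38:36")  # 499.5
minutes_between <- function(t1, t2) {
  s1 <- parse_clock(t1)
  s2 <- parse_clock(t2)
  d <- (s2 - s1) %% 86400
  round(d / 60, 2)
}

#' Sleep-architecture summary from clock times
#'
#' Computes, for each recording, time in bed (TIB = out-of-bed minus in-bed
#' clock time), sleep latency (SL = sleep onset minus in-bed time) and total
#' sleep time under the convention TST = TIB - SL (wake after sleep onset is
#' carried through as an annotation, *not* subtracted from TST - this is the
#' convention of the source cohort's published summary, which differs from
#' the usual clinical TST definition). Latency is flagged `prolonged` when
#' SL >= 20 min, the conventional cutoff separating healthy sleep onset from
#' insomnia-like latency.
#'
#' @param meta Data frame with columns `sleep_start`, `sleep_onset`,
#'   `sleep_end` (clock strings) and optionally `waso_min` plus identifier
#'   columns, which are carried through.
#' @return Tibble with `time_in_bed_min`, `sleep_latency_min`, `tst_min`,
#'   `waso_min`, `latency_flag` appended; the identity
#'   `time_in_bed_min == sleep_latency_min + tst_min` holds exactly.
#' @export
#' @examples
#' sleep_summary(data.frame(sleep_start = "22:49:48", sleep_onset = "22:51:48",
#'                          sleep_end = "7:13:18"))
sleep_summary <- function(meta) {
  stopifnot(is.data.frame(meta),
            all(c("sleep_start", "sleep_onset", "sleep_end") %in% names(meta)))
  tib <- minutes_between(meta$sleep_start, meta$sleep_end)
  sl <- minutes_between(meta$sleep_start, meta$sleep_onset)
  if (any(sl > tib)) {
    abort("Sleep onset outside the in-bed interval.",
          class = "sleepaug_consistency_error")
  }
  out <- tibble::as_tibble(meta)
  out$time_in_bed_min <- tib
  out$sleep_latency_min <- sl
  out$tst_min <- round(tib - sl, 2)
  if (!"waso_min" %in% names(out)) out$waso_min <- NA_real_
  out$latency_flag <- ifelse(sl >= 20, "prolonged", "normal")
  out
}

#' Clock-time metadata of the published 12-subject CAP cohort
#'
#' In-bed, sleep-onset and out-of-bed clock times (plus sex, age and wake
#' after sleep onset) for the 6 insomnia and 6 healthy subjects of the CAP
#' Sleep Database subset recorded at 512 Hz, as published with the cohort
#' summary. One onset clock time (subject n11) is reconstructed from that
#' row's published sleep latency because the published clock entry is
#' internally inconsistent with the rest of its row.
#'
#' @return Tibble with one row per subject.
#' @export
#' @examples
#' sleep_summary(cap_sleep_times())
cap_sleep_times <- function() {
  path <- system.file("extdata", "cap_sleep_times.csv", package = "sleepaug",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
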