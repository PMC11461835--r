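# Minimal European Data Format (EDF) I/O: 16-bit samples, one signal per
# file, 1-second data records. The true sample count is annotated in the
# per-signal reserved header field ("NSAMP=<n>") so that a trailing
# zero-padded record can be trimmed on read; files remain readable by any
# standard EDF tool.

edf_pad <- function(s, width) {
  s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

write_edf_file <- function(samples, fs, path, channel = "EEG",
                           patient = "X", recording = "X",
                           start_time = "00.00.00") {
  if (any(!is.finite(samples))) {
    abort("EDF export requires finite samples.", class = "sleepaug_input_error")
  }
  n <- length(samples)
  spr <- as.integer(round(fs))
  n_rec <- as.integer(ceiling(n / spr))
  pmax_ <- max(abs(samples), 1e-6)
  pmin_ <- -pmax_
  dmax <- 32767L; dmin <- -32767L
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(patient, 80),
    edf_pad(recording, 80),
    edf_pad("01.01.01", 8),
    edf_pad(gsub(":", ".", start_time), 8),
    edf_pad(as.character(256 + 256), 8),
    edf_pad("", 44),
    edf_pad(as.character(n_rec), 8),
    edf_pad("1", 8),
    edf_pad("1", 4),
    # per-signal fields (one signal)
    edf_pad(channel, 16),
    edf_pad("", 80),
    edf_pad("uV", 8),
    edf_pad(formatC(pmin_, format = "g", digits = 7), 8),
    edf_pad(formatC(pmax_, format = "g", digits = 7), 8),
    edf_pad(as.character(dmin), 8),
    edf_pad(as.character(dmax), 8),
    edf_pad("", 80),
    edf_pad(as.character(spr), 8),
    edf_pad(paste0("NSAMP=", n), 32))
  writeChar(hdr, con, nchars = nchar(hdr), eos = NULL)
  scaled <- as.integer(round((samples - pmin_) / (pmax_ - pmin_) *
                               (dmax - dmin) + dmin))
  padded <- c(scaled, integer(n_rec * spr - n))
  writeBin(padded, con, size = 2L, endian = "little")
  invisible(path)
}

read_edf_field <- function(raw, offset, width, path) {
  if (offset + width > length(raw)) {
    abort(sprintf("Malformed EDF '%s': truncated header at byte %d.",
                  path, offset),
          class = "sleepaug_format_error")
  }
  trimws(rawToChar(raw[(offset + 1):(offset + width)]))
}

read_edf_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 256) {
    abort(sprintf("Malformed EDF '%s': header shorter than 256 bytes (got %d).",
                  path, length(raw)),
          class = "sleepaug_format_error")
  }
  num_field <- function(off, w, what) {
    s <- read_edf_field(raw, off, w, path)
    v <- suppressWarnings(as.numeric(s))
    if (!length(v) || is.na(v)) {
      abort(sprintf("Malformed EDF '%s': unparseable %s field at byte %d.",
                    path, what, off),
            class = "sleepaug_format_error")
    }
    v
  }
  patient <- read_edf_field(raw, 8, 80, path)
  start_time <- read_edf_field(raw, 176, 8, path)
  hdr_bytes <- as.integer(num_field(184, 8, "header-size"))
  n_rec <- as.integer(num_field(236, 8, "record-count"))
  rec_dur <- num_field(244, 8, "record-duration")
  ns <- as.integer(num_field(252, 4, "signal-count"))
  if (ns < 1) abort(sprintf("Malformed EDF '%s': no signals declared (byte 252).", path),
                    class = "sleepaug_format_error")
  sig <- function(field_off, width, j) (256 + field_off * ns + (j - 1) * width)
  j <- 1L
  channel <- read_edf_field(raw, sig(0, 16, j), 16, path)
  pmin_ <- num_field(256 + (16 + 80 + 8) * ns, 8, "physical-min")
  pmax_ <- num_field(256 + (16 + 80 + 8) * ns + 8 * ns, 8, "physical-max")
  dmin <- num_field(256 + (16 + 80 + 8 + 8 + 8) * ns, 8, "digital-min")
  dmax <- num_field(256 + (16 + 80 + 8 + 8 + 8) * ns + 8 * ns, 8, "digital-max")
  spr <- as.integer(num_field(256 + (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80) * ns, 8,
                              "samples-per-record"))
  reserved <- read_edf_field(raw, 256 + (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80 + 8) * ns,
                             32, path)
  fs <- spr / rec_dur
  data_off <- hdr_bytes
  n_samp_total <- n_rec * spr
  need <- data_off + 2 * n_samp_total
  if (length(raw) < need) {
    abort(sprintf("Malformed EDF '%s': data truncated at byte %d (need %d).",
                  path, length(raw), need),
          class = "sleepaug_format_error")
  }
  dig <- readBin(raw[(data_off + 1):need], "integer", n = n_samp_total,
                 size = 2L, signed = TRUE, endian = "little")
  phys <- pmin_ + (dig - dmin) * (pmax_ - pmin_) / (dmax - dmin)
  if (grepl("^NSAMP=", reserved)) {
    n_true <- as.integer(sub("^NSAMP=", "", reserved))
    phys <- phys[seq_len(min(n_true, length(phys)))]
  }
  list(samples = phys, fs = fs, channel = channel, patient = patient,
       start_time = gsub("\\.", ":", start_time))
}

#' Write a cohort to EDF files
#'
#' Writes one 16-bit EDF file per cohort row into `dir`
#' (`<subject_id>.edf`), plus a `cohort_meta.csv` sidecar carrying the
#' metadata columns (group, clock times, WASO) that EDF headers do not hold.
#'
#' @param cohort Cohort tibble (see [simulate_cohort()]); needs `subject_id`,
#'   `fs`, `channel` and `samples`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths of the written EDF files.
#' @export
write_edf <- function(cohort, dir) {
  stopifnot(is.data.frame(cohort), all(c("subject_id", "fs", "samples") %in% names(cohort)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    paths[i] <- file.path(dir, paste0(cohort$subject_id[i], ".edf"))
    write_edf_file(
      cohort$samples[[i]], cohort$fs[i], paths[i],
      channel = cohort$channel[i] %||% "EEG",
      patient = paste(cohort$subject_id[i], cohort$group[i] %||% "unknown"),
      start_time = cohort$sleep_start[i] %||% "00:00:00")
  }
  meta <- cohort[setdiff(names(cohort), c("samples", "filtered", "segments"))]
  utils::write.csv(meta, file.path(dir, "cohort_meta.csv"), row.names = FALSE)
  invisible(paths)
}

#' Read EDF recordings into a cohort tibble
#'
#' Reads a single `.edf` file or every `.edf` file in a directory. If a
#' `cohort_meta.csv` sidecar (as written by [write_edf()]) is present its
#' metadata columns are merged in; otherwise subject id and group are taken
#' from the EDF patient field where possible.
#'
#' @param path An `.edf` file or a directory containing `.edf` files.
#' @return A cohort tibble (same shape as [simulate_cohort()] output).
#' @export
read_edf <- function(path) {
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = "\\.edf$", full.names = TRUE))
  } else path
  if (!length(files)) abort("No EDF files found.", class = "sleepaug_input_error")
  rows <- purrr::map(files, function(f) {
    e <- read_edf_file(f)
    pat <- strsplit(e$patient, "\\s+")[[1]]
    tibble::tibble(
      subject_id = if (length(pat) >= 1) pat[1] else basename(f),
      group = if (length(pat) >= 2 && pat[2] %in% c("insomnia", "healthy"))
        pat[2] else NA_character_,
      fs = e$fs, channel = e$channel,
      sleep_start = e$start_time,
      samples = list(e$samples))
  })
  out <- dplyr::bind_rows(rows)
  meta_path <- if (dir.exists(path)) file.path(path, "cohort_meta.csv") else
    file.path(dirname(path), "cohort_meta.csv")
  if (file.exists(meta_path)) {
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    keep <- intersect(c("subject_id", "group", "sleep_start", "sleep_onset",
                        "sleep_end", "waso_min"), names(meta))
    out <- dplyr::left_join(
      out[setdiff(names(out), setdiff(keep, "subject_id"))],
      meta[keep], by = "subject_id")
    out <- dplyr::relocate(out, "samples", .after = dplyr::last_col())
  }
  out
}
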