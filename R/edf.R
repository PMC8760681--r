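# Minimal EDF (European Data Format, 16-bit) reader/writer.
# Layout: 256-byte fixed header, 256 bytes per signal, then data records of
# interleaved little-endian int16. One data record per second, so the
# per-record sample count equals the sampling rate and the recording duration
# must be a whole number of seconds.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width = 8) {
  s <- formatC(x, width = width, format = "g", digits = 7)
  s <- gsub(" ", "", s)
  edf_pad(s, width)
}

#' Write a recording to EDF + events CSV
#'
#' Signals are stored as 16-bit EDF with physical dimension mV and one data
#' record per second; events (including pulse onsets, label `"pulse"`) go to a
#' CSV with header `label,onset_s,duration_s`. Session metadata round-trips
#' through the EDF "local recording identification" header field.
#'
#' @param recording an [lfp_recording()] whose duration is a whole number of
#'   seconds.
#' @param signal_path output EDF path.
#' @param events_path output events CSV path.
#' @return invisibly, a named character vector of the two paths.
#' @export
write_recording <- function(recording, signal_path, events_path) {
  stopifnot(inherits(recording, "lfp_recording"))
  if (length(recording$channels) == 0) abort("recording has zero channels")
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9) abort("EDF export requires an integer fs")
  fs <- as.integer(round(fs))
  n <- length(recording$channels[[1]])
  n_rec <- n / fs
  if (abs(n_rec - round(n_rec)) > 1e-9)
    abort("EDF export requires a whole number of 1-s data records")
  n_rec <- as.integer(round(n_rec))
  nsig <- length(recording$channels)

  # symmetric physical range per channel, headroom so no sample clips
  phys_max <- vapply(recording$channels,
                     function(x) max(1e-6, max(abs(x))) * 1.0001, numeric(1))
  # exact inverse of the read-side affine map over [-32768, 32767]
  digital <- mapply(function(x, pm) {
    scale <- 2 * pm / 65535
    pmin(32767L, pmax(-32768L, as.integer(round((x + pm) / scale - 32768))))
  }, recording$channels, phys_max, SIMPLIFY = FALSE)

  meta <- recording$meta
  rec_id <- paste(
    sprintf("group=%s", meta$group %||% "NA"),
    sprintf("treatment=%s", meta$treatment %||% "NA"),
    sprintf("session=%s", meta$session %||% "NA"),
    sprintf("animal=%s", meta$animal %||% "NA"),
    sprintf("replicate=%s", meta$replicate %||% "NA"))

  con <- file(signal_path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad(rec_id, 80),
    "01.01.00", "00.00.00", edf_num(256L * (1L + nsig)),
    edf_pad("", 44), edf_num(n_rec), edf_num(1L), edf_pad(nsig, 4),
    paste(edf_pad(names(recording$channels), 16), collapse = ""),
    paste(rep(edf_pad("", 80), nsig), collapse = ""),
    paste(rep(edf_pad("mV", 8), nsig), collapse = ""),
    paste(vapply(-phys_max, edf_num, character(1)), collapse = ""),
    paste(vapply(phys_max, edf_num, character(1)), collapse = ""),
    paste(rep(edf_num(-32768L), nsig), collapse = ""),
    paste(rep(edf_num(32767L), nsig), collapse = ""),
    paste(rep(edf_pad("", 80), nsig), collapse = ""),
    paste(rep(edf_num(fs), nsig), collapse = ""),
    paste(rep(edf_pad("", 32), nsig), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  # data records: per record, each signal's fs samples in sequence
  idx <- matrix(seq_len(n), nrow = fs)  # column r = samples of record r
  for (r in seq_len(n_rec)) {
    for (s in seq_len(nsig)) {
      writeBin(digital[[s]][idx[, r]], con, size = 2, endian = "little")
    }
  }

  ev <- recording$annotations
  if (length(recording$pulses)) {
    ev <- bind_rows(ev, tibble(label = "pulse", onset_s = recording$pulses,
                               duration_s = recording$schedule$pulse_width %||% 0))
  }
  ev <- arrange(ev, .data$onset_s)
  readr::write_csv(ev, events_path)
  invisible(c(signal = signal_path, events = events_path))
}

read_edf_header <- function(con) {
  rd <- function(w) readChar(con, w, useBytes = TRUE)
  h <- list(version = rd(8), patient = rd(80), recording = trimws(rd(80)),
            startdate = rd(8), starttime = rd(8),
            header_bytes = as.integer(rd(8)), reserved = rd(44),
            n_records = as.integer(rd(8)), record_duration = as.numeric(rd(8)),
            nsig = as.integer(trimws(rd(4))))
  ns <- h$nsig
  if (is.na(ns) || ns < 1) abort("corrupt EDF header: bad signal count")
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  h$labels <- trimws(fld(16)); fld(80)
  h$phys_dim <- trimws(fld(8))
  h$phys_min <- as.numeric(fld(8)); h$phys_max <- as.numeric(fld(8))
  h$dig_min <- as.numeric(fld(8)); h$dig_max <- as.numeric(fld(8))
  fld(80)
  h$samples_per_record <- as.integer(fld(8)); fld(32)
  h
}

parse_rec_id <- function(s) {
  parts <- strsplit(s, " +")[[1]]
  kv <- strsplit(parts[grepl("=", parts, fixed = TRUE)], "=", fixed = TRUE)
  out <- list()
  for (p in kv) if (p[2] != "NA") out[[p[1]]] <- p[2]
  out
}

#' Read a recording from EDF + events CSV
#'
#' @param signal_path EDF file written by [write_recording()] (or any 16-bit
#'   EDF with equal sampling rates across signals).
#' @param events_path events CSV with header `label,onset_s,duration_s`;
#'   rows labelled `"pulse"` become the pulse-onset vector, all other rows the
#'   annotation list. `NULL` for no events.
#' @param meta optional metadata list overriding what the EDF header carries.
#' @return an [lfp_recording()].
#' @export
read_recording <- function(signal_path, events_path = NULL, meta = NULL) {
  if (!file.exists(signal_path))
    abort(sprintf("signal file not found: %s", signal_path))
  con <- file(signal_path, "rb")
  on.exit(close(con), add = TRUE)
  h <- read_edf_header(con)
  if (length(unique(h$samples_per_record)) != 1)
    abort("EDF signals with differing sampling rates are not supported")
  fs <- h$samples_per_record[1] / h$record_duration
  spr <- h$samples_per_record[1]
  raw <- readBin(con, "integer", n = h$n_records * h$nsig * spr,
                 size = 2, endian = "little", signed = TRUE)
  if (length(raw) < h$n_records * h$nsig * spr)
    abort(sprintf("truncated EDF data in %s", signal_path))
  # raw order: record-major, then signal, then sample
  dim(raw) <- c(spr, h$nsig, h$n_records)
  channels <- lapply(seq_len(h$nsig), function(s) {
    d <- as.numeric(raw[, s, ])
    scale <- (h$phys_max[s] - h$phys_min[s]) / (h$dig_max[s] - h$dig_min[s])
    (d - h$dig_min[s]) * scale + h$phys_min[s]
  })
  names(channels) <- h$labels
  duration <- h$n_records * h$record_duration

  pulses <- NULL
  ann <- event_list()
  if (!is.null(events_path)) {
    if (!file.exists(events_path))
      abort(sprintf("events file not found: %s", events_path))
    ev <- readr::read_csv(events_path, show_col_types = FALSE)
    need <- c("label", "onset_s", "duration_s")
    if (!all(need %in% names(ev)))
      abort("events CSV must have header label,onset_s,duration_s")
    if (is.unsorted(ev$onset_s))
      abort("events CSV must be sorted by onset")
    if (any(ev$onset_s < 0) || any(ev$onset_s + ev$duration_s > duration + 1e-9))
      abort("event outside the recorded interval [0, duration)")
    pulses <- ev$onset_s[ev$label == "pulse"]
    if (!length(pulses)) pulses <- NULL
    ann <- event_list(ev$label[ev$label != "pulse"],
                      ev$onset_s[ev$label != "pulse"],
                      ev$duration_s[ev$label != "pulse"])
  }
  lfp_recording(channels, fs, pulses = pulses, annotations = ann,
                meta = meta %||% parse_rec_id(h$recording))
}
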