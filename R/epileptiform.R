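# Deterministic epileptiform analysis: sharp-wave spike detection, burst
# grouping, spike-load classification, burst ratio. This is a transparent
# threshold pipeline (all thresholds are arguments) standing in for
# semi-automated classifiers used in the field; its load thresholds are
# package defaults, not values from any published classifier.

default_load_thresholds <- function() {
  list(high_rate = 1.0, high_duration = 10, medium_rate = 0.5)
}

# vectorized load classification shared with the simulator's ground truth
load_class <- function(n_spikes, onset, offset,
                       thresholds = default_load_thresholds()) {
  dur <- offset - onset
  if (any(dur <= 0)) abort("zero-duration burst")
  rate <- n_spikes / dur
  ifelse(rate >= thresholds$high_rate & dur >= thresholds$high_duration,
         "high",
         ifelse(rate >= thresholds$medium_rate, "medium", "low"))
}

#' Detect sharp-wave epileptiform spikes
#'
#' Spikes are local extrema of the 5-80 Hz band-passed trace whose absolute
#' amplitude exceeds `threshold_sd` robust standard deviations (median
#' absolute deviation scaled by 1.4826) of the band-passed channel, thinned
#' to one event per refractory window (the largest extremum wins). Intended
#' for 500-Hz downsampled data. Masked samples are excluded.
#'
#' @param signal a [masked_signal()] (or numeric + `fs`), nominally 500 Hz.
#' @param fs sampling rate when `signal` is numeric.
#' @param threshold_sd detection threshold in robust SDs (default 5).
#' @param refractory minimum event separation in seconds (default 0.08).
#' @param band band-pass edges in Hz (default `c(5, 80)`).
#' @return tibble with `time` (s) and `amplitude` (mV, band-passed, signed),
#'   times strictly increasing.
#' @export
detect_spikes <- function(signal, fs = NULL, threshold_sd = 5,
                          refractory = 0.08, band = c(5, 80)) {
  s <- as_masked_signal(signal, fs)
  if (all(s$mask)) return(tibble(time = numeric(), amplitude = numeric()))
  if (sd(s$samples[!s$mask]) < 1e-12)
    abort("flat signal: robust SD is zero, cannot set a threshold")
  bf <- signal::butter(4, band / (s$fs / 2), type = "pass")
  y <- iir_filtfilt(bf, s$samples)
  rsd <- mad(y[!s$mask])
  if (rsd < 1e-12)
    abort("flat signal: robust SD is zero, cannot set a threshold")
  thr <- threshold_sd * rsd
  a <- abs(y)
  n <- length(a)
  cand <- which(a > thr & !s$mask)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[a[cand] >= a[cand - 1] & a[cand] >= a[cand + 1]]
  if (!length(cand)) return(tibble(time = numeric(), amplitude = numeric()))
  # greedy refractory thinning: within a running window keep the largest
  ref_n <- round(refractory * s$fs)
  keep <- integer()
  cur <- cand[1]
  for (k in cand[-1]) {
    if (k - cur <= ref_n) {
      if (a[k] > a[cur]) cur <- k
    } else {
      keep <- c(keep, cur)
      cur <- k
    }
  }
  keep <- c(keep, cur)
  tibble(time = (keep - 1) / s$fs, amplitude = y[keep])
}

#' Group spikes into bursts
#'
#' Maximal runs of spikes whose consecutive inter-spike gaps are at most
#' `max_gap` and that contain at least `min_spikes` members. Burst bounds are
#' the first/last member spike time padded by half a kernel width.
#'
#' @param spikes tibble with a `time` column (sorted), e.g. from
#'   [detect_spikes()].
#' @param max_gap maximum intra-burst inter-spike interval (s, default 2).
#' @param min_spikes minimum member count (default 5).
#' @param kernel_width sharp-wave kernel width used for padding (s).
#' @param thresholds load-class thresholds, see [classify_load()].
#' @return tibble with `onset`, `offset`, `n_spikes`, `load` and a
#'   `spike_times` list-column.
#' @export
group_bursts <- function(spikes, max_gap = 2, min_spikes = 5,
                         kernel_width = 0.04,
                         thresholds = default_load_thresholds()) {
  t <- spikes$time
  if (is.unsorted(t)) abort("spike times must be sorted")
  empty <- tibble(onset = numeric(), offset = numeric(),
                  n_spikes = integer(), load = character(),
                  spike_times = list())
  if (!length(t)) return(empty)
  run_id <- cumsum(c(1, diff(t) > max_gap))
  out <- purrr::map_dfr(split(t, run_id), function(ts) {
    if (length(ts) < min_spikes) return(NULL)
    tibble(onset = ts[1] - kernel_width / 2,
           offset = ts[length(ts)] + kernel_width / 2,
           n_spikes = length(ts), spike_times = list(ts))
  })
  if (!nrow(out)) return(empty)
  out$load <- load_class(out$n_spikes, out$onset, out$offset, thresholds)
  out[, c("onset", "offset", "n_spikes", "load", "spike_times")]
}

#' Classify a burst by spike load
#'
#' Intra-burst spike rate `r = n_spikes / (offset - onset)`: `"high"` when
#' `r >= 1 Hz` and the burst lasts at least 10 s, `"medium"` when
#' `r >= 0.5 Hz`, else `"low"`. Thresholds are configurable package defaults.
#'
#' @param burst one row of [group_bursts()] output (or any list with
#'   `onset`, `offset`, `n_spikes`).
#' @param thresholds list with `high_rate` (Hz), `high_duration` (s),
#'   `medium_rate` (Hz).
#' @return `"low"`, `"medium"` or `"high"`.
#' @export
#' @examples
#' classify_load(list(onset = 0, offset = 20, n_spikes = 30))  # "high"
classify_load <- function(burst, thresholds = default_load_thresholds()) {
  load_class(burst$n_spikes, burst$onset, burst$offset, thresholds)
}

#' Burst ratio of a session
#'
#' The burst ratio is the total duration of high-load bursts divided by the
#' session duration. Sessions containing a generalized seizure are dropped
#' from epileptiform statistics (long postictal suppression): the ratio is
#' reported missing with `dropped = TRUE`.
#'
#' @param bursts output of [group_bursts()].
#' @param session_duration total recording time (s).
#' @param gs_annotations an [event_list()] (rows labelled `"GS"` trigger the
#'   session drop), or `NULL`.
#' @return one-row tibble: `burst_ratio`, `n_low`, `n_medium`, `n_high`,
#'   `high_load_time`, `dropped`.
#' @export
burst_ratio <- function(bursts, session_duration, gs_annotations = NULL) {
  if (session_duration <= 0) abort("session duration must be positive")
  dropped <- !is.null(gs_annotations) && nrow(gs_annotations) > 0 &&
    any(gs_annotations$label == "GS")
  high_time <- sum(bursts$offset[bursts$load == "high"] -
                     bursts$onset[bursts$load == "high"])
  tibble(burst_ratio = if (dropped) NA_real_
         else min(1, high_time / session_duration),
         n_low = sum(bursts$load == "low"),
         n_medium = sum(bursts$load == "medium"),
         n_high = sum(bursts$load == "high"),
         high_load_time = high_time,
         dropped = dropped)
}

#' Cross-channel generalized-seizure auto-detector
#'
#' Optional helper that flags candidate generalized seizures: windows where
#' BOTH channels simultaneously exceed `4` robust SDs in rhythmic 3-8 Hz
#' activity for at least `min_duration`, followed by at least 30 s whose RMS
#' drops below half the baseline RMS (postictal depression). Annotation-driven
#' masking remains authoritative; this detector only assists screening.
#'
#' @param recording a two-channel [lfp_recording()] at 500 Hz.
#' @param threshold_sd robust-SD threshold on the 3-8 Hz band envelope.
#' @param min_duration minimum seizure duration (s).
#' @param postictal_window,postictal_rms_ratio postictal check parameters.
#' @return an [event_list()] of candidate `"GS"` intervals.
#' @export
detect_gs <- function(recording, threshold_sd = 4, min_duration = 10,
                      postictal_window = 30, postictal_rms_ratio = 0.5) {
  stopifnot(inherits(recording, "lfp_recording"),
            length(recording$channels) >= 2)
  fs <- recording$fs
  bf <- signal::butter(2, c(3, 8) / (fs / 2), type = "pass")
  hot <- lapply(recording$channels[1:2], function(x) {
    y <- iir_filtfilt(bf, x)
    # 1-s moving RMS envelope against the robust SD of the band-passed trace
    e <- sqrt(as.numeric(stats::filter(y^2, rep(1 / fs, fs), sides = 2)))
    e[is.na(e)] <- 0
    e > threshold_sd * mad(y)
  })
  both <- hot[[1]] & hot[[2]]
  r <- rle(both)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= min_duration * fs)
  res <- event_list()
  base_rms <- sd(recording$channels[[1]])
  for (i in cand) {
    post <- window_indices((ends[i]) / fs,
                           min((ends[i]) / fs + postictal_window,
                               recording$duration), fs)
    if (length(post) &&
        sd(recording$channels[[1]][post]) < postictal_rms_ratio * base_rms) {
      res <- event_list(c(res$label, "GS"), c(res$onset_s, (starts[i] - 1) / fs),
                        c(res$duration_s, r$lengths[i] / fs))
    }
  }
  res
}
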