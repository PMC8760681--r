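#' optolfp: quantification of optogenetic silencing in long-term LFP recordings
#'
#' Tools to quantify multi-hour local field potential (LFP) recordings with
#' intermittent optogenetic stimulation: line-length magnitude analysis,
#' pulse-triggered response analysis, Welch band-power and spectrogram
#' computation, epileptiform burst detection with the burst-ratio metric,
#' a matching statistical battery, and a synthetic two-channel LFP generator
#' with ground truth so every stage can be validated end to end.
#'
#' @import dplyr tibble
#' @importFrom rlang abort warn .data %||%
#' @importFrom stats fft mad median sd var approx rnorm runif rexp quantile
#' @keywords internal
"_PACKAGE"

# Interval convention used throughout: all time windows are half-open [a, b)
# in float seconds from recording start; sample i covers [i/fs, (i+1)/fs), so
# the samples of window [a, b) are indices ceiling(a*fs) .. ceiling(b*fs)-1
# (0-based).

#' Sample indices covered by a half-open time window
#'
#' @param from,to window bounds in seconds, window is `[from, to)`.
#' @param fs sampling rate in Hz.
#' @return 1-based integer sample indices.
#' @keywords internal
window_indices <- function(from, to, fs) {
  lo <- ceiling(from * fs - 1e-9)    # 0-based first sample at or after `from`
  hi <- ceiling(to * fs - 1e-9) - 1  # 0-based last sample strictly before `to`
  if (hi < lo) return(integer(0))
  seq.int(lo, hi) + 1L
}

#' Event list
#'
#' A tibble of labelled intervals (`label`, `onset_s`, `duration_s`) sorted by
#' onset. Pulse events carry label `"pulse"`, generalized seizures `"GS"`.
#'
#' @param label character labels.
#' @param onset_s event onsets in seconds (>= 0).
#' @param duration_s event durations in seconds (>= 0; 0 for point events).
#' @return a tibble sorted by onset.
#' @export
#' @examples
#' event_list(c("GS", "pulse"), c(120, 10), c(45, 0))
event_list <- function(label = character(), onset_s = numeric(),
                       duration_s = numeric()) {
  ev <- tibble(label = as.character(label), onset_s = as.numeric(onset_s),
               duration_s = as.numeric(duration_s))
  if (any(ev$onset_s < 0)) abort("event onsets must be >= 0")
  if (any(ev$duration_s < 0)) abort("event durations must be >= 0")
  arrange(ev, .data$onset_s)
}

#' Illumination pulse schedule
#'
#' Protocol of the light-ON hour: pulse repetition frequency (0.05 or 0.1 Hz
#' in the experiments this package models), 10-ms pulse width with a 5-ms
#' ramp-like termination, and a fade-off tail at the end of the light-ON
#' window that is excluded from analysis.
#'
#' @param frequency pulse rate in Hz.
#' @param pulse_width pulse duration in seconds.
#' @param ramp ramp-like pulse termination in seconds.
#' @param light_on half-open interval `[t0, t1)` in seconds.
#' @param fadeoff_tail seconds at the end of `light_on` excluded from analysis.
#' @return an object of class `pulse_schedule`.
#' @export
pulse_schedule <- function(frequency = 0.1, pulse_width = 0.010, ramp = 0.005,
                           light_on = c(3600, 7200), fadeoff_tail = 600) {
  if (frequency <= 0) abort("pulse frequency must be positive")
  if (pulse_width >= 1 / frequency)
    abort("pulse_width must be shorter than the inter-pulse interval")
  if (length(light_on) != 2 || light_on[2] <= light_on[1])
    abort("light_on must be an increasing interval [t0, t1)")
  if (fadeoff_tail < 0 || fadeoff_tail >= diff(light_on))
    abort("fadeoff_tail must lie within the light_on window")
  structure(list(frequency = frequency, pulse_width = pulse_width,
                 ramp = ramp, light_on = as.numeric(light_on),
                 fadeoff_tail = fadeoff_tail),
            class = "pulse_schedule")
}

#' Expected pulse onset times of a schedule
#'
#' Onsets are `t0, t0 + 1/f, ...` within `[t0, t1)`; pulses continue through
#' the fade-off tail (the analysis window simply stops before it).
#'
#' @param schedule a [pulse_schedule()].
#' @return numeric vector of onsets in seconds, strictly increasing.
#' @export
#' @examples
#' length(expected_pulse_times(pulse_schedule(0.1)))  # 360 over the hour
expected_pulse_times <- function(schedule) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  t0 <- schedule$light_on[1]
  t1 <- schedule$light_on[2]
  seq(t0, t1 - 1e-9, by = 1 / schedule$frequency)
}

#' Session layout
#'
#' Half-open hour intervals of a three-hour session: pre-recording, light-ON
#' hour, post-recording. The analysis window of the light-ON hour drops the
#' fade-off tail (default: first 50 of 60 minutes). `hour` is scalable so that
#' simulations and tests can run with shortened "hours".
#'
#' @param hour duration of one session "hour" in seconds.
#' @param fadeoff_tail seconds dropped at the end of the light-ON hour.
#' @return an object of class `session_layout` with elements `pre`,
#'   `light_on`, `light_analysis`, `post`, `hours` (list of 3 intervals) and
#'   `duration`.
#' @export
session_layout <- function(hour = 3600, fadeoff_tail = 600) {
  if (hour <= 0) abort("hour duration must be positive")
  if (fadeoff_tail < 0 || fadeoff_tail >= hour)
    abort("fadeoff_tail must be shorter than the hour")
  structure(list(
    pre = c(0, hour),
    light_on = c(hour, 2 * hour),
    light_analysis = c(hour, 2 * hour - fadeoff_tail),
    post = c(2 * hour, 3 * hour),
    hours = list(c(0, hour), c(hour, 2 * hour), c(2 * hour, 3 * hour)),
    hour = hour, fadeoff_tail = fadeoff_tail,
    duration = 3 * hour
  ), class = "session_layout")
}

#' LFP recording container
#'
#' Holds named channel traces in mV, the sampling rate, pulse times and/or a
#' pulse schedule, interval annotations, and session metadata. Channel naming
#' follows the experiments modelled here: `HCi`/`HCc` (ipsi-/contralateral
#' hippocampus) for kainate-treated animals, `left`/`right` for saline
#' controls.
#'
#' @param channels named list of numeric vectors (mV), equal lengths.
#' @param fs sampling rate in Hz.
#' @param pulses numeric vector of pulse onsets (s), or `NULL`.
#' @param schedule optional [pulse_schedule()]; if given and `pulses` is
#'   `NULL`, pulse onsets are derived via [expected_pulse_times()].
#' @param annotations an [event_list()].
#' @param meta named list with optional tags `group`
#'   (PACK/bPAC/mCherry/no_virus), `treatment` (saline/kainate), `session`
#'   (ref/stim_0.05/stim_0.1), `animal`, `replicate`.
#' @return an object of class `lfp_recording`.
#' @export
lfp_recording <- function(channels, fs, pulses = NULL, schedule = NULL,
                          annotations = event_list(), meta = list()) {
  if (!is.list(channels) || length(channels) == 0)
    abort("`channels` must be a non-empty named list of numeric traces")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    abort("all channels must be named")
  ns <- lengths(channels)
  if (length(unique(ns)) != 1)
    abort("all channels must have identical sample counts")
  if (!is.numeric(fs) || fs <= 0) abort("`fs` must be a positive sampling rate")
  duration <- ns[[1]] / fs
  if (is.null(pulses) && !is.null(schedule))
    pulses <- expected_pulse_times(schedule)
  pulses <- as.numeric(pulses %||% numeric())
  if (length(pulses)) {
    if (any(diff(pulses) <= 0)) abort("pulse onsets must be strictly increasing")
    if (any(pulses < 0 | pulses >= duration))
      abort("pulse onsets must lie within [0, duration)")
  }
  stopifnot(is.data.frame(annotations))
  if (nrow(annotations) &&
      any(annotations$onset_s + annotations$duration_s > duration + 1e-9))
    abort("annotation intervals must lie within [0, duration)")
  structure(list(channels = lapply(channels, as.numeric), fs = fs,
                 duration = duration, pulses = pulses, schedule = schedule,
                 annotations = annotations, meta = meta),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channel(s) [%s], fs = %g Hz, %.1f s\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              x$fs, x$duration))
  if (length(x$pulses))
    cat(sprintf("  %d pulses in [%.0f, %.0f] s\n", length(x$pulses),
                min(x$pulses), max(x$pulses)))
  if (nrow(x$annotations))
    cat(sprintf("  %d annotation(s): %s\n", nrow(x$annotations),
                paste(unique(x$annotations$label), collapse = ", ")))
  tags <- unlist(x$meta[c("group", "treatment", "session")])
  if (length(tags)) cat("  meta:", paste(tags, collapse = " / "), "\n")
  invisible(x)
}

#' @export
print.pulse_schedule <- function(x, ...) {
  cat(sprintf(
    "<pulse_schedule> %g Hz, %g-ms pulses (%g-ms ramp), light ON [%g, %g) s, %g-s fade-off\n",
    x$frequency, 1000 * x$pulse_width, 1000 * x$ramp,
    x$light_on[1], x$light_on[2], x$fadeoff_tail))
  invisible(x)
}

#' @export
print.session_layout <- function(x, ...) {
  cat(sprintf(
    "<session_layout> hour = %g s; pre [%g, %g), light analysis [%g, %g), post [%g, %g)\n",
    x$hour, x$pre[1], x$pre[2], x$light_analysis[1], x$light_analysis[2],
    x$post[1], x$post[2]))
  invisible(x)
}
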