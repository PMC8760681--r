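# Line length: the sum of absolute differences between successive samples
# divided by the duration (mV/s). Sensitive to both amplitude and frequency,
# it is the primary magnitude statistic of this pipeline. Computed on 500-Hz
# downsampled data.

#' Line length of a window
#'
#' `L = sum(|x[k] - x[k-1]|) / t` over consecutive *included* sample pairs,
#' where `t` is the included duration in seconds. Differences that straddle an
#' excluded (masked) gap are not counted, and the masked time is removed from
#' `t`.
#'
#' @param signal a [masked_signal()] or numeric trace.
#' @param window half-open window `c(from, to)` in seconds; `NULL` = whole
#'   trace.
#' @param fs sampling rate, required for a bare numeric trace.
#' @return line length in mV/s, or `NA_real_` when fewer than two included
#'   samples remain (an undefined, not a zero, result).
#' @export
#' @examples
#' line_length(rep(c(0, 1), 250), fs = 500)  # 499 unit steps over 1 s
line_length <- function(signal, window = NULL, fs = NULL) {
  s <- as_masked_signal(signal, fs)
  idx <- if (is.null(window)) seq_along(s$samples)
         else window_indices(window[1], window[2], s$fs)
  idx <- idx[idx >= 1 & idx <= length(s$samples)]
  x <- s$samples[idx]
  m <- s$mask[idx]
  n_inc <- sum(!m)
  if (n_inc < 2) return(NA_real_)
  d <- abs(diff(x))
  valid <- !m[-length(m)] & !m[-1]
  sum(d[valid]) / (n_inc / s$fs)
}

#' Hour-wise line length with baseline subtraction
#'
#' Line length of each session hour, with the first hour as baseline
#' (`delta = L - L[hour 1]`, so `delta[1] == 0`). For stimulation sessions
#' (`stim = TRUE`) the second hour is replaced by the light-analysis window
#' (the light-ON hour minus its fade-off tail).
#'
#' @param signal a [masked_signal()] at 500 Hz (any rate accepted).
#' @param layout a [session_layout()].
#' @param stim does this session contain illumination? (uses the 50-min
#'   analysis window for hour 2).
#' @return a `line_length_summary` tibble: `hour`, `from_s`, `to_s`,
#'   `line_length` (mV/s), `delta` (mV/s), `masked_fraction`.
#' @export
hourly_line_length <- function(signal, layout = session_layout(), stim = FALSE) {
  s <- as_masked_signal(signal)
  wins <- layout$hours
  if (stim) wins[[2]] <- layout$light_analysis
  res <- purrr::map_dfr(seq_along(wins), function(h) {
    w <- wins[[h]]
    idx <- window_indices(w[1], w[2], s$fs)
    tibble(hour = h, from_s = w[1], to_s = w[2],
           line_length = line_length(s, w),
           masked_fraction = mean(s$mask[idx]))
  })
  if (is.na(res$line_length[1]))
    abort("baseline hour is fully masked; deltas undefined")
  res$delta <- res$line_length - res$line_length[1]
  class(res) <- c("line_length_summary", class(res))
  res[, c("hour", "from_s", "to_s", "line_length", "delta", "masked_fraction")]
}

#' Pulse-triggered line-length analysis
#'
#' For every light pulse in the analysis window, the line length of the 2-s
#' snippet before the pulse (`[p - w, p)`) and after the pulse offset
#' (`[p + pulse_width, p + pulse_width + w)`) is computed, together with a
#' baseline snippet at the matched clock offset in the pre-recording hour
#' (pulse time minus one layout hour). Pulses whose three windows touch any
#' excluded sample are dropped from all three series to keep them aligned.
#'
#' @param signal a [masked_signal()].
#' @param pulses pulse onsets in seconds.
#' @param layout a [session_layout()].
#' @param window snippet length in seconds (default 2).
#' @param pulse_width pulse duration in seconds (default 0.010).
#' @return a `pulse_response` object: `$snippets` (per-pulse tibble with
#'   `pulse_time`, `pre`, `before`, `after` in mV/s), `$means` (tibble of the
#'   three series means), `$n_used`, `$n_dropped`, `$window`.
#' @export
pulse_triggered <- function(signal, pulses, layout = session_layout(),
                            window = 2, pulse_width = 0.010) {
  s <- as_masked_signal(signal)
  la <- layout$light_analysis
  # keep pulses whose before/after windows fit the analysis window (the first
  # pulse, sitting on the light-ON boundary, has no matched-pre offset)
  pulses <- pulses[pulses - window >= la[1] &
                     pulses + pulse_width + window <= la[2]]
  if (!length(pulses)) abort("no pulses inside the light-analysis window")
  snips <- purrr::map_dfr(pulses, function(p) {
    w_before <- c(p - window, p)
    w_after <- c(p + pulse_width, p + pulse_width + window)
    off <- p - layout$hour                      # matched pre-recording offset
    w_pre <- c(off - window, off)
    tibble(pulse_time = p,
           pre = line_length(s, w_pre),
           before = line_length(s, w_before),
           after = line_length(s, w_after),
           excluded = any(s$mask[c(window_indices(w_pre[1], w_pre[2], s$fs),
                                   window_indices(w_before[1], w_before[2], s$fs),
                                   window_indices(w_after[1], w_after[2], s$fs))]))
  })
  used <- snips[!snips$excluded & stats::complete.cases(snips[c("pre", "before", "after")]), ]
  if (!nrow(used)) abort("all pulses excluded by masking; no usable pulses")
  means <- tibble(series = c("pre", "before", "after"),
                  mean_line_length = c(mean(used$pre), mean(used$before),
                                       mean(used$after)),
                  sem = c(sd(used$pre), sd(used$before), sd(used$after)) /
                    sqrt(nrow(used)),
                  n = nrow(used))
  structure(list(snippets = used[, c("pulse_time", "pre", "before", "after")],
                 means = means, n_used = nrow(used),
                 n_dropped = sum(snips$excluded), window = window),
            class = "pulse_response")
}

#' @export
print.pulse_response <- function(x, ...) {
  cat(sprintf("<pulse_response> %d pulses used (%d dropped), %g-s windows\n",
              x$n_used, x$n_dropped, x$window))
  m <- x$means
  cat(sprintf("  mean L: pre %.2f, before %.2f, after %.2f mV/s\n",
              m$mean_line_length[1], m$mean_line_length[2],
              m$mean_line_length[3]))
  invisible(x)
}
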