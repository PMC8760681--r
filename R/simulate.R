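# Synthetic two-channel LFP generator. Emulates the signal structure the
# analysis pipeline assumes: 1/f background plus band-limited theta/beta/gamma
# oscillators, hour-scale habituation (stepwise per-hour gain), pulse-locked
# multiplicative suppression or enhancement with exponential recovery,
# interictal sharp-wave bursts on the ipsilateral channel (with optional
# contralateral propagation), and bilateral generalized seizures followed by
# postictal depression. Fully deterministic given a seed, with ground truth.

#' Simulation configuration
#'
#' Defaults describe a healthy-animal session at full scale; pass a shortened
#' [session_layout()] and a lower `fs_raw` for fast tests. `amplitude_scale`
#' is a single calibration constant chosen so that the hour-1 line length of
#' the default composite at 500 Hz is ~50 mV/s (see the package vignette).
#'
#' @param fs_raw raw sampling rate in Hz.
#' @param layout a [session_layout()].
#' @param oscillators tibble with `name`, `center` (Hz), `bandwidth` (Hz),
#'   `rms` (mV).
#' @param background list: `beta` (1/f exponent), `rms` (mV).
#' @param amplitude_scale global multiplicative calibration of the composite.
#' @param habituation per-hour gain multipliers, hour 1 first.
#' @param pulse list: `mode` ("none", "suppress", "enhance"), `depth` (s in
#'   \[0, 1)), `tau` (recovery time constant, s), `frequency` (Hz),
#'   `pulse_width` (s), `channels` (names to modulate; `NULL` = all).
#' @param burst_model list: `n_bursts`, `duration_s`, `intra_rate` (Hz),
#'   `kernel_ms`, `amplitude_snr` (peak over background SD), `propagate`,
#'   `propagate_gain`.
#' @param gs_model list: `n_gs`, `duration_s`, `freq` (Hz), `amplitude_snr`,
#'   `postictal_gain`, `postictal_duration_s`.
#' @param channels channel names; defaults to `left`/`right` for saline,
#'   `HCi`/`HCc` for kainate.
#' @param group,treatment,session metadata tags.
#' @param seed integer master seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(fs_raw = 10000,
                       layout = session_layout(),
                       oscillators = tibble(
                         name = c("theta", "beta", "gamma"),
                         center = c(7, 20, 40),
                         bandwidth = c(3, 8, 30),
                         rms = c(0.15, 0.05, 0.04)),
                       background = list(beta = 1.0, rms = 0.10),
                       amplitude_scale = 1.92,
                       habituation = c(1.00, 0.84, 0.79),
                       pulse = list(mode = "none", depth = 0.25, tau = 12,
                                    frequency = 0.1, pulse_width = 0.010,
                                    channels = NULL),
                       burst_model = list(n_bursts = 0, duration_s = 60,
                                          intra_rate = 2, kernel_ms = 40,
                                          amplitude_snr = 8, propagate = FALSE,
                                          propagate_gain = 0.7),
                       gs_model = list(n_gs = 0, duration_s = 30, freq = 5,
                                       amplitude_snr = 6, postictal_gain = 0.2,
                                       postictal_duration_s = 60),
                       channels = NULL,
                       group = "PACK", treatment = "saline", session = "ref",
                       seed = 1L) {
  if (any(oscillators$rms < 0) || background$rms < 0 || amplitude_scale < 0)
    abort("amplitudes must be >= 0")
  if (pulse$depth < 0 || pulse$depth >= 1)
    abort("pulse depth must lie in [0, 1)")
  if (pulse$tau <= 0) abort("pulse recovery tau must be positive")
  if (any(habituation <= 0) || any(habituation > 1.5))
    abort("habituation gains must lie in (0, 1.5]")
  channels <- channels %||%
    (if (treatment == "kainate") c("HCi", "HCc") else c("left", "right"))
  structure(list(fs_raw = fs_raw, layout = layout, oscillators = oscillators,
                 background = background, amplitude_scale = amplitude_scale,
                 habituation = habituation, pulse = pulse,
                 burst_model = burst_model, gs_model = gs_model,
                 channels = channels, group = group, treatment = treatment,
                 session = session, seed = as.integer(seed)),
            class = "sim_config")
}

# stable per-stage sub-seeds below 2^31
sub_seed <- function(seed, stage, k = 0L) {
  (as.numeric(seed) * 7919 + stage * 104729 + k * 1299709) %% 2147483629 + 1
}

pink_noise <- function(n, fs, beta, seed, f_hi = 200) {
  set.seed(seed)
  x <- rnorm(n)
  f <- c(seq(0, floor(n / 2)), -seq(ceiling(n / 2) - 1, 1)) * fs / n
  # flat below 1 Hz (the acquisition chain is AC-coupled at 1 Hz); band-limited
  # above f_hi so the configured RMS lands in the analysis band regardless of
  # the raw sampling rate
  shape <- pmax(abs(f), 1)^(-beta / 2)
  shape[1] <- 0
  shape[abs(f) > min(f_hi, 0.45 * fs)] <- 0
  y <- Re(fft(fft(x) * shape, inverse = TRUE)) / n
  y - mean(y)
}

bandlimited_noise <- function(n, fs, center, bandwidth, seed) {
  set.seed(seed)
  lo <- max(center - bandwidth / 2, 0.5)
  hi <- min(center + bandwidth / 2, 0.45 * fs)
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  y <- iir_filtfilt(bf, rnorm(n))
  y - mean(y)
}

#' Generate the oscillatory background of one channel
#'
#' 1/f^beta noise plus band-pass-filtered white-noise oscillators, each
#' component scaled to its configured RMS (empirically exact), the composite
#' scaled by `amplitude_scale`. Zero mean; deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed for this trace.
#' @param channel channel index (only used to decorrelate the default seed).
#' @return numeric trace (mV) of `3 * layout$hour * fs_raw` samples.
#' @export
generate_background <- function(config, seed = config$seed, channel = 1L) {
  n <- as.integer(round(config$layout$duration * config$fs_raw))
  fs <- config$fs_raw
  out <- numeric(n)
  if (config$background$rms > 0) {
    y <- pink_noise(n, fs, config$background$beta,
                    sub_seed(seed, 1L, channel),
                    f_hi = config$background$f_hi %||% 200)
    out <- out + y * (config$background$rms / sd(y))
  }
  osc <- config$oscillators
  for (i in seq_len(nrow(osc))) {
    if (osc$rms[i] <= 0) next
    y <- bandlimited_noise(n, fs, osc$center[i], osc$bandwidth[i],
                           sub_seed(seed, 1L + i, channel))
    out <- out + y * (osc$rms[i] / sd(y))
  }
  out * config$amplitude_scale
}

#' Pulse-locked multiplicative gain trace
#'
#' `g(t) = 1 -/+ depth * sum_k exp(-(t - p_k)/tau)` for `t >= p_k` (minus for
#' suppression, plus for enhancement), clipped below at 0.05, and identically
#' 1 outside the light-ON window.
#'
#' @param schedule a [pulse_schedule()].
#' @param mode "suppress", "enhance" or "none".
#' @param depth suppression/enhancement depth in \[0, 1).
#' @param tau exponential recovery time constant (s).
#' @param duration trace duration (s).
#' @param fs sampling rate (Hz).
#' @return numeric gain trace of `duration * fs` samples, all `>= 0.05`.
#' @export
pulse_gain_trace <- function(schedule, mode, depth, tau, duration, fs) {
  n <- as.integer(round(duration * fs))
  if (mode == "none" || depth == 0) return(rep(1, n))
  onsets <- expected_pulse_times(schedule)
  onsets <- onsets[onsets < duration]
  imp <- numeric(n)
  k <- floor(onsets * fs) + 1L
  imp[k] <- imp[k] + 1
  decay <- exp(-1 / (tau * fs))
  e <- as.numeric(stats::filter(imp, decay, method = "recursive"))
  g <- if (mode == "suppress") 1 - depth * e else 1 + depth * e
  g <- pmax(g, 0.05)
  t0 <- schedule$light_on[1]
  t1 <- schedule$light_on[2]
  outside <- c(window_indices(0, t0, fs),
               window_indices(min(t1, duration), duration, fs))
  g[outside] <- 1
  g
}

# biphasic sharp-wave kernel, unit peak, width_s total support
spike_kernel <- function(width_s, fs) {
  t <- seq(-width_s / 2, width_s / 2, by = 1 / fs)
  k <- exp(-(t / (width_s / 8))^2) - 0.55 * exp(-((t - width_s / 5) /
                                                    (width_s / 4))^2)
  k / max(abs(k))
}

#' Insert sharp-wave bursts into a trace
#'
#' Bursts of biphasic sharp-wave kernels placed without overlap; spike times
#' inside a burst follow a jittered regular grid at `intra_rate`. Peak spike
#' amplitude is `amplitude_snr` times the SD of the incoming trace.
#'
#' @param signal numeric trace (mV).
#' @param fs sampling rate (Hz).
#' @param burst_model list as in [sim_config()].
#' @param seed integer seed.
#' @param at optional explicit burst onsets (s); `NULL` = random placement.
#' @return list: `signal` (trace with bursts added), `spikes` (tibble `time`),
#'   `bursts` (tibble `onset`, `offset`, `n_spikes`, `load` — intended class
#'   from [classify_load()] thresholds).
#' @export
insert_bursts <- function(signal, fs, burst_model, seed = 1L, at = NULL) {
  bm <- burst_model
  dur <- length(signal) / fs
  kernel_w <- bm$kernel_ms / 1000
  if (bm$n_bursts == 0 && is.null(at))
    return(list(signal = signal,
                spikes = tibble(time = numeric()),
                bursts = tibble(onset = numeric(), offset = numeric(),
                                n_spikes = integer(), load = character())))
  if (kernel_w >= 1 / bm$intra_rate)
    abort("spike kernel width must be shorter than the intra-burst interval")
  set.seed(sub_seed(seed, 9L))
  n_b <- if (!is.null(at)) length(at) else bm$n_bursts
  bdur <- rep_len(bm$duration_s, n_b)
  if (is.null(at)) {
    # one burst per equal slot, uniformly placed where it fits (5-s margins)
    slot <- dur / n_b
    if (any(bdur + 10 > slot))
      abort("bursts do not fit the trace without overlap")
    at <- (seq_len(n_b) - 1) * slot + 5 + runif(n_b) * (slot - bdur - 10)
  }
  ker <- spike_kernel(kernel_w, fs)
  half <- (length(ker) - 1L) %/% 2L
  amp <- bm$amplitude_snr * sd(signal)
  spikes <- numeric()
  bursts <- vector("list", n_b)
  for (b in seq_len(n_b)) {
    tt <- at[b]
    st <- numeric()
    while (tt <= at[b] + bdur[b] - 1 / bm$intra_rate) {
      st <- c(st, tt)
      tt <- tt + (1 / bm$intra_rate) * runif(1, 0.8, 1.2)
    }
    for (s0 in st) {
      c0 <- floor(s0 * fs) + 1L
      idx <- (c0 - half):(c0 + half)
      ok <- idx >= 1 & idx <= length(signal)
      signal[idx[ok]] <- signal[idx[ok]] + amp * ker[ok]
    }
    spikes <- c(spikes, st)
    bursts[[b]] <- tibble(onset = st[1] - kernel_w / 2,
                          offset = st[length(st)] + kernel_w / 2,
                          n_spikes = length(st))
  }
  bursts <- bind_rows(bursts)
  bursts$load <- load_class(bursts$n_spikes, bursts$onset, bursts$offset)
  list(signal = signal, spikes = tibble(time = spikes), bursts = bursts)
}

#' Insert a generalized seizure into a recording
#'
#' Adds a high-amplitude rhythmic (spike-and-wave, 3-8 Hz) discharge to BOTH
#' channels over `[onset, onset + duration)`, scales both channels by
#' `postictal_gain` over the following `postictal_duration` (postictal
#' depression), and appends a `"GS"` annotation.
#'
#' @param recording an [lfp_recording()].
#' @param onset,duration seizure interval (s).
#' @param postictal_gain multiplicative gain of the postictal window.
#' @param postictal_duration seconds of postictal depression.
#' @param freq discharge frequency (Hz, 3-8).
#' @param amplitude_snr discharge amplitude over per-channel SD.
#' @return the modified recording (annotation added).
#' @export
insert_generalized_seizure <- function(recording, onset, duration,
                                       postictal_gain = 0.2,
                                       postictal_duration = 60,
                                       freq = 5, amplitude_snr = 6) {
  stopifnot(inherits(recording, "lfp_recording"))
  if (duration <= 0) return(recording)
  if (onset + duration > recording$duration) {
    warn("generalized seizure truncated at recording end")
    duration <- recording$duration - onset
  }
  fs <- recording$fs
  idx <- window_indices(onset, onset + duration, fs)
  t <- (idx - 1) / fs
  # sharpened sinusoid: spike-and-wave-like morphology
  base <- sin(2 * pi * freq * t)
  wave <- sign(base) * abs(base)^0.3 + 0.5 * sin(4 * pi * freq * t)
  wave <- wave / max(abs(wave))
  pidx <- window_indices(onset + duration,
                         min(onset + duration + postictal_duration,
                             recording$duration), fs)
  for (ch in seq_along(recording$channels)) {
    amp <- amplitude_snr * sd(recording$channels[[ch]])
    recording$channels[[ch]][idx] <- recording$channels[[ch]][idx] + amp * wave
    recording$channels[[ch]][pidx] <- recording$channels[[ch]][pidx] *
      postictal_gain
  }
  recording$annotations <- event_list(
    c(recording$annotations$label, "GS"),
    c(recording$annotations$onset_s, onset),
    c(recording$annotations$duration_s, duration))
  recording
}

#' Simulate a full experimental session
#'
#' Composes, per channel: background x stepwise habituation gain x pulse gain,
#' then adds interictal bursts (kainate: always on `HCi`, on `HCc` only with
#' propagation) and generalized seizures. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `recording` (an [lfp_recording()]) and `truth` (list:
#'   `gain` per-channel numeric gain traces, `spikes`, `bursts` per-channel
#'   tibbles, `gs` tibble).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$pulse$mode != "none" && config$session == "ref")
    abort("a 'ref' session cannot have an active pulse mode")
  fs <- config$fs_raw
  layout <- config$layout
  n <- as.integer(round(layout$duration * fs))
  stim <- config$session != "ref"
  schedule <- if (stim)
    pulse_schedule(frequency = config$pulse$frequency,
                   pulse_width = config$pulse$pulse_width,
                   light_on = layout$light_on,
                   fadeoff_tail = layout$fadeoff_tail)

  hab <- rep(config$habituation,
             times = diff(c(0, vapply(layout$hours, `[`, numeric(1), 2))) * fs)[seq_len(n)]
  gmod <- if (stim && config$pulse$mode != "none")
    pulse_gain_trace(schedule, config$pulse$mode, config$pulse$depth,
                     config$pulse$tau, layout$duration, fs)
  else rep(1, n)

  mod_ch <- config$pulse$channels %||% config$channels
  channels <- list()
  gains <- list()
  spikes <- list()
  bursts <- list()
  for (ci in seq_along(config$channels)) {
    nm <- config$channels[ci]
    bg <- generate_background(config, config$seed, ci)
    g <- hab * (if (nm %in% mod_ch) gmod else 1)
    channels[[nm]] <- bg * g
    gains[[nm]] <- g
    spikes[[nm]] <- tibble(time = numeric())
    bursts[[nm]] <- tibble(onset = numeric(), offset = numeric(),
                           n_spikes = integer(), load = character())
  }

  if (config$treatment == "kainate" && config$burst_model$n_bursts > 0) {
    bi <- insert_bursts(channels[["HCi"]], fs, config$burst_model,
                        seed = config$seed)
    channels[["HCi"]] <- bi$signal
    spikes[["HCi"]] <- bi$spikes
    bursts[["HCi"]] <- bi$bursts
    if (isTRUE(config$burst_model$propagate) && "HCc" %in% names(channels)) {
      bm2 <- config$burst_model
      bm2$amplitude_snr <- bm2$amplitude_snr * (bm2$propagate_gain %||% 0.7)
      bc <- insert_bursts(channels[["HCc"]], fs, bm2, seed = config$seed,
                          at = bi$bursts$onset + bm2$kernel_ms / 2000)
      channels[["HCc"]] <- bc$signal
      spikes[["HCc"]] <- bc$spikes
      bursts[["HCc"]] <- bc$bursts
    }
  }

  rec <- lfp_recording(channels, fs,
                       pulses = if (stim) expected_pulse_times(schedule),
                       schedule = schedule,
                       meta = list(group = config$group,
                                   treatment = config$treatment,
                                   session = config$session,
                                   seed = config$seed))

  gs <- tibble(onset = numeric(), duration = numeric())
  if (config$gs_model$n_gs > 0) {
    set.seed(sub_seed(config$seed, 20L))
    margin <- config$gs_model$duration_s + config$gs_model$postictal_duration_s
    ons <- sort(runif(config$gs_model$n_gs, 30, layout$duration - margin - 30))
    for (o in ons) {
      rec <- insert_generalized_seizure(
        rec, o, config$gs_model$duration_s,
        postictal_gain = config$gs_model$postictal_gain,
        postictal_duration = config$gs_model$postictal_duration_s,
        freq = config$gs_model$freq,
        amplitude_snr = config$gs_model$amplitude_snr)
    }
    gs <- tibble(onset = ons, duration = config$gs_model$duration_s)
  }

  list(recording = rec,
       truth = list(gain = gains, spikes = spikes, bursts = bursts, gs = gs))
}
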