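# Welch PSD, band-power AUC, spectrogram. Spectral analysis runs on raw-rate
# data; the periodogram length is ten times the sampling rate (0.1-Hz
# resolution), band power is the area under the PSD within delta (1-4),
# theta (4-12), beta (12-30) and gamma (30-120 Hz).

#' Canonical frequency bands (Hz)
#' @export
lfp_bands <- function() {
  tibble(band = c("delta", "theta", "beta", "gamma"),
         f_lo = c(1, 4, 12, 30), f_hi = c(4, 12, 30, 120))
}

hanning_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

# mean periodogram over segments; x is a bare numeric vector
welch_mean_periodogram <- function(x, fs, nfft, hop, win) {
  n <- length(x)
  starts <- seq.int(1L, n - nfft + 1L, by = hop)
  acc <- numeric(nfft %/% 2 + 1)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nfft - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- fft(seg)[seq_len(nfft %/% 2 + 1)]
    acc <- acc + Re(sp * Conj(sp))
  }
  p <- acc / length(starts) * 2 / (fs * sum(win^2))
  p[1] <- p[1] / 2                       # DC not doubled
  if (nfft %% 2 == 0) p[length(p)] <- p[length(p)] / 2
  p
}

#' Welch power spectral density
#'
#' Mean of Hanning-windowed, mean-removed, 50%-overlapping periodograms.
#' One-sided density in mV^2/Hz, normalized so that its integral over
#' frequency approximates the signal variance.
#'
#' @param signal numeric trace or [masked_signal()] (mask ignored here; see
#'   [hourly_band_power()] for mask-aware spectra).
#' @param fs sampling rate in Hz.
#' @param periodogram_length segment/FFT length in samples (default `10 * fs`,
#'   i.e. 0.1-Hz resolution).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return a `psd_result` tibble with columns `frequency` (Hz) and `density`
#'   (mV^2/Hz); attributes `fs`, `periodogram_length`.
#' @export
welch_psd <- function(signal, fs = NULL, periodogram_length = NULL,
                      overlap = 0.5) {
  if (inherits(signal, "masked_signal")) {
    fs <- signal$fs
    signal <- signal$samples
  }
  if (is.null(fs)) abort("`fs` required")
  nfft <- as.integer(periodogram_length %||% (10 * fs))
  if (length(signal) < nfft)
    abort(sprintf("signal (%d samples) shorter than one periodogram (%d)",
                  length(signal), nfft))
  hop <- max(1L, as.integer(round(nfft * (1 - overlap))))
  p <- welch_mean_periodogram(as.numeric(signal), fs, nfft, hop,
                              hanning_window(nfft))
  out <- tibble(frequency = seq(0, length(p) - 1) * fs / nfft, density = p)
  attr(out, "fs") <- fs
  attr(out, "periodogram_length") <- nfft
  class(out) <- c("psd_result", class(out))
  out
}

#' Band power as area under the PSD
#'
#' Trapezoidal integral of the (piecewise-linear) density between the exact
#' band edges, so that power is additive over adjacent bands.
#'
#' @param psd a `psd_result` from [welch_psd()] (or any tibble with
#'   `frequency`, `density`).
#' @param band `c(f_lo, f_hi)` in Hz with `f_lo < f_hi`.
#' @return power in mV^2.
#' @export
#' @examples
#' psd <- welch_psd(sin(2 * pi * 8 * seq(0, 60, by = 1 / 500)), fs = 500)
#' band_auc(psd, c(4, 12))  # ~0.5 mV^2 for a unit-amplitude sine
band_auc <- function(psd, band) {
  if (band[2] <= band[1]) abort("band must satisfy f_lo < f_hi")
  f <- psd$frequency
  d <- psd$density
  if (band[1] < min(f) - 1e-9 || band[2] > max(f) + 1e-9)
    abort("band outside the PSD frequency grid")
  keep <- f > band[1] & f < band[2]
  fk <- c(band[1], f[keep], band[2])
  dk <- c(approx(f, d, band[1])$y, d[keep], approx(f, d, band[2])$y)
  sum(diff(fk) * (utils::head(dk, -1) + utils::tail(dk, -1)) / 2)
}

#' Spectrogram (short-time Fourier power)
#'
#' Hanning-windowed segments of `0.5 * fs` samples, hop `0.25 * fs` samples,
#' zero-padded to an FFT length of `10 * fs`.
#'
#' @param signal numeric trace or [masked_signal()].
#' @param fs sampling rate in Hz.
#' @param segment_length,hop,fft_length sample counts; defaults `0.5 * fs`,
#'   `0.25 * fs`, `10 * fs`.
#' @return a `spectrogram_result` list: `time` (segment centers, s),
#'   `frequency` (Hz), `power` (frequency x time matrix, mV^2/Hz).
#' @export
lfp_spectrogram <- function(signal, fs = NULL, segment_length = NULL,
                            hop = NULL, fft_length = NULL) {
  if (inherits(signal, "masked_signal")) {
    fs <- signal$fs
    signal <- signal$samples
  }
  if (is.null(fs)) abort("`fs` required")
  x <- as.numeric(signal)
  seg_n <- as.integer(segment_length %||% (0.5 * fs))
  hop_n <- as.integer(hop %||% (0.25 * fs))
  nfft <- as.integer(fft_length %||% (10 * fs))
  if (length(x) < seg_n) abort("signal shorter than one spectrogram segment")
  win <- hanning_window(seg_n)
  starts <- seq.int(1L, length(x) - seg_n + 1L, by = hop_n)
  nf <- nfft %/% 2 + 1
  pow <- matrix(0, nrow = nf, ncol = length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + seg_n - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- fft(c(seg, rep(0, nfft - seg_n)))[seq_len(nf)]
    pow[, j] <- Re(sp * Conj(sp)) * 2 / (fs * sum(win^2))
  }
  pow[1, ] <- pow[1, ] / 2
  if (nfft %% 2 == 0) pow[nf, ] <- pow[nf, ] / 2
  structure(list(time = (starts - 1 + seg_n / 2) / fs,
                 frequency = seq(0, nf - 1) * fs / nfft,
                 power = pow, fs = fs),
            class = "spectrogram_result")
}

#' @export
print.spectrogram_result <- function(x, ...) {
  cat(sprintf("<spectrogram_result> %d frequencies x %d frames, %.2f-s step\n",
              nrow(x$power), ncol(x$power), diff(x$time[1:2])))
  invisible(x)
}

#' Hour-wise band power with baseline-referenced deltas
#'
#' Welch band power per session hour (stimulation sessions use the 50-min
#' light-analysis window for hour 2). Masked (e.g. generalized-seizure)
#' samples are excluded by splitting each hour into its maximal contiguous
#' unmasked runs of at least one periodogram length and averaging their
#' periodograms with duration weights.
#'
#' @param signal a [masked_signal()] at the raw sampling rate.
#' @param layout a [session_layout()].
#' @param stim stimulation session? (uses the light-analysis window).
#' @param periodogram_length default `10 * fs`.
#' @param bands tibble like [lfp_bands()].
#' @return a `band_power_table` tibble: `hour`, `band`, `auc` (mV^2), `delta`
#'   (mV^2 vs hour 1).
#' @export
hourly_band_power <- function(signal, layout = session_layout(), stim = FALSE,
                              periodogram_length = NULL, bands = lfp_bands()) {
  s <- as_masked_signal(signal)
  nfft <- as.integer(periodogram_length %||% (10 * s$fs))
  hop <- nfft %/% 2L
  win <- hanning_window(nfft)
  wins <- layout$hours
  if (stim) wins[[2]] <- layout$light_analysis
  res <- purrr::map_dfr(seq_along(wins), function(h) {
    idx <- window_indices(wins[[h]][1], wins[[h]][2], s$fs)
    m <- s$mask[idx]
    runs <- rle(!m)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    ok <- runs$values & runs$lengths >= nfft
    if (!any(ok))
      abort(sprintf("hour %d has no unmasked run of >= %d samples", h, nfft))
    acc <- numeric(nfft %/% 2 + 1)
    wsum <- 0
    for (r in which(ok)) {
      x <- s$samples[idx[starts[r]:ends[r]]]
      acc <- acc + welch_mean_periodogram(x, s$fs, nfft, hop, win) * length(x)
      wsum <- wsum + length(x)
    }
    psd <- tibble(frequency = seq(0, nfft %/% 2) * s$fs / nfft,
                  density = acc / wsum)
    tibble(hour = h, band = bands$band,
           auc = purrr::map2_dbl(bands$f_lo, bands$f_hi,
                                 ~ band_auc(psd, c(.x, .y))))
  })
  res <- res |>
    group_by(.data$band) |>
    mutate(delta = .data$auc - .data$auc[.data$hour == 1]) |>
    ungroup() |>
    arrange(.data$hour, match(.data$band, bands$band))
  class(res) <- c("band_power_table", class(res))
  res
}
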