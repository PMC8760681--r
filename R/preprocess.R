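# Downsampling, exclusion masking, session segmentation.

#' Masked signal
#'
#' A single-channel trace with a per-sample exclusion mask. Masked samples
#' (e.g. generalized-seizure periods) are excluded from analysis: sums skip
#' them and effective durations shrink accordingly — they are never
#' zero-filled.
#'
#' @param samples numeric trace in mV.
#' @param fs sampling rate in Hz.
#' @param mask logical, `TRUE` = excluded; recycled from `FALSE` if missing.
#' @param provenance character vector of applied operations.
#' @return an object of class `masked_signal`.
#' @export
masked_signal <- function(samples, fs, mask = NULL, provenance = character()) {
  samples <- as.numeric(samples)
  mask <- mask %||% rep(FALSE, length(samples))
  if (length(mask) != length(samples))
    abort("mask length must equal sample length")
  structure(list(samples = samples, fs = fs, mask = as.logical(mask),
                 provenance = provenance),
            class = "masked_signal")
}

#' @export
print.masked_signal <- function(x, ...) {
  cat(sprintf("<masked_signal> %d samples @ %g Hz (%.1f s), %.2f%% masked\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              100 * mean(x$mask)))
  invisible(x)
}

as_masked_signal <- function(x, fs = NULL) {
  if (inherits(x, "masked_signal")) return(x)
  if (is.null(fs)) abort("`fs` required when passing a bare numeric trace")
  masked_signal(x, fs)
}

# IIR filtering at C speed: the MA part via stats::filter(convolution), the
# AR part via stats::filter(recursive). `a[1]` must be 1 (signal::butter
# returns normalized coefficients).
iir_filter <- function(b, a, x) {
  y <- stats::filter(c(rep(0, length(b) - 1), x), b, method = "convolution",
                     sides = 1)
  y <- y[-seq_len(length(b) - 1)]
  if (length(a) > 1)
    y <- stats::filter(y, -a[-1], method = "recursive")
  as.numeric(y)
}

# zero-phase IIR: forward then time-reversed pass
iir_filtfilt <- function(flt, x) {
  b <- as.numeric(flt$b)
  a <- as.numeric(flt$a)
  rev(iir_filter(b, a, rev(iir_filter(b, a, x))))
}

# Symmetric FIR low-pass applied with exact group-delay compensation:
# linear-phase taps (odd count), FFT overlap-free convolution, then an
# integer shift, which for a symmetric kernel equals zero-phase filtering.
# Edges are reflection-padded.
fir_zerophase <- function(x, taps) {
  l <- (length(taps) - 1L) / 2L
  n <- length(x)
  if (n <= l) abort("signal too short for the anti-alias filter")
  pad <- c(rev(x[seq_len(l) + 1L]), x, rev(x[n - seq_len(l)]))
  nfft <- stats::nextn(length(pad) + length(taps) - 1L, c(2, 3, 5))
  y <- Re(fft(fft(c(pad, rep(0, nfft - length(pad)))) *
              fft(c(taps, rep(0, nfft - length(taps)))), inverse = TRUE)) / nfft
  y[(2L * l + 1L):(2L * l + n)]
}

#' Downsample by an integer factor with anti-alias filtering
#'
#' Zero-phase low-pass (symmetric FIR, cutoff `0.4 * fs_out`) followed by
#' decimation. Sinusoids below `0.4 * fs_out` keep their amplitude within 1%;
#' content above the output Nyquist is attenuated by more than 20 dB.
#'
#' @param signal numeric trace or [masked_signal()].
#' @param fs_in input rate (Hz); taken from the object if a `masked_signal`.
#' @param fs_out output rate (Hz); `fs_in` must be an integer multiple.
#' @return same type as the input, at `fs_out`. For a `masked_signal`, an
#'   output sample is masked if any contributing input sample was masked.
#' @export
#' @examples
#' x <- sin(2 * pi * 8 * seq(0, 2, by = 1e-4))
#' length(downsample(x, 10000, 500))
downsample <- function(signal, fs_in = NULL, fs_out = 500) {
  is_ms <- inherits(signal, "masked_signal")
  if (is_ms) fs_in <- signal$fs
  if (is.null(fs_in)) abort("`fs_in` required")
  factor <- fs_in / fs_out
  if (abs(factor - round(factor)) > 1e-9)
    abort(sprintf("fs_in (%g) must be an integer multiple of fs_out (%g)",
                  fs_in, fs_out))
  factor <- as.integer(round(factor))
  x <- if (is_ms) signal$samples else as.numeric(signal)
  if (factor == 1L) return(signal)
  cutoff <- 0.4 * fs_out / (fs_in / 2)     # in Nyquist units
  ntaps <- 2L * (10L * factor) + 1L        # odd, symmetric
  taps <- signal::fir1(ntaps - 1L, cutoff)
  y <- fir_zerophase(x, taps)
  keep <- seq.int(1L, length(y), by = factor)
  if (!is_ms) return(y[keep])
  m <- signal$mask
  pad_n <- factor * ceiling(length(m) / factor) - length(m)
  mm <- matrix(c(m, rep(FALSE, pad_n)), nrow = factor)
  masked_signal(y[keep], fs_out, mask = colSums(mm) > 0,
                provenance = c(signal$provenance,
                               sprintf("downsample:%g->%g", fs_in, fs_out)))
}

#' Build an exclusion mask from annotations
#'
#' Samples inside any annotated interval whose label is in `labels` are
#' flagged excluded (union of intervals; overlaps are not double-counted).
#'
#' @param recording an [lfp_recording()].
#' @param channel channel name or index.
#' @param labels annotation labels to exclude (default `"GS"`).
#' @return a [masked_signal()] for the chosen channel.
#' @export
build_mask <- function(recording, channel = 1, labels = "GS") {
  stopifnot(inherits(recording, "lfp_recording"))
  x <- recording$channels[[channel]]
  ann <- recording$annotations
  known <- unique(ann$label)
  missing_lab <- setdiff(labels, known)
  if (length(missing_lab) && nrow(ann))
    warn(sprintf("no annotations with label(s): %s",
                 paste(missing_lab, collapse = ", ")))
  mask <- rep(FALSE, length(x))
  sel <- ann[ann$label %in% labels, , drop = FALSE]
  for (i in seq_len(nrow(sel))) {
    idx <- window_indices(sel$onset_s[i],
                          min(sel$onset_s[i] + sel$duration_s[i],
                              recording$duration),
                          recording$fs)
    mask[idx] <- TRUE
  }
  masked_signal(x, recording$fs, mask,
                provenance = sprintf("mask:%s", paste(labels, collapse = "+")))
}

#' Split a session into analysis segments
#'
#' Returns the named half-open windows of a [session_layout()]: the three
#' hours, `pre`, `light_analysis` (the light-ON hour minus the fade-off
#' tail) and `post`.
#'
#' @param signal a [masked_signal()] (or an [lfp_recording()], in which case
#'   `channel` selects the trace and no samples are masked).
#' @param layout a [session_layout()].
#' @param channel channel used when `signal` is a recording.
#' @return a tibble with columns `segment`, `from_s`, `to_s`, `n_samples`.
#' @export
segment_session <- function(signal, layout = session_layout(), channel = 1) {
  if (inherits(signal, "lfp_recording"))
    signal <- masked_signal(signal$channels[[channel]], signal$fs)
  stopifnot(inherits(signal, "masked_signal"))
  dur <- length(signal$samples) / signal$fs
  segs <- list(hour1 = layout$hours[[1]], hour2 = layout$hours[[2]],
               hour3 = layout$hours[[3]], pre = layout$pre,
               light_analysis = layout$light_analysis, post = layout$post)
  short <- names(segs)[vapply(segs, function(s) s[2] > dur + 1e-9, logical(1))]
  if (length(short))
    abort(sprintf("recording (%.0f s) shorter than layout; missing segment(s): %s",
                  dur, paste(short, collapse = ", ")))
  tibble(segment = names(segs),
         from_s = vapply(segs, `[`, numeric(1), 1),
         to_s = vapply(segs, `[`, numeric(1), 2),
         n_samples = vapply(segs, function(s)
           length(window_indices(s[1], s[2], signal$fs)), numeric(1)))
}
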