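# ggplot2 graphics for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_errorbar geom_raster labs scale_x_log10 scale_y_log10
#'   scale_fill_viridis_c facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot hour-wise line length
#'
#' @param object a `line_length_summary` from [hourly_line_length()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot line_length_summary
#' @export
autoplot.line_length_summary <- function(object, ...) {
  ggplot(object, aes(x = factor(.data$hour), y = .data$delta)) +
    geom_col(fill = "grey35") +
    labs(x = "recording hour", y = "line length change (mV/s)",
         title = "Hour-wise line length (hour 1 = baseline)") +
    theme_minimal()
}

#' Plot pulse-triggered line lengths
#'
#' @param object a `pulse_response` from [pulse_triggered()].
#' @param ... unused.
#' @return a ggplot with per-pulse values and series means.
#' @method autoplot pulse_response
#' @export
autoplot.pulse_response <- function(object, ...) {
  long <- tidy(object)
  long$series <- factor(long$series, levels = c("pre", "before", "after"))
  ggplot(long, aes(x = .data$series, y = .data$line_length)) +
    geom_point(alpha = 0.25, position = ggplot2::position_jitter(width = 0.1)) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "black") +
    labs(x = NULL, y = "line length (mV/s)",
         title = "Pulse-triggered line length") +
    theme_minimal()
}

#' Plot a power spectral density
#'
#' @param object a `psd_result` from [welch_psd()].
#' @param fmax upper frequency limit of the plot (Hz).
#' @param ... unused.
#' @return a ggplot (log-log).
#' @method autoplot psd_result
#' @export
autoplot.psd_result <- function(object, fmax = 120, ...) {
  d <- object[object$frequency > 0 & object$frequency <= fmax, ]
  ggplot(d, aes(x = .data$frequency, y = .data$density)) +
    geom_line() +
    scale_x_log10() + scale_y_log10() +
    labs(x = "frequency (Hz)", y = expression(PSD ~ (mV^2 / Hz))) +
    theme_minimal()
}

#' Plot a spectrogram
#'
#' @param object a `spectrogram_result` from [lfp_spectrogram()].
#' @param fmax upper frequency limit (Hz).
#' @param ... unused.
#' @return a ggplot raster of log10 power.
#' @method autoplot spectrogram_result
#' @export
autoplot.spectrogram_result <- function(object, fmax = 120, ...) {
  keep <- object$frequency <= fmax
  d <- tidyr::expand_grid(time = object$time,
                          frequency = object$frequency[keep])
  d$power <- as.vector(t(object$power[keep, , drop = FALSE]))
  ggplot(d, aes(.data$time, .data$frequency,
                fill = log10(.data$power + 1e-12))) +
    geom_raster() +
    scale_fill_viridis_c(name = "log10 power") +
    labs(x = "time (s)", y = "frequency (Hz)") +
    theme_minimal()
}

#' Plot hour-wise band power
#'
#' @param object a `band_power_table` from [hourly_band_power()].
#' @param ... unused.
#' @return a ggplot faceted by band.
#' @method autoplot band_power_table
#' @export
autoplot.band_power_table <- function(object, ...) {
  d <- as_tibble(object)
  d$band <- factor(d$band, levels = c("delta", "theta", "beta", "gamma"))
  ggplot(d, aes(x = factor(.data$hour), y = .data$auc)) +
    geom_col(fill = "grey35") +
    facet_wrap(~band, scales = "free_y") +
    labs(x = "recording hour", y = expression(band ~ power ~ (mV^2))) +
    theme_minimal()
}
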