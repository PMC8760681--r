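# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a statistical result
#'
#' @param x an `lfp_stat`.
#' @param ... unused.
#' @return one row per effect (omnibus tests) plus one row per post-hoc pair
#'   if present; columns `test`, `term`, `statistic`, `df1`, `df2`,
#'   `p.value`, `alpha`, `estimate`.
#' @method tidy lfp_stat
#' @export
tidy.lfp_stat <- function(x, ...) {
  base <- if (!is.null(x$terms)) {
    tibble(test = x$test, term = x$terms$effect, statistic = x$terms$statistic,
           df1 = x$terms$df1, df2 = x$terms$df2, p.value = x$terms$p_value,
           alpha = x$alpha, estimate = NA_real_)
  } else {
    tibble(test = x$test, term = "omnibus", statistic = x$statistic,
           df1 = x$df[1], df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
           p.value = x$p_value, alpha = x$alpha, estimate = x$estimate)
  }
  if (!is.null(x$posthoc))
    base <- bind_rows(base,
                      tibble(test = x$test, term = x$posthoc$pair,
                             statistic = NA_real_, df1 = NA_real_,
                             df2 = NA_real_, p.value = x$posthoc$p_adjusted,
                             alpha = x$alpha, estimate = x$posthoc$estimate))
  base
}

#' @rdname tidy.lfp_stat
#' @method glance lfp_stat
#' @export
glance.lfp_stat <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic,
         df1 = x$df[1], df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
         p.value = x$p_value, alpha = x$alpha, n = x$n,
         significant = x$p_value < x$alpha)
}

#' Tidy a pulse response
#'
#' @param x a `pulse_response` from [pulse_triggered()].
#' @param ... unused.
#' @return the per-pulse snippet tibble in long form: `pulse_time`, `series`,
#'   `line_length`.
#' @method tidy pulse_response
#' @export
tidy.pulse_response <- function(x, ...) {
  tidyr::pivot_longer(x$snippets, c("pre", "before", "after"),
                      names_to = "series", values_to = "line_length")
}

#' @rdname tidy.pulse_response
#' @method glance pulse_response
#' @export
glance.pulse_response <- function(x, ...) {
  m <- x$means$mean_line_length
  tibble(pre = m[1], before = m[2], after = m[3],
         after_pre_ratio = m[3] / m[1], before_pre_ratio = m[2] / m[1],
         n_pulses = x$n_used, n_dropped = x$n_dropped, window_s = x$window)
}
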