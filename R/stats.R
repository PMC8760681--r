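# Statistical battery over per-animal summaries. Conventions: two-tailed
# p-values throughout; the significance level alpha is recorded with every
# result (Bonferroni-scaled where several planned comparisons share a
# family, e.g. alpha = 0.025 for the two hour-wise baseline contrasts);
# statistics run on per-animal values after technical-replicate averaging.

new_lfp_stat <- function(test, statistic, df, p_value, alpha = 0.05,
                         estimate = NA_real_, n = NA_integer_,
                         posthoc = NULL, terms = NULL) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, alpha = alpha, estimate = estimate,
                 n = n, posthoc = posthoc, terms = terms),
            class = "lfp_stat")
}

#' @export
print.lfp_stat <- function(x, ...) {
  cat(sprintf("<lfp_stat> %s: statistic = %.4f, df = %s, p = %.4g (alpha = %g)\n",
              x$test, x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_value, x$alpha))
  if (!is.null(x$terms)) print(x$terms)
  if (!is.null(x$posthoc)) {
    cat("  post hoc:\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' Average technical replicates into per-animal values
#'
#' Arithmetic mean of repeated sessions of the same type, so that the animal
#' (biological replicate) is the statistical unit.
#'
#' @param data a data frame of per-session values.
#' @param value name of the value column.
#' @param by grouping columns identifying one animal-level cell (default
#'   `c("animal", "session")`).
#' @return a tibble with one row per group: the grouping columns, `value`
#'   (mean) and `n_sessions`.
#' @export
#' @examples
#' average_replicates(
#'   data.frame(animal = "m1", session = "ref", value = c(10, 12)))
average_replicates <- function(data, value = "value",
                               by = intersect(c("animal", "session"),
                                              names(data))) {
  data |>
    group_by(across(all_of(by))) |>
    summarise(n_sessions = dplyr::n(),
              value = mean(.data[[value]]), .groups = "drop") |>
    relocate(all_of(by), "value", "n_sessions")
}

#' One-sample t-test
#'
#' `t = (mean - mu) / (sd / sqrt(n))`, `df = n - 1`, two-tailed p. The
#' recorded significance level is Bonferroni-scaled:
#' `alpha = 0.05 / n_comparisons`.
#'
#' @param values numeric vector, `n >= 2`.
#' @param mu null value (default 0).
#' @param n_comparisons size of the planned-comparison family (default 1).
#' @return an `lfp_stat`.
#' @export
one_sample_t <- function(values, mu = 0, n_comparisons = 1) {
  n <- length(values)
  if (n < 2) abort("need at least two values")
  if (sd(values) == 0) abort("zero variance: t-test undefined")
  tt <- stats::t.test(values, mu = mu)
  new_lfp_stat("one-sample t", unname(tt$statistic), unname(tt$parameter),
               tt$p.value, alpha = 0.05 / n_comparisons,
               estimate = mean(values) - mu, n = n)
}

#' Paired t-test
#'
#' One-sample t-test of the pairwise differences against zero.
#'
#' @param values_a,values_b matched numeric vectors of equal length.
#' @param n_comparisons planned-comparison family size.
#' @return an `lfp_stat`.
#' @export
paired_t <- function(values_a, values_b, n_comparisons = 1) {
  if (length(values_a) != length(values_b))
    abort("paired samples must have equal length")
  d <- values_a - values_b
  if (sd(d) == 0) abort("zero variance of differences: paired t undefined")
  out <- one_sample_t(d, mu = 0, n_comparisons = n_comparisons)
  out$test <- "paired t"
  out
}

# balanced complete check + cell means
rm_table <- function(data, value, subject, factors) {
  cells <- data |> count(across(all_of(c(subject, factors))))
  if (any(cells$n != 1))
    abort("repeated-measures design must have exactly one value per cell")
  full <- prod(vapply(c(subject, factors),
                      function(f) length(unique(data[[f]])), numeric(1)))
  if (nrow(cells) != full)
    abort("repeated-measures design has missing cells (no imputation)")
  invisible(TRUE)
}

#' Repeated-measures ANOVA (one or two within-subject factors)
#'
#' Balanced complete designs only; no sphericity correction is applied (a
#' documented limitation of the battery this package mirrors). With a single
#' two-level factor, `F` equals the square of the paired t statistic. A zero
#' effect sum of squares yields `F = 0`, `p = 1` by convention.
#'
#' @param data long data frame.
#' @param value,subject column names of the response and the subject id.
#' @param within character vector of one or two within-subject factor
#'   columns.
#' @return an `lfp_stat`; for two factors, `$terms` is a tibble with one row
#'   per effect (two main effects and the interaction) and the head fields
#'   describe the first factor's main effect.
#' @export
rm_anova <- function(data, value = "value", subject = "subject",
                     within = "condition") {
  if (!length(within) %in% 1:2) abort("`within` must name one or two factors")
  rm_table(data, value, subject, within)
  y <- data[[value]]
  s <- factor(data[[subject]])
  g <- mean(y)
  eff <- function(means, mult, df) list(ss = mult * sum((means - g)^2), df = df)
  if (length(within) == 1) {
    a <- factor(data[[within]])
    ybar_a <- tapply(y, a, mean)
    ybar_s <- tapply(y, s, mean)
    ss_a <- nlevels(s) * sum((ybar_a - g)^2)
    fit <- ybar_s[s] + ybar_a[a] - g
    ss_e <- sum((y - fit)^2)
    df_a <- nlevels(a) - 1
    df_e <- df_a * (nlevels(s) - 1)
    f <- if (ss_a == 0) 0 else (ss_a / df_a) / (ss_e / df_e)
    p <- if (ss_a == 0) 1 else stats::pf(f, df_a, df_e, lower.tail = FALSE)
    return(new_lfp_stat("RM ANOVA (one-way)", f, c(df_a, df_e), p,
                        n = nlevels(s)))
  }
  a <- factor(data[[within[1]]])
  b <- factor(data[[within[2]]])
  m_s <- tapply(y, s, mean); m_a <- tapply(y, a, mean); m_b <- tapply(y, b, mean)
  m_sa <- tapply(y, list(s, a), mean); m_sb <- tapply(y, list(s, b), mean)
  m_ab <- tapply(y, list(a, b), mean)
  ns <- nlevels(s); na <- nlevels(a); nb <- nlevels(b)
  terms <- list(
    list(name = within[1],
         ss = ns * nb * sum((m_a - g)^2), df1 = na - 1,
         ss_e = nb * sum((m_sa - outer(m_s, m_a, `+`) + g)^2),
         df2 = (na - 1) * (ns - 1)),
    list(name = within[2],
         ss = ns * na * sum((m_b - g)^2), df1 = nb - 1,
         ss_e = na * sum((m_sb - outer(m_s, m_b, `+`) + g)^2),
         df2 = (nb - 1) * (ns - 1)),
    list(name = paste(within, collapse = ":"),
         ss = ns * sum((m_ab - outer(m_a, m_b, `+`) + g)^2),
         df1 = (na - 1) * (nb - 1),
         ss_e = {
           fit <- m_sa[cbind(s, a)] + m_sb[cbind(s, b)] + m_ab[cbind(a, b)] -
             m_s[s] - m_a[a] - m_b[b] + g
           sum((y - fit)^2)
         },
         df2 = (na - 1) * (nb - 1) * (ns - 1)))
  tab <- purrr::map_dfr(terms, function(tm) {
    f <- if (tm$ss == 0) 0 else (tm$ss / tm$df1) / (tm$ss_e / tm$df2)
    p <- if (tm$ss == 0) 1 else stats::pf(f, tm$df1, tm$df2, lower.tail = FALSE)
    tibble(effect = tm$name, statistic = f, df1 = tm$df1, df2 = tm$df2,
           p_value = p)
  })
  new_lfp_stat("RM ANOVA (two-way)", tab$statistic[1],
               c(tab$df1[1], tab$df2[1]), tab$p_value[1],
               n = ns, terms = tab)
}

#' One-way (between-subjects) ANOVA
#'
#' @param data long data frame.
#' @param value,group column names.
#' @return an `lfp_stat`.
#' @export
one_way_anova <- function(data, value = "value", group = "group") {
  fit <- stats::aov(stats::reformulate(group, value), data = data)
  tab <- summary(fit)[[1]]
  new_lfp_stat("one-way ANOVA", tab$`F value`[1], tab$Df[1:2],
               tab$`Pr(>F)`[1], n = nrow(data))
}

#' Post hoc multiple comparisons
#'
#' `"tukey"`: all pairwise comparisons via the studentized range, using the
#' within-subject error when `subject` is given (matched design) or the
#' one-way ANOVA error otherwise. `"dunnett"`: comparisons against a control
#' level (multivariate-t adjustment via multcomp). `"dunn"`: rank-based
#' pairwise z tests with Bonferroni scaling over the tested pairs.
#'
#' @param data long data frame.
#' @param value,group,subject column names (`subject = NULL` for unmatched).
#' @param method `"tukey"`, `"dunnett"` or `"dunn"`.
#' @param control control level for Dunnett (default: first factor level).
#' @return a tibble with `pair`, `estimate`, `p_adjusted`.
#' @export
posthoc <- function(data, value = "value", group = "group", subject = NULL,
                    method = c("tukey", "dunnett", "dunn"), control = NULL) {
  method <- match.arg(method)
  g <- factor(data[[group]])
  y <- data[[value]]
  if (method == "dunn") {
    r <- rank(y)
    n <- length(y)
    tie <- table(y)
    tie_corr <- sum(tie^3 - tie) / (12 * (n - 1))
    v0 <- n * (n + 1) / 12 - tie_corr
    levs <- levels(g)
    pairs <- utils::combn(levs, 2, simplify = FALSE)
    m <- length(pairs)
    return(purrr::map_dfr(pairs, function(pr) {
      i <- g == pr[1]; j <- g == pr[2]
      z <- (mean(r[i]) - mean(r[j])) /
        sqrt(v0 * (1 / sum(i) + 1 / sum(j)))
      tibble(pair = paste(pr, collapse = " vs "),
             estimate = mean(y[i]) - mean(y[j]),
             p_adjusted = min(1, 2 * stats::pnorm(-abs(z)) * m))
    }))
  }
  df <- data.frame(y = y, g = g)
  if (!is.null(subject)) df$s <- factor(data[[subject]])
  if (method == "tukey") {
    fit <- if (is.null(subject)) stats::aov(y ~ g, data = df)
           else stats::aov(y ~ s + g, data = df)
    tk <- stats::TukeyHSD(fit, "g")$g
    return(tibble(pair = gsub("-", " vs ", rownames(tk), fixed = TRUE),
                  estimate = tk[, "diff"], p_adjusted = tk[, "p adj"]))
  }
  # dunnett
  if (!is.null(control)) df$g <- stats::relevel(df$g, ref = control)
  fit <- if (is.null(subject)) stats::aov(y ~ g, data = df)
         else stats::aov(y ~ s + g, data = df)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- summary(gl)
  tibble(pair = gsub(" - ", " vs ", names(sm$test$coefficients)),
         estimate = unname(sm$test$coefficients),
         p_adjusted = unname(as.numeric(sm$test$pvalues)))
}

#' Rank-based omnibus tests
#'
#' Friedman's test for matched designs (complete subject-by-condition table,
#' at least three conditions) or the Kruskal-Wallis test (tie-corrected) for
#' independent groups. When all observations are equal the statistic is 0 and
#' p is 1 by convention (the tie correction is degenerate there).
#'
#' @param data long data frame.
#' @param value,group,subject column names (`subject` required for Friedman).
#' @param design `"friedman"` or `"kruskal"`.
#' @return an `lfp_stat`.
#' @export
rank_tests <- function(data, value = "value", group = "group",
                       subject = "subject",
                       design = c("friedman", "kruskal")) {
  design <- match.arg(design)
  y <- data[[value]]
  g <- factor(data[[group]])
  if (length(unique(y)) == 1) {
    return(new_lfp_stat(design, 0, nlevels(g) - 1, 1, n = length(y)))
  }
  if (design == "friedman") {
    if (nlevels(g) < 3) abort("Friedman's test needs at least 3 conditions")
    rm_table(data, value, subject, group)
    s <- factor(data[[subject]])
    ft <- stats::friedman.test(y, g, s)
    new_lfp_stat("Friedman", unname(ft$statistic), unname(ft$parameter),
                 ft$p.value, n = nlevels(s))
  } else {
    if (nlevels(g) < 2) abort("Kruskal-Wallis needs at least 2 groups")
    kt <- stats::kruskal.test(y, g)
    new_lfp_stat("Kruskal-Wallis", unname(kt$statistic),
                 unname(kt$parameter), kt$p.value, n = length(y))
  }
}

#' Pearson correlation
#'
#' @param x,y numeric vectors, `n >= 3`, non-degenerate.
#' @return an `lfp_stat` whose `estimate` is `r`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    abort("need matched vectors with n >= 3")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  new_lfp_stat("Pearson correlation", unname(ct$statistic),
               unname(ct$parameter), ct$p.value,
               estimate = unname(ct$estimate), n = length(x))
}
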