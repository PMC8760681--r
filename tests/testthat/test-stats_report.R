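test_that("replicate averaging reduces sessions to per-animal values", {
  d <- tibble::tibble(animal = c("m1", "m1", "m2"),
                      session = "ref", value = c(10, 12, 7))
  out <- average_replicates(d)
  expect_equal(out$value, c(11, 7))
  expect_equal(out$n_sessions, c(2L, 1L))
  d3 <- tibble::tibble(animal = "m1", session = "ref", value = c(1, 2, 6))
  expect_equal(average_replicates(d3)$value, 3)
})

test_that("one-sample t matches hand computation and the t CDF", {
  r <- one_sample_t(c(1, 2, 3), mu = 0, n_comparisons = 2)
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-6)
  expect_equal(r$statistic, 3.4641, tolerance = 1e-4)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 2 * stats::pt(-2 * sqrt(3), df = 2),
               tolerance = 1e-9)
  expect_equal(r$p_value, 0.0742, tolerance = 1e-3)
  expect_equal(r$alpha, 0.025)
  r0 <- one_sample_t(c(-3, -1, 1, 3), mu = 0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_error(one_sample_t(c(2, 2, 2), 0), "zero variance")
  expect_error(one_sample_t(5, 0), "two values")
})

test_that("paired t reduces to the one-sample case on differences", {
  a <- c(4, 6, 9)
  b <- c(3, 4, 6)
  r <- paired_t(a, b)
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-6)
  r_swap <- paired_t(b, a)
  expect_equal(r_swap$statistic, -r$statistic, tolerance = 1e-12)
  expect_equal(r_swap$p_value, r$p_value, tolerance = 1e-12)
  expect_error(paired_t(a, a), "zero variance")
  expect_error(paired_t(a, c(1, 2)), "equal length")
})

test_that("one-way RM ANOVA equals the squared paired t on two conditions", {
  set.seed(19)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    d <- tidyr::expand_grid(subject = paste0("s", 1:n),
                            condition = c("a", "b"))
    d$value <- rnorm(nrow(d))
    wide <- tidyr::pivot_wider(d, names_from = "condition",
                               values_from = "value")
    tt <- paired_t(wide$a, wide$b)
    fr <- rm_anova(d, within = "condition")
    expect_equal(fr$statistic, tt$statistic^2, tolerance = 1e-9)
    expect_equal(fr$p_value, tt$p_value, tolerance = 1e-9)
  }
})

test_that("RM ANOVA agrees with aov error strata and handles degeneracy", {
  set.seed(20)
  d <- tidyr::expand_grid(subject = paste0("s", 1:6),
                          condition = c("pre", "before", "after"))
  d$value <- rnorm(nrow(d))
  fr <- rm_anova(d, within = "condition")
  fit <- stats::aov(value ~ condition + Error(subject/condition),
                    data = transform(d, subject = factor(subject),
                                     condition = factor(condition)))
  tab <- summary(fit)[["Error: subject:condition"]][[1]]
  expect_equal(fr$statistic, tab$`F value`[1], tolerance = 1e-9)
  expect_equal(fr$p_value, tab$`Pr(>F)`[1], tolerance = 1e-9)
  # per-subject constants: zero effect, F = 0 by convention
  d0 <- tidyr::expand_grid(subject = paste0("s", 1:4),
                           condition = c("a", "b", "c"))
  d0$value <- rep(c(1, 5, 9, 2), each = 3)
  f0 <- rm_anova(d0, within = "condition")
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p_value, 1)
  # adding a constant to one subject's whole row leaves F unchanged
  d1 <- d
  d1$value[d1$subject == "s3"] <- d1$value[d1$subject == "s3"] + 100
  expect_equal(rm_anova(d1, within = "condition")$statistic, fr$statistic,
               tolerance = 1e-9)
  # incomplete designs are refused
  expect_error(rm_anova(d[-1, ], within = "condition"), "missing cells")
})

test_that("two-way RM ANOVA matches aov within-subject strata", {
  set.seed(21)
  d <- tidyr::expand_grid(subject = paste0("s", 1:5),
                          band = c("theta", "beta", "gamma"),
                          hour = c("h1", "h2", "h3"))
  d$value <- rnorm(nrow(d))
  fr <- rm_anova(d, within = c("band", "hour"))
  fit <- stats::aov(value ~ band * hour + Error(subject / (band * hour)),
                    data = transform(d, subject = factor(subject),
                                     band = factor(band), hour = factor(hour)))
  sm <- summary(fit)
  f_band <- sm[["Error: subject:band"]][[1]]$`F value`[1]
  f_hour <- sm[["Error: subject:hour"]][[1]]$`F value`[1]
  f_int <- sm[["Error: subject:band:hour"]][[1]]$`F value`[1]
  expect_equal(fr$terms$statistic, c(f_band, f_hour, f_int), tolerance = 1e-9)
  expect_equal(fr$terms$effect, c("band", "hour", "band:hour"))
})

test_that("post hoc adjustments behave sanely on identical and ordered groups", {
  same <- tibble::tibble(group = rep(c("a", "b", "c"), each = 4),
                         subject = rep(paste0("s", 1:4), 3),
                         value = rep(c(1.0, 1.1, 0.9, 1.0), 3))
  tk <- posthoc(same, group = "group", method = "tukey")
  expect_true(all(tk$p_adjusted > 0.999))
  dn <- posthoc(same, group = "group", method = "dunn")
  expect_true(all(dn$p_adjusted == 1))
  set.seed(22)
  dunn_in <- tibble::tibble(group = rep(c("g1", "g2", "g3"), each = 2),
                            value = c(1, 2, 3, 4, 5, 6))
  dd <- posthoc(dunn_in, method = "dunn")
  # the largest-gap pair gets the smallest adjusted p
  expect_equal(dd$pair[which.min(dd$p_adjusted)], "g1 vs g3")
  # Bonferroni-scaled p never undercuts the unadjusted z-test p
  r <- rank(dunn_in$value)
  z13 <- abs(mean(r[1:2]) - mean(r[5:6])) /
    sqrt((6 * 7 / 12) * (1 / 2 + 1 / 2))
  expect_gte(dd$p_adjusted[dd$pair == "g1 vs g3"], 2 * stats::pnorm(-z13))
  set.seed(23)
  dt <- posthoc(tibble::tibble(group = rep(c("ctrl", "t1", "t2"), each = 5),
                               value = rnorm(15)),
                method = "dunnett", control = "ctrl")
  expect_equal(nrow(dt), 2)
  expect_true(all(grepl("vs ctrl", dt$pair)))
  expect_true(all(dt$p_adjusted >= 0 & dt$p_adjusted <= 1))
  expect_error(posthoc(same, method = "holm"), "arg")
})

test_that("rank tests reproduce hand-computed statistics", {
  d <- tidyr::expand_grid(subject = paste0("s", 1:3),
                          group = c("pre", "light", "post"))
  d$value <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)  # strictly increasing per subject
  fr <- rank_tests(d, design = "friedman")
  expect_equal(fr$statistic, 6)
  expect_equal(fr$df, 2)
  kd <- tibble::tibble(group = rep(c("a", "b", "c"), each = 2),
                       value = c(1, 2, 3, 4, 5, 6))
  kw <- rank_tests(kd, design = "kruskal")
  expect_equal(kw$statistic, 4.571, tolerance = 1e-3)
  allsame <- tibble::tibble(group = rep(c("a", "b", "c"), each = 2),
                            subject = rep(paste0("s", 1:2), 3), value = 5)
  expect_equal(rank_tests(allsame, design = "kruskal")$statistic, 0)
  expect_equal(rank_tests(allsame, design = "friedman")$statistic, 0)
  two <- tibble::tibble(subject = rep(c("s1", "s2"), 2),
                        group = rep(c("a", "b"), each = 2), value = 1:4)
  expect_error(rank_tests(two, design = "friedman"), "3 conditions")
})

test_that("Pearson correlation matches hand computation", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1)$estimate, 1)
  expect_equal(pearson_r(x, -x)$estimate, -1)
  r <- pearson_r(x, c(2, 1, 4, 3))
  expect_equal(r$estimate, 0.6, tolerance = 1e-12)
  expect_error(pearson_r(x, rep(2, 4)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
})

test_that("tidy and glance produce broom-shaped output", {
  r <- one_sample_t(c(1, 2, 3))
  td <- tidy(r)
  expect_true(all(c("test", "term", "statistic", "p.value", "alpha") %in%
                    names(td)))
  gl <- glance(r)
  expect_equal(nrow(gl), 1)
  expect_false(gl$significant)
  set.seed(24)
  d <- tidyr::expand_grid(subject = paste0("s", 1:5),
                          band = c("t", "g"), hour = c("1", "2"))
  d$value <- rnorm(nrow(d))
  td2 <- tidy(rm_anova(d, within = c("band", "hour")))
  expect_equal(nrow(td2), 3)
})
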