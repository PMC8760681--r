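make_spiky_trace <- function(n_spikes = 100, dur = 600, fs = 500, seed = 31,
                             snr = 8) {
  set.seed(seed)
  x <- stationary_trace(dur * fs, fs, seed = seed)
  # well-separated truth spikes on a jittered grid
  tt <- sort(seq(5, dur - 5, length.out = n_spikes) +
               runif(n_spikes, -0.2, 0.2))
  ker <- optolfp:::spike_kernel(0.04, fs)
  half <- (length(ker) - 1) %/% 2
  amp <- snr * sd(x)
  for (s0 in tt) {
    c0 <- floor(s0 * fs) + 1
    x[(c0 - half):(c0 + half)] <- x[(c0 - half):(c0 + half)] + amp * ker
  }
  list(x = x, truth = tt, fs = fs)
}

test_that("spike detection recovers inserted sharp waves with few false alarms", {
  sp <- make_spiky_trace()
  det <- detect_spikes(sp$x, fs = sp$fs)
  hits <- vapply(sp$truth, function(t0) any(abs(det$time - t0) <= 0.01),
                 logical(1))
  expect_gte(sum(hits), 95)
  # pure background: false-positive rate below 0.05 / s
  bg <- stationary_trace(600 * 500, 500, seed = 99)
  fp <- detect_spikes(bg, fs = 500)
  expect_lt(nrow(fp) / 600, 0.05)
  expect_true(all(diff(det$time) > 0))
})

test_that("spike detection handles degenerate inputs", {
  expect_error(detect_spikes(rep(1, 5000), fs = 500), "flat")
  ms <- masked_signal(rnorm(5000), 500, rep(TRUE, 5000))
  expect_equal(nrow(detect_spikes(ms)), 0)
  # refractory window enforces one event per cluster
  sp <- make_spiky_trace(n_spikes = 50, seed = 7)
  det <- detect_spikes(sp$x, fs = sp$fs, refractory = 0.08)
  expect_true(all(diff(det$time) > 0.08))
})

test_that("burst grouping follows the gap/min-spike rules", {
  b1 <- group_bursts(tibble::tibble(time = 0:4), max_gap = 2, min_spikes = 5)
  expect_equal(nrow(b1), 1)
  expect_equal(b1$n_spikes, 5L)
  b2 <- group_bursts(tibble::tibble(time = c(0, 1, 2, 10, 11, 12)),
                     max_gap = 2, min_spikes = 5)
  expect_equal(nrow(b2), 0)
  b3 <- group_bursts(tibble::tibble(time = seq(0, 19)), max_gap = 2,
                     min_spikes = 5, kernel_width = 0.04)
  expect_equal(nrow(b3), 1)
  expect_equal(b3$offset - b3$onset, 19 + 0.04)
  expect_error(group_bursts(tibble::tibble(time = c(3, 1))), "sorted")
})

test_that("load classes partition bursts by rate and duration", {
  expect_equal(classify_load(list(onset = 0, offset = 20, n_spikes = 30)),
               "high")     # 1.5 Hz, 20 s
  expect_equal(classify_load(list(onset = 0, offset = 15, n_spikes = 6)),
               "low")      # 0.4 Hz
  expect_equal(classify_load(list(onset = 0, offset = 20, n_spikes = 12)),
               "medium")   # 0.6 Hz
  # a fast but short burst is not high-load
  expect_equal(classify_load(list(onset = 0, offset = 5, n_spikes = 10)),
               "medium")
  expect_error(classify_load(list(onset = 3, offset = 3, n_spikes = 5)),
               "zero-duration")
  # every burst receives exactly one class
  set.seed(13)
  for (i in 1:25) {
    cl <- classify_load(list(onset = 0, offset = runif(1, 1, 40),
                             n_spikes = sample(5:60, 1)))
    expect_true(cl %in% c("low", "medium", "high"))
    expect_equal(length(cl), 1)
  }
})

test_that("the burst ratio is the high-load time fraction", {
  empty <- group_bursts(tibble::tibble(time = numeric()))
  expect_equal(burst_ratio(empty, 1800)$burst_ratio, 0)
  b <- tibble::tibble(onset = c(0, 500, 1000), offset = c(60, 560, 1060),
                      n_spikes = 120L, load = "high")
  expect_equal(burst_ratio(b, 1800)$burst_ratio, 0.1)
  # sessions with a generalized seizure are dropped, not zeroed
  br <- burst_ratio(b, 1800, event_list("GS", 100, 30))
  expect_true(br$dropped)
  expect_true(is.na(br$burst_ratio))
  expect_error(burst_ratio(b, 0), "positive")
})

test_that("raising the high-load threshold never raises the burst ratio", {
  sp <- make_spiky_trace(n_spikes = 200, dur = 600, seed = 17)
  det <- detect_spikes(sp$x, fs = sp$fs)
  ratios <- vapply(c(0.5, 1, 2, 4), function(hr) {
    th <- list(high_rate = hr, high_duration = 10, medium_rate = 0.25)
    b <- group_bursts(det, max_gap = 4, min_spikes = 5, thresholds = th)
    burst_ratio(b, 600)$burst_ratio
  }, numeric(1))
  expect_true(all(diff(ratios) <= 0))
})

test_that("detection is deterministic and recovers truth intervals", {
  x <- stationary_trace(600 * 500, 500, seed = 23)
  bm <- list(n_bursts = 2, duration_s = 40, intra_rate = 2, kernel_ms = 40,
             amplitude_snr = 8, propagate = FALSE)
  r <- insert_bursts(x, 500, bm, seed = 23)
  d1 <- detect_spikes(r$signal, fs = 500)
  d2 <- detect_spikes(r$signal, fs = 500)
  expect_identical(d1, d2)
  b <- group_bursts(d1)
  expect_gte(interval_jaccard(r$bursts, b, 600), 0.8)
  est <- burst_ratio(b, 600)$burst_ratio
  truth_frac <- sum(r$bursts$offset - r$bursts$onset) / 600
  expect_equal(est, truth_frac, tolerance = 0.2)
})

test_that("the cross-channel GS screener flags a bilateral seizure", {
  fs <- 200
  n <- 400 * fs
  rec <- lfp_recording(list(left = stationary_trace(n, fs, 1) * 0.1,
                            right = stationary_trace(n, fs, 2) * 0.1),
                       fs = fs)
  rec2 <- insert_generalized_seizure(rec, 150, 30, postictal_gain = 0.1,
                                     postictal_duration = 60,
                                     amplitude_snr = 10)
  rec2$annotations <- event_list()   # force the detector to work unaided
  hits <- detect_gs(rec2)
  expect_gte(nrow(hits), 1)
  expect_true(any(abs(hits$onset_s - 150) < 10))
  # no seizure, no detection
  expect_equal(nrow(detect_gs(rec)), 0)
})
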