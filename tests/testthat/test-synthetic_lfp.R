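test_that("background generation is deterministic and respects amplitudes", {
  cfg0 <- tiny_sim(oscillators = tibble::tibble(name = character(),
                                                center = numeric(),
                                                bandwidth = numeric(),
                                                rms = numeric()),
                   background = list(beta = 1, rms = 0))
  expect_equal(generate_background(cfg0, 1, 1), rep(0, 360 * 500))
  cfg <- tiny_sim(seed = 5)
  a <- generate_background(cfg, 5, 1)
  b <- generate_background(cfg, 5, 1)
  expect_identical(a, b)
  expect_false(identical(a, generate_background(cfg, 6, 1)))
  expect_lt(abs(mean(a)), 1e-9)
})

test_that("a theta-only oscillator carries its configured band power", {
  cfg <- sim_config(fs_raw = 500, layout = session_layout(60, 10),
                    oscillators = tibble::tibble(name = "theta", center = 7,
                                                 bandwidth = 3, rms = 0.15),
                    background = list(beta = 1, rms = 0),
                    amplitude_scale = 1, seed = 2)
  x <- generate_background(cfg, 2, 1)
  psd <- welch_psd(x[1:(60 * 500)], fs = 500)
  expect_equal(band_auc(psd, c(4, 12)), 0.15^2, tolerance = 0.10)
})

test_that("the pulse gain trace matches its closed forms", {
  # depth 0: identically one
  s <- pulse_schedule(0.05, light_on = c(0, 100), fadeoff_tail = 10)
  expect_equal(pulse_gain_trace(s, "suppress", 0, 3, 100, 500), rep(1, 50000))
  # single pulse: mean over (0, 2] against the analytic integral and a
  # numeric-quadrature oracle
  s1 <- pulse_schedule(0.005, light_on = c(0, 150), fadeoff_tail = 1)
  g <- pulse_gain_trace(s1, "suppress", 0.4, 3, 150, 1000)
  analytic <- 1 - 0.4 * (3 / 2) * (1 - exp(-2 / 3))
  quad <- 1 - 0.4 * stats::integrate(function(u) exp(-u / 3), 0, 2)$value / 2
  expect_equal(analytic, quad, tolerance = 1e-8)
  expect_equal(mean(g[2:2001]), analytic, tolerance = 1e-3)
  # steady-state superposition at 0.1 Hz against a long explicit summation
  s2 <- pulse_schedule(0.1, light_on = c(0, 1000), fadeoff_tail = 10)
  g2 <- pulse_gain_trace(s2, "suppress", 0.25, 12, 1000, 500)
  onsets <- seq(0, 990, by = 10)
  t_eval <- 901
  esum <- sum(exp(-(t_eval - onsets[onsets <= t_eval]) / 12))
  expect_equal(g2[t_eval * 500 + 1], 1 - 0.25 * esum, tolerance = 1e-3)
  expect_equal(1 - 0.25 * exp(-1 / 12) / (1 - exp(-10 / 12)), 0.593,
               tolerance = 1e-3)
  expect_equal(g2[t_eval * 500 + 1], 0.593, tolerance = 2e-3)
  # enhancement flips the sign
  ge <- pulse_gain_trace(s1, "enhance", 0.4, 3, 150, 500)
  expect_equal(mean(ge[2:1001]), 2 - analytic, tolerance = 1e-3)
})

test_that("gain traces are clipped at 0.05 and neutral outside light ON", {
  s <- pulse_schedule(0.5, pulse_width = 0.01, light_on = c(10, 60),
                      fadeoff_tail = 5)
  g <- pulse_gain_trace(s, "suppress", 0.9, 30, 80, 200)
  expect_true(all(g >= 0.05))
  expect_true(any(g == 0.05))       # deep stacked suppression saturates
  expect_equal(g[1:(10 * 200)], rep(1, 2000))          # before light ON
  expect_equal(g[(60 * 200 + 1):(80 * 200)], rep(1, 4000))  # after light ON
})

test_that("burst insertion writes truth that matches its own arithmetic", {
  x <- stationary_trace(1800 * 500, 500)
  bm0 <- list(n_bursts = 0, duration_s = 60, intra_rate = 2, kernel_ms = 40,
              amplitude_snr = 8, propagate = FALSE)
  r0 <- insert_bursts(x, 500, bm0, seed = 1)
  expect_identical(r0$signal, x)
  expect_equal(nrow(r0$spikes), 0)

  bm <- list(n_bursts = 3, duration_s = 60, intra_rate = 2, kernel_ms = 40,
             amplitude_snr = 8, propagate = FALSE)
  r <- insert_bursts(x, 500, bm, seed = 3)
  expect_equal(nrow(r$bursts), 3)
  frac <- sum(r$bursts$offset - r$bursts$onset) / 1800
  expect_equal(frac, 0.1, tolerance = 0.02)
  expect_true(all(r$bursts$load == "high"))
  # determinism
  r2 <- insert_bursts(x, 500, bm, seed = 3)
  expect_identical(r$spikes, r2$spikes)
  # inserted peaks are large relative to background
  expect_gt(max(abs(r$signal)), 6 * sd(x))
  # overlapping spike kernels rejected
  bm_bad <- bm
  bm_bad$kernel_ms <- 600
  expect_error(insert_bursts(x, 500, bm_bad, seed = 1), "kernel width")
})

test_that("generalized seizures are bilateral with postictal depression", {
  n <- 300 * 200
  rec <- lfp_recording(list(left = stationary_trace(n, 200, 1),
                            right = stationary_trace(n, 200, 2)),
                       fs = 200)
  out <- insert_generalized_seizure(rec, onset = 100, duration = 30,
                                    postictal_gain = 0.2,
                                    postictal_duration = 60)
  expect_equal(nrow(out$annotations), 1)
  expect_equal(out$annotations$label, "GS")
  for (ch in c("left", "right")) {
    ict <- out$channels[[ch]][(100 * 200 + 1):(130 * 200)]
    pre <- rec$channels[[ch]][(40 * 200 + 1):(100 * 200)]
    post <- out$channels[[ch]][(130 * 200 + 1):(190 * 200)]
    expect_gt(sd(ict), 3 * sd(pre))           # high-amplitude discharge
    expect_equal(sd(post), 0.2 * sd(pre), tolerance = 0.15)
  }
  # zero duration: no change
  expect_identical(insert_generalized_seizure(rec, 100, 0)$channels,
                   rec$channels)
  # truncation beyond the end warns
  expect_warning(insert_generalized_seizure(rec, 290, 30), "truncated")
})

test_that("simulated sessions are deterministic and internally consistent", {
  cfg <- tiny_sim(session = "stim_0.1", seed = 9,
                  pulse = list(mode = "suppress", depth = 0.25, tau = 12,
                               frequency = 0.1, pulse_width = 0.01,
                               channels = NULL))
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$recording$channels, s2$recording$channels)
  expect_true(all(unlist(s1$truth$gain) >= 0.05))
  expect_equal(length(s1$recording$pulses),
               length(expected_pulse_times(s1$recording$schedule)))
  # a ref session cannot carry an active pulse mode
  expect_error(simulate_experiment(
    tiny_sim(session = "ref",
             pulse = list(mode = "suppress", depth = 0.25, tau = 12,
                          frequency = 0.1, pulse_width = 0.01,
                          channels = NULL))), "ref")
  # byte-identical EDF under a fixed seed
  p1 <- withr::local_tempfile(fileext = ".edf")
  p2 <- withr::local_tempfile(fileext = ".edf")
  e1 <- withr::local_tempfile(fileext = ".csv")
  e2 <- withr::local_tempfile(fileext = ".csv")
  write_recording(s1$recording, p1, e1)
  write_recording(s2$recording, p2, e2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("kainate simulations put bursts on HCi and propagate on demand", {
  bm <- list(n_bursts = 2, duration_s = 20, intra_rate = 2, kernel_ms = 40,
             amplitude_snr = 8, propagate = FALSE, propagate_gain = 0.7)
  s <- simulate_experiment(tiny_sim(treatment = "kainate", burst_model = bm,
                                    seed = 4))
  expect_gt(nrow(s$truth$bursts$HCi), 0)
  expect_equal(nrow(s$truth$bursts$HCc), 0)
  bm$propagate <- TRUE
  s2 <- simulate_experiment(tiny_sim(treatment = "kainate", burst_model = bm,
                                     seed = 4))
  expect_gt(nrow(s2$truth$bursts$HCc), 0)
})

test_that("line length scales with the injected mean gain (linearity hook)", {
  fs <- 500
  x <- stationary_trace(20 * fs, fs)
  for (g0 in c(0.4, 0.7, 1.3)) {
    ramp <- seq(g0, g0 + 0.05, length.out = length(x))  # slowly varying gain
    l_mod <- line_length(ramp * x, fs = fs)
    l_pred <- mean(ramp) * line_length(x, fs = fs)
    expect_equal(l_mod, l_pred, tolerance = 0.03)
  }
})
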