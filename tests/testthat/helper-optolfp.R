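# Shared fixtures and independent oracles.

# naive two-line reference for the line length (independent of the package
# path: no masking, plain sum over successive differences)
ll_naive <- function(x, fs) {
  sum(abs(diff(x))) / (length(x) / fs)
}

# interval-set Jaccard overlap on a fine grid
interval_jaccard <- function(a, b, t_max, step = 0.01) {
  grid <- seq(0, t_max, by = step)
  ina <- rep(FALSE, length(grid))
  inb <- ina
  for (k in seq_len(nrow(a))) ina[grid >= a$onset[k] & grid < a$offset[k]] <- TRUE
  for (k in seq_len(nrow(b))) inb[grid >= b$onset[k] & grid < b$offset[k]] <- TRUE
  sum(ina & inb) / sum(ina | inb)
}

# steady-state mean pulse gain over [u0, u1] after a pulse, for pulse period
# T and exponential recovery tau (geometric superposition, closed form)
mean_gain_closed_form <- function(depth, tau, T, u0, u1, mode = "suppress") {
  m <- (tau / (u1 - u0)) * (exp(-u0 / tau) - exp(-u1 / tau)) /
    (1 - exp(-T / tau))
  if (mode == "suppress") 1 - depth * m else 1 + depth * m
}

# deterministic stationary test trace: sine mix plus fixed-seed noise
stationary_trace <- function(n, fs, seed = 42) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / fs
  sin(2 * pi * 7 * t) + 0.4 * sin(2 * pi * 23 * t + 1) + rnorm(n, sd = 0.3)
}

# small, fast simulator config for unit tests (not the study-scale defaults)
tiny_sim <- function(..., hour = 120, fadeoff = 20, fs_raw = 500) {
  sim_config(fs_raw = fs_raw, layout = session_layout(hour, fadeoff), ...)
}
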