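# End-to-end orchestration: simulate (optional) -> preprocess -> line length
# + spectra (+ epileptiform for kainate animals) -> replicate averaging ->
# statistics -> tidy report bundle.

pulse_mode_for_group <- function(group) {
  switch(group, PACK = "suppress", bPAC = "enhance", "none")
}

#' Pipeline configuration
#'
#' @param group virus group (`PACK`, `bPAC`, `mCherry`, `no_virus`).
#' @param treatment `saline` or `kainate`.
#' @param n_animals number of biological replicates.
#' @param replicates technical replicates per session type.
#' @param sessions session types, subset of
#'   `c("ref", "stim_0.05", "stim_0.1")`.
#' @param fs_raw raw simulation rate (Hz).
#' @param fs_ds line-length analysis rate (Hz).
#' @param layout a [session_layout()].
#' @param pulse_depth,pulse_tau pulse-response parameters passed to the
#'   simulator (mode follows the group).
#' @param habituation per-hour gains.
#' @param burst_model,gs_model simulator models (see [sim_config()]).
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(group = "PACK", treatment = "saline",
                            n_animals = 6, replicates = 2,
                            sessions = c("ref", "stim_0.1"),
                            fs_raw = 1000, fs_ds = 500,
                            layout = session_layout(600, 100),
                            pulse_depth = 0.25, pulse_tau = 12,
                            habituation = c(1.00, 0.84, 0.79),
                            burst_model = NULL, gs_model = NULL,
                            seed = 1L) {
  structure(list(group = group, treatment = treatment,
                 n_animals = n_animals, replicates = replicates,
                 sessions = sessions, fs_raw = fs_raw, fs_ds = fs_ds,
                 layout = layout, pulse_depth = pulse_depth,
                 pulse_tau = pulse_tau, habituation = habituation,
                 burst_model = burst_model, gs_model = gs_model,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

session_frequency <- function(session) {
  switch(session, stim_0.05 = 0.05, stim_0.1 = 0.1, NA_real_)
}

analyze_session <- function(rec, cfg) {
  stim <- rec$meta$session != "ref"
  target <- names(rec$channels)[length(rec$channels)]
  out <- list()
  ms_raw <- build_mask(rec, channel = target, labels = "GS")
  ms <- downsample(ms_raw, fs_out = cfg$fs_ds)
  hl <- hourly_line_length(ms, cfg$layout, stim = stim)
  out$hourly <- mutate(as_tibble(hl), channel = target)
  if (stim) {
    pr <- pulse_triggered(ms, rec$pulses, cfg$layout,
                          pulse_width = rec$schedule$pulse_width)
    out$pulse <- pr$means
  }
  bp <- hourly_band_power(ms_raw, cfg$layout, stim = stim)
  out$bands <- as_tibble(bp)
  if (cfg$treatment == "kainate") {
    out$bursts <- purrr::map_dfr(names(rec$channels), function(ch) {
      mch <- downsample(build_mask(rec, channel = ch, labels = "GS"),
                        fs_out = cfg$fs_ds)
      sp <- detect_spikes(mch)
      b <- group_bursts(sp)
      mutate(burst_ratio(b, rec$duration, rec$annotations), channel = ch)
    })
  }
  out$gs_count <- sum(rec$annotations$label == "GS")
  out
}

#' Run the full analysis pipeline on simulated sessions
#'
#' Simulates `n_animals x sessions x replicates` recordings, runs the
#' line-length, pulse-response, band-power (and, for kainate animals,
#' epileptiform) analyses on each, averages technical replicates, and runs
#' the statistical battery on per-animal values. Deterministic given
#' `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return a `report_bundle`: list of tidy tibbles (`hourly`, `pulse`,
#'   `bands`, `bursts`, `gs_counts`), a `stats` list of `lfp_stat` objects,
#'   and `provenance` (config hash, seed, package version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  rows <- tidyr::expand_grid(animal = seq_len(cfg$n_animals),
                             session = cfg$sessions,
                             replicate = seq_len(cfg$replicates))
  per_session <- purrr::pmap(rows, function(animal, session, replicate) {
    stim <- session != "ref"
    sc <- sim_config(
      fs_raw = cfg$fs_raw, layout = cfg$layout,
      habituation = cfg$habituation,
      pulse = list(mode = if (stim) pulse_mode_for_group(cfg$group) else "none",
                   depth = cfg$pulse_depth, tau = cfg$pulse_tau,
                   frequency = if (stim) session_frequency(session) else 0.1,
                   pulse_width = 0.010, channels = NULL),
      burst_model = cfg$burst_model %||% eval(formals(sim_config)$burst_model),
      gs_model = cfg$gs_model %||% eval(formals(sim_config)$gs_model),
      group = cfg$group, treatment = cfg$treatment, session = session,
      seed = sub_seed(cfg$seed, 50L, animal * 101L + replicate * 13L +
                        match(session, cfg$sessions)))
    sim <- simulate_experiment(sc)
    res <- analyze_session(sim$recording, cfg)
    res$key <- tibble(animal = animal, session = session,
                      replicate = replicate)
    res
  })

  tag <- function(tb, key) if (is.null(tb)) NULL else bind_cols(key, tb)
  hourly <- purrr::map_dfr(per_session, ~ tag(.x$hourly, .x$key))
  pulse <- purrr::map_dfr(per_session, ~ tag(.x$pulse, .x$key))
  bands <- purrr::map_dfr(per_session, ~ tag(.x$bands, .x$key))
  bursts <- purrr::map_dfr(per_session, ~ tag(.x$bursts, .x$key))
  gs_counts <- purrr::map_dfr(per_session,
                              ~ bind_cols(.x$key, tibble(gs = .x$gs_count)))

  stats_out <- list()
  # hour-wise baseline contrasts on per-animal deltas (Bonferroni family of 2)
  for (sess in cfg$sessions) {
    d <- hourly |> filter(.data$session == sess, .data$hour > 1)
    if (!nrow(d)) next
    per_an <- d |>
      group_by(.data$animal, .data$hour) |>
      summarise(value = mean(.data$delta), .groups = "drop")
    for (h in unique(per_an$hour)) {
      v <- per_an$value[per_an$hour == h]
      nm <- sprintf("hour%d_delta_%s", h, sess)
      stats_out[[nm]] <- tryCatch(one_sample_t(v, 0, n_comparisons = 2),
                                  error = function(e) NULL)
    }
  }
  # pulse response: RM ANOVA over pre/before/after + Tukey
  if (nrow(pulse)) {
    for (sess in setdiff(cfg$sessions, "ref")) {
      pa <- pulse |>
        filter(.data$session == sess) |>
        group_by(.data$animal, .data$series) |>
        summarise(value = mean(.data$mean_line_length), .groups = "drop")
      if (!nrow(pa)) next
      stats_out[[paste0("pulse_rm_", sess)]] <-
        rm_anova(pa, value = "value", subject = "animal", within = "series")
      stats_out[[paste0("pulse_tukey_", sess)]] <-
        posthoc(pa, value = "value", group = "series", subject = "animal",
                method = "tukey")
    }
  }
  # band power across hours: two-way RM ANOVA (band x hour) on ref sessions
  ba <- bands |>
    filter(.data$session == "ref") |>
    group_by(.data$animal, .data$band, .data$hour) |>
    summarise(value = mean(.data$auc), .groups = "drop")
  if (nrow(ba))
    stats_out$bands_rm_ref <- rm_anova(ba, value = "value",
                                       subject = "animal",
                                       within = c("band", "hour"))

  bundle <- structure(list(
    hourly = hourly, pulse = pulse, bands = bands, bursts = bursts,
    gs_counts = gs_counts, stats = stats_out,
    provenance = list(seed = cfg$seed, config_hash = rlang::hash(cfg),
                      n_sessions = nrow(rows))),
    class = "report_bundle")
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d session analyses (seed %d, config %s)\n",
              x$provenance$n_sessions, x$provenance$seed,
              substr(x$provenance$config_hash, 1, 8)))
  for (nm in c("hourly", "pulse", "bands", "bursts", "gs_counts"))
    if (nrow(x[[nm]] %||% tibble()))
      cat(sprintf("  $%s: %d rows\n", nm, nrow(x[[nm]])))
  cat(sprintf("  $stats: %d tests\n", length(x$stats)))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Tidy CSV per table, a JSON statistics appendix, and a run log carrying the
#' config hash and master seed. Output is deterministic (byte-identical for
#' identical bundles).
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in c("hourly", "pulse", "bands", "bursts", "gs_counts")) {
    tb <- bundle[[nm]]
    if (is.null(tb) || !nrow(tb)) next
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tb, p)
    paths <- c(paths, p)
  }
  stats_json <- purrr::map(bundle$stats, function(s) {
    if (inherits(s, "lfp_stat"))
      list(test = s$test, statistic = s$statistic, df = s$df,
           p_value = s$p_value, alpha = s$alpha, n = s$n,
           terms = s$terms, posthoc = s$posthoc)
    else s
  })
  p <- file.path(dir, "stats.json")
  jsonlite::write_json(stats_json, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)
  p <- file.path(dir, "run_log.txt")
  writeLines(c(sprintf("seed: %d", bundle$provenance$seed),
               sprintf("config_hash: %s", bundle$provenance$config_hash),
               sprintf("n_sessions: %d", bundle$provenance$n_sessions)), p)
  invisible(c(paths, p))
}
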