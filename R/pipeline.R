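# End-to-end orchestration: simulate -> preprocess -> analyze -> report.
# A run is deterministic given (inputs, seed); the manifest records the
# package version, the config, and per-stage row counts, so any table can
# be regenerated from the manifest alone. No timestamps are written, so
# re-running a config reproduces every output byte for byte.

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yml", "yaml")) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the yaml package", call. = FALSE)
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a file path",
                             call. = FALSE)
  config
}

cfg_get <- function(config, name, default = NULL, required = FALSE) {
  if (!is.null(config[[name]])) return(config[[name]])
  if (required) stop(sprintf("config is missing required field `%s` for mode `%s`",
                             name, config$mode %||% "?"), call. = FALSE)
  default
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_table <- function(df, outdir, name, counts) {
  path <- file.path(outdir, name)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  counts[[name]] <- nrow(df)
  counts
}

read_sessions_index <- function(input_dir) {
  idx_path <- file.path(input_dir, "sessions.csv")
  if (!file.exists(idx_path))
    stop(sprintf("stage input: sessions index not found: %s", idx_path),
         call. = FALSE)
  idx <- read.csv(idx_path, stringsAsFactors = FALSE)
  for (col in c("recording", "events", "truth"))
    if (col %in% names(idx))
      idx[[col]] <- ifelse(is.na(idx[[col]]) | idx[[col]] == "", NA,
                           file.path(input_dir, idx[[col]]))
  idx
}

#' Run an end-to-end analysis pipeline
#'
#' Modes (field `mode` of the config, a list or a JSON/YAML file path):
#'
#' * `"simulate"` - write a fixture suite of simulated sessions
#'   (recording + event-log CSVs, ground-truth JSON sidecars, sessions
#'   index). Fields: `preset`, `n_mice`, `schedules`, `duration`,
#'   `sample_rate`, `start_zt`.
#' * `"longterm"` - day-long fasting analysis of each `fast` session in
#'   `input_dir`: rise time constant (ZT11-ZT18 search, ZT11-ZT12
#'   baseline, reported from ZT12) and mean z dF/F0 in 1-h bins ZT11-ZT16.
#'   Writes `tau_report.csv` and `zt_bins.csv`.
#' * `"food_response"` - short-trial analysis: fall time constant and
#'   pre/post pellet-drop window means per trial. Fields: `trials` (data
#'   frame/list with `recording`, `drop_time`, `mouse_id`). Writes
#'   `trial_report.csv`.
#' * `"operant"` - extinction-session analysis of each session with an
#'   event log in `input_dir`: 30-min sliding poke rate, and (when a
#'   recording is present) poke-aligned activity with the 45-s refractory
#'   filter and decile split over the fast period. Writes
#'   `poke_rate.csv`, `aligned_pokes.csv`, `deciles.csv`.
#' * `"contrast"` - per-mouse paired difference of tau between two
#'   conditions. Fields: `tau_report` (path to a `tau_report.csv`),
#'   `conditions`. Writes `contrast.csv`.
#'
#' Common fields: `mode`, `seed`, `outdir`; `input_dir` where noted.
#'
#' @param config List or path to a JSON/YAML config.
#' @return The run manifest (list), invisibly; tables and `manifest.json`
#'   are written to `outdir`.
#' @export
run_pipeline <- function(config) {
  config <- read_config(config)
  mode <- cfg_get(config, "mode", required = TRUE)
  seed <- as.integer(cfg_get(config, "seed", 1))
  outdir <- cfg_get(config, "outdir", required = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  if (mode == "simulate") {
    fix_dir <- file.path(outdir, "fixtures")
    man <- write_fixture_suite(
      fix_dir,
      n_mice = cfg_get(config, "n_mice", 3),
      preset = cfg_get(config, "preset", "agrp_fast"),
      schedules = cfg_get(config, "schedules", c("ad_lib", "fast")),
      duration = cfg_get(config, "duration", 23),
      sample_rate = cfg_get(config, "sample_rate", 1),
      seed = seed,
      start_zt = cfg_get(config, "start_zt", 6))
    counts[["fixtures"]] <- nrow(man)
  } else if (mode == "longterm") {
    idx <- read_sessions_index(cfg_get(config, "input_dir", required = TRUE))
    tau_rows <- list()
    bin_rows <- list()
    for (i in seq_len(nrow(idx))) {
      row <- idx[i, ]
      meta <- session_meta(mouse_id = row$mouse_id, condition = row$condition,
                           recording_start_zt = cfg_get(config, "start_zt", 6))
      rec <- load_recording(row$recording, meta = meta)
      if (row$condition == "fast") {
        est <- estimate_rise_tau(rec)
        tau_rows[[length(tau_rows) + 1L]] <-
          data.frame(mouse_id = row$mouse_id, condition = row$condition,
                     tau_h = est$tau_h,
                     tau_exp_h = tau_to_exponential(est$tau_h),
                     valid = est$valid)
      }
      pp <- preprocess_longterm(rec)
      ws <- window_summary(pp$z, hourly_zt_bins(meta))
      bin_rows[[length(bin_rows) + 1L]] <-
        cbind(data.frame(mouse_id = row$mouse_id, condition = row$condition),
              ws)
    }
    counts <- write_table(do.call(rbind, tau_rows), outdir, "tau_report.csv",
                          counts)
    counts <- write_table(do.call(rbind, bin_rows), outdir, "zt_bins.csv",
                          counts)
  } else if (mode == "food_response") {
    trials <- as.data.frame(cfg_get(config, "trials", required = TRUE))
    rows <- list()
    for (i in seq_len(nrow(trials))) {
      tr <- trials[i, ]
      meta <- session_meta(mouse_id = tr$mouse_id, condition = "fasted",
                           recording_start_zt = cfg_get(config, "start_zt", 6))
      rec <- load_recording(tr$recording, meta = meta)
      est <- estimate_fall_tau(rec, tr$drop_time)
      pp <- preprocess_trial(rec, tr$drop_time)
      ws <- window_summary(pp$z, pellet_windows(tr$drop_time))
      rows[[i]] <- data.frame(mouse_id = tr$mouse_id, tau_s = est$tau,
                              valid = est$valid,
                              pre3 = ws$value[ws$window == "pre3"],
                              post3 = ws$value[ws$window == "post3"],
                              post5 = ws$value[ws$window == "post5"])
    }
    counts <- write_table(do.call(rbind, rows), outdir, "trial_report.csv",
                          counts)
  } else if (mode == "operant") {
    idx <- read_sessions_index(cfg_get(config, "input_dir", required = TRUE))
    idx <- idx[!is.na(idx$events), , drop = FALSE]
    rate_rows <- list()
    aligned_rows <- list()
    decile_rows <- list()
    for (i in seq_len(nrow(idx))) {
      row <- idx[i, ]
      if (!file.exists(row$events))
        stop(sprintf("stage operant: events file missing: %s", row$events),
             call. = FALSE)
      ev <- load_events(row$events)
      meta <- session_meta(mouse_id = row$mouse_id, condition = row$condition,
                           recording_start_zt = cfg_get(config, "start_zt", 6))
      pr <- poke_rate(ev, session = c(0, max(ev$t_s)))
      rate_rows[[length(rate_rows) + 1L]] <-
        cbind(data.frame(mouse_id = row$mouse_id, condition = row$condition),
              pr)
      if (!is.na(row$recording) && row$condition == "fast") {
        rec <- load_recording(row$recording, meta = meta)
        fastw <- zt_window_seconds(12, 2, meta, t_max = max(rec$t))
        pokes <- refractory_filter(ev)
        pokes <- pokes[pokes > fastw[1] & pokes <= min(fastw[2], max(rec$t))]
        corrected <- motion_correct(rec, smooth = TRUE)
        al <- align_to_events(corrected, pokes,
                              group_keys = rep(row$mouse_id, length(pokes)))
        if (nrow(al$traces) > 0) {
          am <- aligned_mean(al)
          aligned_rows[[length(aligned_rows) + 1L]] <-
            cbind(data.frame(mouse_id = row$mouse_id), am)
          ds <- decile_split(al)
          for (dd in ds$presented_deciles)
            decile_rows[[length(decile_rows) + 1L]] <-
              data.frame(mouse_id = row$mouse_id, decile = dd,
                         rel_t = ds$rel_t, z = ds$decile_means[dd, ])
        }
      }
    }
    counts <- write_table(do.call(rbind, rate_rows), outdir, "poke_rate.csv",
                          counts)
    if (length(aligned_rows)) {
      counts <- write_table(do.call(rbind, aligned_rows), outdir,
                            "aligned_pokes.csv", counts)
      counts <- write_table(do.call(rbind, decile_rows), outdir,
                            "deciles.csv", counts)
    }
  } else if (mode == "contrast") {
    path <- cfg_get(config, "tau_report", required = TRUE)
    if (!file.exists(path))
      stop(sprintf("stage contrast: tau report not found: %s", path),
           call. = FALSE)
    rep_df <- read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(c("mouse_id", "condition", "tau_h") %in% names(rep_df)))
    summ <- data.frame(mouse_id = rep_df$mouse_id,
                       condition = rep_df$condition, value = rep_df$tau_h)
    cc <- condition_contrast(summ,
                             conditions = cfg_get(config, "conditions",
                                                  c("vehicle", "cno")))
    out <- rbind(cc$per_mouse,
                 data.frame(mouse_id = "GROUP_MEAN", diff = cc$mean))
    counts <- write_table(out, outdir, "contrast.csv", counts)
  } else {
    stop(sprintf("unknown pipeline mode `%s`", mode), call. = FALSE)
  }

  manifest <- list(package = "photofed",
                   version = as.character(packageVersion("photofed")),
                   config = config, seed = seed, counts = counts)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
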