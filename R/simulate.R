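# Synthetic-data generator: latent activity state, two-channel photometry
# with shared motion artifact and photobleaching, and FR1 operant sessions
# with an extinction burst when pellet delivery is paused. Ground truth is
# returned alongside every simulated object so each analysis stage can be
# verified end to end.

#' Simulate the noiseless latent activity state s(t)
#'
#' The state is the sum of a single-harmonic circadian term (cosine peaking
#' at `circadian_peak_zt`) and a condition term:
#' * `"ad_lib"` - circadian term only;
#' * `"fast"` - saturating-exponential rise
#'   `fast_rise_amplitude * (1 - exp(-(t - onset)/fast_rise_tau))` starting
#'   when food is removed at `fast_onset_zt`;
#' * `"food_presentation_trial"` - exponential fall of amplitude
#'   `food_fall_amplitude` and time constant `food_fall_tau` at the
#'   pellet-drop time.
#'
#' Optional spontaneous transients (amplitude > 0) are drawn as a Poisson
#' train (0.5 events/min) of exponentially decaying kicks; the output is
#' deterministic given all inputs including `seed`.
#'
#' @param params A [state_params()].
#' @param schedule Condition descriptor.
#' @param duration Recording duration, hours.
#' @param sample_rate Samples per second, Hz.
#' @param seed Integer seed (only consumed when transients are enabled).
#' @param start_zt ZT hour at recording start. Default 6.
#' @param event_time Pellet-drop time (seconds) for
#'   `"food_presentation_trial"`; default 180 s (3-minute baseline).
#' @return An object of class `latent_state`: list with `t` (seconds), `s`,
#'   `start_zt`, `sample_rate`, `schedule`, `params`, `event_time`.
#' @export
simulate_latent_state <- function(params = state_params(),
                                  schedule = c("ad_lib", "fast",
                                               "food_presentation_trial"),
                                  duration = 23, sample_rate = 1,
                                  seed = 1, start_zt = 6,
                                  event_time = 180) {
  stopifnot(inherits(params, "state_params"))
  schedule <- match.arg(schedule)
  if (!is.numeric(duration) || duration <= 0)
    stop_param("duration", "must be > 0")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop_param("sample_rate", "must be > 0")
  n <- floor(duration * 3600 * sample_rate) + 1L
  t <- (seq_len(n) - 1L) / sample_rate
  zt <- (start_zt + t / 3600) %% 24
  s <- params$circadian_amplitude *
    cos(2 * pi * (zt - params$circadian_peak_zt) / 24)
  if (schedule == "fast") {
    onset_s <- zt_to_seconds(params$fast_onset_zt, start_zt)
    after <- t >= onset_s
    s[after] <- s[after] + params$fast_rise_amplitude *
      (1 - exp(-(t[after] - onset_s) / (params$fast_rise_tau * 3600)))
  } else if (schedule == "food_presentation_trial") {
    after <- t >= event_time
    s[after] <- s[after] - params$food_fall_amplitude *
      (1 - exp(-(t[after] - event_time) / params$food_fall_tau))
  }
  if (params$transient_amplitude > 0) {
    set.seed(seed)
    n_tr <- rpois(1, 0.5 * duration * 60)  # fixed rate: 0.5 transients/min
    if (n_tr > 0) {
      t_tr <- sort(runif(n_tr, 0, duration * 3600))
      for (tt in t_tr) {
        after <- t >= tt
        s[after] <- s[after] + params$transient_amplitude *
          exp(-(t[after] - tt) / params$transient_decay)
      }
    }
  }
  structure(list(t = t, s = s, start_zt = start_zt,
                 sample_rate = sample_rate, schedule = schedule,
                 params = params,
                 event_time = if (schedule == "food_presentation_trial")
                   event_time else NULL),
            class = "latent_state")
}

#' Simulate a two-channel photometry recording from a latent state
#'
#' Acquisition model (time-division multiplexed dual excitation):
#' \deqn{ca(t) = B_{ca} \cdot bleach_{ca}(t) \cdot (1 + s(t)) + a(t) + \epsilon_{ca}(t)}
#' \deqn{iso(t) = B_{iso} \cdot bleach_{iso}(t) + g \cdot a(t) + \epsilon_{iso}(t)}
#' where `a(t)` is a zero-mean Ornstein-Uhlenbeck motion artifact with 1-s
#' correlation time, identical in waveform on both channels up to the gain
#' `g = artifact_gain_iso`, `bleach` is mono-exponential with the stated
#' half-life, and the white-noise terms are independent. The same seed
#' always yields the identical recording.
#'
#' @param state A `latent_state` from [simulate_latent_state()].
#' @param noise A [noise_params()].
#' @param seed Integer seed.
#' @param meta Optional [session_meta()]; a default is derived from the state.
#' @return List with `recording` (a `photo_recording`) and `ground_truth`
#'   (class `ground_truth`: parameters, seed, latent state trace, and the
#'   realized artifact waveform `a`).
#' @export
simulate_photometry <- function(state, noise = noise_params(), seed = 1,
                                meta = NULL) {
  stopifnot(inherits(state, "latent_state"), inherits(noise, "noise_params"))
  n <- length(state$t)
  if (n == 0L) stop("latent state trace is empty", call. = FALSE)
  t <- state$t
  dt <- if (n > 1L) t[2] - t[1] else 1
  set.seed(seed)
  # Ornstein-Uhlenbeck artifact, correlation time 1 s, stationary SD artifact_sd
  if (noise$artifact_sd > 0) {
    phi <- exp(-dt / 1)
    innov <- rnorm(n, 0, noise$artifact_sd * sqrt(1 - phi^2))
    innov[1] <- rnorm(1, 0, noise$artifact_sd)
    a <- as.numeric(stats::filter(innov, phi, method = "recursive"))
  } else a <- numeric(n)
  eps_ca <- if (noise$white_noise_sd > 0) rnorm(n, 0, noise$white_noise_sd)
            else numeric(n)
  eps_iso <- if (noise$white_noise_sd > 0) rnorm(n, 0, noise$white_noise_sd)
             else numeric(n)
  bleach_ca <- if (is.finite(noise$bleach_halflife_ca))
    0.5^(t / (noise$bleach_halflife_ca * 3600)) else rep(1, n)
  bleach_iso <- if (is.finite(noise$bleach_halflife_iso))
    0.5^(t / (noise$bleach_halflife_iso * 3600)) else rep(1, n)
  f_ca <- noise$baseline_ca * bleach_ca * (1 + state$s) + a + eps_ca
  f_iso <- noise$baseline_iso * bleach_iso + noise$artifact_gain_iso * a +
    eps_iso
  if (is.null(meta))
    meta <- session_meta(condition = state$schedule,
                         recording_start_zt = state$start_zt,
                         acquisition_rate_label =
                           sprintf("%g Hz", state$sample_rate))
  rec <- photo_recording(t, f_ca, f_iso, meta = meta,
                         sample_rate = state$sample_rate)
  truth <- structure(list(state = state$params, noise = noise,
                          behavior = NULL, seed = seed,
                          latent_state_trace = state$s, artifact = a,
                          schedule = state$schedule,
                          event_time = state$event_time,
                          start_zt = state$start_zt),
                     class = "ground_truth")
  list(recording = rec, ground_truth = truth)
}

# Inhomogeneous Poisson event times on [0, t_end] (rate in events/s) by
# thinning a homogeneous process at rate_max.
rpoisproc <- function(t_end, rate_fn, rate_max) {
  if (rate_max <= 0 || t_end <= 0) return(numeric(0))
  n <- rpois(1, rate_max * t_end)
  cand <- sort(runif(n, 0, t_end))
  keep <- runif(n) < rate_fn(cand) / rate_max
  cand[keep]
}

#' Simulate an FR1 operant session (FED3-style)
#'
#' Nose pokes are drawn from an inhomogeneous Poisson process. Under the
#' ad-libitum schedule every poke is followed by a `pellet_drop` and a
#' `pellet_retrieval` after an exponential delay (fixed-ratio 1). Under the
#' fasting schedule, inside the fast window pokes are logged but no pellet
#' events occur, and the poke intensity follows the extinction-burst law
#' `floor_rate + burst_rate * exp(-(t - fast_start)/extinction_tau)`.
#' `food_out` / `food_in` events mark the window boundaries.
#'
#' @param behavior A [behavior_params()].
#' @param schedule `"ad_lib"` or `"fast"`.
#' @param duration Session length, hours.
#' @param seed Integer seed.
#' @param start_zt ZT hour at session start. Default 6.
#' @param state_link Optional `latent_state` (recorded in the ground truth;
#'   behavior couples to the state only through the schedule).
#' @return List with `events` (an `event_log`) and `ground_truth`.
#' @export
simulate_operant_session <- function(behavior = behavior_params(),
                                     schedule = c("ad_lib", "fast"),
                                     duration = 23, seed = 1, start_zt = 6,
                                     state_link = NULL) {
  stopifnot(inherits(behavior, "behavior_params"))
  schedule <- match.arg(schedule)
  if (!is.numeric(duration) || duration <= 0)
    stop_param("duration", "must be > 0")
  t_end <- duration * 3600
  set.seed(seed)

  fast_s <- zt_window_seconds(behavior$fast_window[1], behavior$fast_window[2],
                              start_zt)
  fast_s[2] <- min(fast_s[2], t_end)
  in_fast <- function(tt) schedule == "fast" &
    tt >= fast_s[1] & tt <= fast_s[2]

  # Meal clusters elevate the ad-lib base rate 8-fold for 10 minutes.
  n_cl <- rpois(1, behavior$adlib_meal_cluster_rate * duration)
  cl_start <- sort(runif(n_cl, 0, t_end))
  in_cluster <- function(tt) {
    if (length(cl_start) == 0) return(rep(FALSE, length(tt)))
    i <- findInterval(tt, cl_start)
    i > 0 & (tt - cl_start[pmax(i, 1)]) <= 600
  }
  rate_fn <- function(tt) {  # pokes per second
    r <- ifelse(in_cluster(tt), 8 * behavior$adlib_poke_rate_base,
                behavior$adlib_poke_rate_base) / 60
    fast <- in_fast(tt)
    r[fast] <- (behavior$floor_rate + behavior$burst_rate *
                  exp(-(tt[fast] - fast_s[1]) /
                        (behavior$extinction_tau * 3600))) / 60
    r
  }
  rate_max <- max(8 * behavior$adlib_poke_rate_base,
                  behavior$floor_rate + behavior$burst_rate,
                  behavior$adlib_poke_rate_base) / 60
  pokes <- rpoisproc(t_end, rate_fn, rate_max)

  port <- sample(POKE_LABELS, length(pokes), replace = TRUE)
  times <- pokes
  labels <- port
  rewarded <- !in_fast(pokes)
  if (any(rewarded)) {
    drops <- pokes[rewarded]   # FR1: dispense logged with the poke
    retr <- drops + rexp(sum(rewarded), 1 / behavior$retrieval_delay_mean)
    times <- c(times, drops, retr)
    labels <- c(labels, rep("pellet_drop", length(drops)),
                rep("pellet_retrieval", length(retr)))
  }
  if (schedule == "fast" && fast_s[1] < t_end) {
    times <- c(times, fast_s[1])
    labels <- c(labels, "food_out")
    if (fast_s[2] < t_end) {
      times <- c(times, fast_s[2])
      labels <- c(labels, "food_in")
    }
  }
  keep <- times <= t_end
  events <- event_log(times[keep], labels[keep])
  truth <- structure(list(state = if (!is.null(state_link)) state_link$params,
                          noise = NULL, behavior = behavior, seed = seed,
                          schedule = schedule, start_zt = start_zt,
                          fast_window_s = if (schedule == "fast") fast_s,
                          n_pokes = length(pokes)),
                     class = "ground_truth")
  list(events = events, ground_truth = truth)
}

#' Simulate a complete session (photometry + behavior) and write it to disk
#'
#' Emits, per session, a recording CSV, an events CSV, and a ground-truth
#' JSON sidecar, in the dialects consumed by [load_recording()] and
#' [load_events()].
#'
#' @param dir Output directory (created if needed).
#' @param n_mice Number of mice.
#' @param preset Latent-state preset name (see [state_preset()]).
#' @param schedules Conditions simulated for every mouse.
#' @param duration,sample_rate Passed to [simulate_latent_state()].
#' @param noise A [noise_params()].
#' @param behavior A [behavior_params()] (operant logs are only written for
#'   `"ad_lib"` and `"fast"` schedules).
#' @param seed Integer base seed; per-session seeds are derived from it.
#' @param start_zt ZT hour at session start.
#' @param with_operant Also simulate and write FED3-style event logs.
#' @return Data frame manifest of written files (one row per session),
#'   invisibly.
#' @export
write_fixture_suite <- function(dir, n_mice = 3, preset = "agrp_fast",
                                schedules = c("ad_lib", "fast"),
                                duration = 23, sample_rate = 1,
                                noise = noise_params(sample_rate = 1),
                                behavior = behavior_params(),
                                seed = 1, start_zt = 6,
                                with_operant = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  params <- state_preset(preset)
  rows <- list()
  k <- 0L
  for (m in seq_len(n_mice)) {
    for (sched in schedules) {
      k <- k + 1L
      sseed <- (seed * 10007L + k * 131L) %% .Machine$integer.max
      st <- simulate_latent_state(params, schedule = sched,
                                  duration = duration,
                                  sample_rate = sample_rate,
                                  seed = sseed, start_zt = start_zt)
      meta <- session_meta(mouse_id = sprintf("m%02d", m), condition = sched,
                           recording_start_zt = start_zt)
      sim <- simulate_photometry(st, noise, seed = sseed, meta = meta)
      stem <- file.path(dir, sprintf("m%02d_%s", m, sched))
      write_recording(sim$recording, paste0(stem, "_recording.csv"))
      ev_path <- NA_character_
      if (with_operant && sched %in% c("ad_lib", "fast")) {
        op <- simulate_operant_session(behavior, schedule = sched,
                                       duration = duration, seed = sseed + 1L,
                                       start_zt = start_zt, state_link = st)
        ev_path <- paste0(stem, "_events.csv")
        write_events(op$events, ev_path)
      }
      truth <- list(mouse_id = meta$mouse_id, condition = sched,
                    start_zt = start_zt, seed = sseed, preset = preset,
                    state = unclass(params), noise = unclass(noise),
                    behavior = unclass(behavior))
      jsonlite::write_json(truth, paste0(stem, "_truth.json"),
                           auto_unbox = TRUE, digits = NA)
      rows[[k]] <- data.frame(mouse_id = meta$mouse_id, condition = sched,
                              recording = paste0(stem, "_recording.csv"),
                              events = ev_path,
                              truth = paste0(stem, "_truth.json"),
                              seed = sseed, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  idx <- manifest
  for (col in c("recording", "events", "truth"))
    idx[[col]] <- ifelse(is.na(idx[[col]]), NA, basename(idx[[col]]))
  write.csv(idx, file.path(dir, "sessions.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(manifest)
}
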