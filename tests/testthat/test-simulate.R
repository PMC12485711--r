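test_that("latent state obeys its closed forms", {
  # null model: all amplitudes zero
  p0 <- state_params(circadian_amplitude = 0, fast_rise_amplitude = 0,
                     food_fall_amplitude = 0)
  st <- simulate_latent_state(p0, "fast", duration = 2, sample_rate = 1)
  expect_true(all(st$s == 0))

  # saturating exponential: at one time constant past onset, 1 - 1/e
  p <- state_params(circadian_amplitude = 0, fast_rise_amplitude = 0.8,
                    fast_rise_tau = 1.0, fast_onset_zt = 12)
  st <- simulate_latent_state(p, "fast", duration = 12, sample_rate = 1,
                              start_zt = 6)
  at_zt13 <- st$s[st$t == zt_to_seconds(13, 6)]
  expect_equal(at_zt13, 0.8 * (1 - exp(-1)), tolerance = 1e-12)

  # circadian term peaks at the stated ZT hour
  pc <- state_params(circadian_amplitude = 0.2, fast_rise_amplitude = 0)
  stc <- simulate_latent_state(pc, "ad_lib", duration = 24, sample_rate = 1 / 60,
                               start_zt = 0)
  expect_equal(zt_at(stc$t[which.max(stc$s)], 0),
               pc$circadian_peak_zt, tolerance = 0.02)

  expect_error(simulate_latent_state(p, "fast", duration = -1), "duration")
  expect_error(simulate_latent_state(p, "fast", duration = 1, sample_rate = 0),
               "sample_rate")
})

test_that("presets carry the published calibration", {
  expect_equal(state_preset("agrp_fast")$fast_rise_tau, 1.78)
  expect_equal(state_preset("sim2_fast")$fast_rise_tau, 0.87)
  expect_equal(state_preset("food_trial")$food_fall_tau, 7.5)
})

test_that("photometry simulation is deterministic and respects the channel model", {
  st <- simulate_latent_state(state_preset("agrp_fast"), "fast",
                              duration = 1, sample_rate = 5)
  np <- noise_params(sample_rate = 5)
  a <- simulate_photometry(st, np, seed = 99)
  b <- simulate_photometry(st, np, seed = 99)
  expect_identical(a$recording$f_ca, b$recording$f_ca)
  expect_identical(a$recording$f_iso, b$recording$f_iso)

  # noise off, bleaching off, s = 0: calcium channel constant at baseline
  p0 <- state_params(circadian_amplitude = 0, fast_rise_amplitude = 0)
  st0 <- simulate_latent_state(p0, "ad_lib", duration = 0.1, sample_rate = 5)
  quiet <- noise_params(bleach_halflife_ca = Inf, bleach_halflife_iso = Inf,
                        artifact_sd = 0, white_noise_sd = 0, sample_rate = 5)
  sim0 <- simulate_photometry(st0, quiet, seed = 1)
  expect_true(all(sim0$recording$f_ca == quiet$baseline_ca))

  # channel-artifact contract: with white noise off, the artifact enters both
  # channels with the stated gains, exactly
  noisy <- noise_params(bleach_halflife_ca = Inf, bleach_halflife_iso = Inf,
                        artifact_sd = 0.05, artifact_gain_iso = 0.7,
                        white_noise_sd = 0, sample_rate = 5)
  st1 <- simulate_latent_state(state_preset("agrp_fast"), "fast",
                               duration = 0.5, sample_rate = 5)
  sim1 <- simulate_photometry(st1, noisy, seed = 2)
  art_ca <- sim1$recording$f_ca - noisy$baseline_ca * (1 + st1$s)
  art_iso <- (sim1$recording$f_iso - noisy$baseline_iso) / 0.7
  expect_equal(art_ca, art_iso, tolerance = 1e-12)
  expect_equal(art_ca, sim1$ground_truth$artifact, tolerance = 1e-12)

  # regression-validity regime at defaults: iso variance is artifact-dominated
  def <- noise_params(sample_rate = 1)
  st23 <- simulate_latent_state(state_preset("agrp_fast"), "ad_lib",
                                duration = 23, sample_rate = 1)
  trend <- def$baseline_iso * 0.5^(st23$t / (def$bleach_halflife_iso * 3600))
  expect_gt(def$artifact_sd^2, 10 * var(trend))
})

test_that("simulated pulse recovers through the correction + dF/F0 pipeline", {
  # square pulse of known amplitude; recovered within 10% at 1% white noise
  p <- state_params(circadian_amplitude = 0, fast_rise_amplitude = 0)
  st <- simulate_latent_state(p, "ad_lib", duration = 0.5, sample_rate = 10)
  pulse <- 0.4
  st$s[st$t >= 600 & st$t < 1200] <- pulse
  np <- noise_params(white_noise_sd = 0.01, sample_rate = 10)
  sim <- simulate_photometry(st, np, seed = 8)
  corrected <- motion_correct(sim$recording)
  d <- compute_dff(corrected, baseline = c(0, 500))
  est <- mean(d$y[d$t >= 650 & d$t < 1150]) - mean(d$y[d$t < 500])
  expect_lt(abs(est - pulse) / pulse, 0.1)
})

test_that("operant sessions implement FR1 and the fast-window pellet pause", {
  bp <- behavior_params()
  adlib <- simulate_operant_session(bp, "ad_lib", duration = 4, seed = 5)
  n_pokes <- sum(adlib$events$label %in% c("poke_left", "poke_right"))
  n_drops <- sum(adlib$events$label == "pellet_drop")
  expect_equal(n_drops, n_pokes)  # FR1: one pellet per poke

  # fast window covering the whole session: no pellet events at all
  bp_all <- behavior_params(fast_window = c(6, 5.99))
  fast <- simulate_operant_session(bp_all, "fast", duration = 4, seed = 5,
                                   start_zt = 6)
  expect_equal(sum(fast$events$label == "pellet_drop"), 0)

  # determinism
  a <- simulate_operant_session(bp, "fast", duration = 4, seed = 11)
  b <- simulate_operant_session(bp, "fast", duration = 4, seed = 11)
  expect_identical(a$events, b$events)
})

test_that("poke process is Poisson-like at constant rate", {
  # variance/mean ratio of counts in disjoint unit intervals near 1
  bp <- behavior_params(adlib_poke_rate_base = 2, adlib_meal_cluster_rate = 0)
  counts <- integer(0)
  for (k in 1:50) {
    s <- simulate_operant_session(bp, "ad_lib", duration = 1, seed = 1000 + k)
    tp <- event_times(s$events)
    counts <- c(counts, tabulate(findInterval(tp, seq(0, 3600, by = 300)), 12))
  }
  expect_length(counts, 600)
  ratio <- var(counts) / mean(counts)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
})

test_that("fasting produces an extinction burst that decays", {
  # Monte-Carlo check of the intensity law: hour 1 after fast onset busier
  # than hour 4
  bp <- behavior_params(burst_rate = 3, floor_rate = 0.05, extinction_tau = 1.5)
  h1 <- h4 <- numeric(200)
  for (k in 1:200) {
    s <- simulate_operant_session(bp, "fast", duration = 11, seed = 2000 + k,
                                  start_zt = 6)
    tp <- event_times(s$events)
    fs <- zt_to_seconds(12, 6)
    h1[k] <- sum(tp > fs & tp <= fs + 3600)
    h4[k] <- sum(tp > fs + 3 * 3600 & tp <= fs + 4 * 3600)
  }
  expect_gt(mean(h1), mean(h4))
  # and the hour-1 mean is near the integrated intensity
  expected_h1 <- 0.05 * 60 + 3 * 60 * 1.5 * (1 - exp(-1 / 1.5))
  expect_equal(mean(h1), expected_h1, tolerance = 0.1)
})

test_that("fixture suite writes paired files and an index", {
  dir <- withr::local_tempdir()
  man <- write_fixture_suite(dir, n_mice = 1, duration = 0.2, sample_rate = 2,
                             seed = 42)
  expect_equal(nrow(man), 2)
  expect_true(all(file.exists(man$recording)))
  expect_true(all(file.exists(man$truth)))
  expect_true(file.exists(file.path(dir, "sessions.csv")))
  rec <- load_recording(man$recording[1])
  expect_gt(length(rec$t), 100)
  truth <- jsonlite::read_json(man$truth[1])
  expect_equal(truth$preset, "agrp_fast")
})
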