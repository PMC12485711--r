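test_that("tau threshold crossing follows its closed forms", {
  # step trace: first sample at or past threshold is the step time
  t <- seq(0, 100, by = 0.5)
  y <- ifelse(t >= 40, 1, 0) + 1e-4 * sin(t)
  est <- estimate_tau(y, "rise", search_window = c(10, 100),
                      baseline_window = c(0, 10), ref_time = 10, t = t)
  expect_true(est$valid)
  expect_equal(est$tau_time, 40)

  # saturating exponential, T = 1 h over a 7 h window: analytic root 1.014 h
  th <- seq(-0.5, 7, by = 1 / 1000)
  y2 <- ifelse(th <= 0, 0, 1 - exp(-th))
  est2 <- estimate_tau(y2, "rise", search_window = c(0, 7) * 3600,
                       baseline_window = c(-0.5, 0) * 3600, ref_time = 0,
                       t = th * 3600)
  analytic <- -log(1 - 0.638 * (1 - exp(-7)))
  expect_equal(est2$tau / 3600, analytic, tolerance = 2e-3)
  expect_equal(analytic, 1.0145, tolerance = 1e-3)

  # falls mirror rises
  est3 <- estimate_tau(-y2, "fall", search_window = c(0, 7) * 3600,
                       baseline_window = c(-0.5, 0) * 3600, ref_time = 0,
                       t = th * 3600)
  expect_equal(est3$tau, est2$tau)

  # wrong-direction extremum: flagged invalid, no spurious time
  expect_warning(
    bad <- estimate_tau(-y2, "rise", search_window = c(0, 7) * 3600,
                        baseline_window = c(-0.5, 0) * 3600, t = th * 3600),
    "invalid")
  expect_false(bad$valid)
  expect_true(is.na(bad$tau))
})

test_that("tau is invariant to affine rescaling and matches a scan oracle", {
  set.seed(17)
  for (rep in 1:30) {
    t <- seq(0, 200, by = 1)
    y <- cumsum(abs(rnorm(length(t))))  # monotone rise
    frac <- runif(1, 0.2, 0.9)
    sw <- c(50, 200)
    bw <- c(0, 50)
    est <- estimate_tau(y, "rise", sw, bw, threshold_fraction = frac,
                        ref_time = 50, t = t)
    # brute-force scan oracle
    b <- mean(y[t > 0 & t <= 50])
    dev <- y[t > 50] - b
    thr <- frac * max(dev)
    oracle_t <- t[t > 50][which(dev >= thr)[1]]
    expect_equal(est$tau_time, oracle_t)
    # affine invariance: y -> a*y + c
    est2 <- estimate_tau(3.7 * y + 11, "rise", sw, bw,
                         threshold_fraction = frac, ref_time = 50, t = t)
    expect_equal(est2$tau_time, est$tau_time)
  }
})

test_that("threshold tau converts to the exponential time constant", {
  expect_equal(tau_to_exponential(1.0161), 1, tolerance = 1e-3)
  expect_equal(log(1 / (1 - 0.638)), 1.0161, tolerance = 1e-4)
})

test_that("fall tau of a simulated food trial matches the generator", {
  rec <- fall_trial_recording(drop_time = 180, tau = 7.5)
  est <- estimate_fall_tau(rec, drop_time = 180)
  expect_true(est$valid)
  # threshold crossing of a clean exponential: tau * 1.0164, sampled at 10 Hz
  expect_equal(est$tau, 7.5 * log(1 / (1 - 0.638)), tolerance = 0.05)
})

test_that("window summaries cover pellet windows and hourly ZT bins", {
  # piecewise constant around a pellet drop
  t <- seq(0, 1200, by = 0.5)
  y <- ifelse(t > 600, 1, 0)
  tr <- photo_trace(t, y, "z")
  ws <- window_summary(tr, pellet_windows(600))
  expect_equal(ws$value[ws$window == "pre3"], 0)
  expect_equal(ws$value[ws$window == "post3"], 1)
  expect_equal(ws$value[ws$window == "post5"], 1)

  # trace equal to the ZT hour index: hourly bin means are midpoints
  meta <- session_meta(recording_start_zt = 6)
  t2 <- seq(0, 23 * 3600, by = 60)
  tr2 <- photo_trace(t2, zt_at(t2, meta), "z", meta = meta)
  bins <- hourly_zt_bins(meta)
  expect_length(bins, 5)
  ws2 <- window_summary(tr2, bins)
  expect_equal(ws2$value, c(11.5, 12.5, 13.5, 14.5, 15.5), tolerance = 0.01)

  # constant trace: every window mean equals the constant
  tr3 <- photo_trace(t, rep(7, length(t)), "z")
  ws3 <- window_summary(tr3, pellet_windows(600))
  expect_true(all(ws3$value == 7))

  expect_warning(window_summary(tr, list(gone = c(5000, 6000))), "outside")
})

test_that("condition contrasts pair mice and drop unpaired ones", {
  s <- data.frame(mouse_id = c("m1", "m2", "m1", "m2"),
                  condition = c("vehicle", "vehicle", "cno", "cno"),
                  value = c(1, 2, 3, 3))
  cc <- condition_contrast(s)
  expect_equal(cc$per_mouse$diff, c(2, 1))
  expect_equal(cc$mean, 1.5)

  same <- data.frame(mouse_id = rep(c("a", "b"), 2),
                     condition = rep(c("vehicle", "cno"), each = 2),
                     value = c(4, 9, 4, 9))
  expect_equal(condition_contrast(same)$per_mouse$diff, c(0, 0))

  unpaired <- rbind(s, data.frame(mouse_id = "m3", condition = "vehicle",
                                  value = 9))
  expect_warning(cc2 <- condition_contrast(unpaired), "unpaired")
  expect_equal(cc2$n_mice, 2)
})

test_that("Holm-Sidak adjustment matches the textbook step-down oracle", {
  expect_equal(holm_sidak_adjust(0.03), 0.03)               # m = 1 unchanged
  expect_equal(holm_sidak_adjust(c(0.01, 0.04)),
               c(1 - (1 - 0.01)^2, 0.04), tolerance = 1e-12)
  expect_equal(holm_sidak_adjust(rep(1, 5)), rep(1, 5))
  expect_error(holm_sidak_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(23)
  for (rep in 1:300) {
    m <- sample(1:12, 1)
    p <- runif(m)
    adj <- holm_sidak_adjust(p)
    expect_equal(adj, holm_sidak_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))               # never below raw p
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))         # monotone when sorted
    # Sidak step-down is no more conservative than Holm-Bonferroni
    expect_true(all(adj <= p.adjust(p, "holm") + 1e-12))
  }
})
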