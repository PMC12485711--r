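# Shared fixture builders. Everything is generated in code; no data files.

# Tiny deterministic recording: gentle sine on both channels plus a linear
# relation so motion correction has structure to fit.
tiny_recording <- function(n = 100, start_zt = 6) {
  t <- seq_len(n) - 1
  iso <- 0.5 + 0.05 * sin(t / 7)
  ca <- 1 + 0.1 * sin(t / 7) + 0.02 * cos(t / 3)
  photo_recording(t, ca, iso, meta = session_meta(recording_start_zt = start_zt))
}

# Noise-free fall trial: baseline then exponential drop at drop_time, with a
# small deterministic ripple so per-window SDs are non-degenerate.
fall_trial_recording <- function(drop_time = 180, tau = 7.5, amp = 0.3,
                                 duration_s = 27 * 60, fs = 10) {
  t <- seq(0, duration_s, by = 1 / fs)
  s <- ifelse(t >= drop_time, -amp * (1 - exp(-(t - drop_time) / tau)), 0)
  ripple <- 1e-3 * sin(t * 2)
  photo_recording(t, 1 + s + ripple, rep(0.5, length(t)) + 1e-4 * cos(t),
                  meta = session_meta(condition = "fasted"))
}

# Brute-force oracles -------------------------------------------------------

# O(n * w) direct weighted average for the truncated Gaussian kernel.
gaussian_smooth_oracle <- function(y, window = 7, sigma = 1) {
  n <- length(y)
  h <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    js <- max(1, i - h):min(n, i + h)
    w <- exp(-0.5 * ((js - i) / sigma)^2)
    out[i] <- sum(w * y[js]) / sum(w)
  }
  out
}

# O(n^2) trailing mean over (t[i] - w_s, t[i]].
trailing_mean_oracle <- function(y, t, window_min) {
  w_s <- window_min * 60
  sapply(seq_along(t), function(i) {
    sel <- t > t[i] - w_s & t <= t[i]
    mean(y[sel])
  })
}

# O(n^2) all-pairs refractory filter.
refractory_oracle <- function(tp, refractory = 45) {
  tp <- sort(tp)
  keep <- vapply(seq_along(tp), function(i) {
    !any(tp > tp[i] - refractory & tp < tp[i])
  }, logical(1))
  tp[keep]
}

# Textbook step-down Holm-Sidak, written as an explicit loop.
holm_sidak_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    cand <- 1 - (1 - p[o[i]])^(m - i + 1)
    running <- max(running, cand)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Brute-force decile assignment by the ceiling-of-cumulative-percentage rule.
decile_oracle <- function(n) {
  vapply(seq_len(n), function(i) {
    d <- ceiling((100 * i / n) / 10)
    min(10, max(1, d))
  }, numeric(1))
}
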