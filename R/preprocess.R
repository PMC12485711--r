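# Normalization of raw two-channel recordings: Gaussian smoothing, motion
# correction by isosbestic regression, dF/F0, z-scoring, trailing mean.
#
# All baseline/analysis windows are half-open (start, end] in seconds on
# the recording time base; resolve ZT windows via zt_window_seconds().

#' Normalized single-channel trace
#'
#' @param t Seconds since recording start.
#' @param y Signal values (a.u. for `corrected`, dimensionless for `dff`/`z`).
#' @param kind One of `"corrected"`, `"dff"`, `"z"`.
#' @param baseline Baseline window `c(start, end)` in seconds (provenance),
#'   or `NULL`.
#' @param smoothing Character descriptor of smoothing applied (provenance).
#' @param meta Optional [session_meta()] carried over from the recording.
#' @return An object of class `photo_trace`.
#' @export
photo_trace <- function(t, y, kind = c("corrected", "dff", "z"),
                        baseline = NULL, smoothing = "none", meta = NULL) {
  kind <- match.arg(kind)
  if (length(t) != length(y)) stop("t and y must have equal length",
                                   call. = FALSE)
  structure(list(t = as.numeric(t), y = as.numeric(y), kind = kind,
                 baseline = baseline, smoothing = smoothing, meta = meta),
            class = "photo_trace")
}

#' @export
print.photo_trace <- function(x, ...) {
  cat(sprintf("<photo_trace:%s> %d samples, %.3g h, smoothing=%s\n",
              x$kind, length(x$t), diff(range(x$t)) / 3600, x$smoothing))
  invisible(x)
}

# Indices of samples with t in (window[1], window[2]].
window_idx <- function(t, window) {
  which(t > window[1] & t <= window[2])
}

#' Gaussian smoothing with a truncated, renormalized kernel
#'
#' Discrete Gaussian kernel of `window` samples (odd), weights renormalized
#' to sum to 1 after truncation. Edges are handled by renormalizing over the
#' samples actually available (no padding).
#'
#' @param y Numeric samples.
#' @param window Kernel width in samples (odd, >= 1). Default 7.
#' @param sigma Kernel SD in samples. Default 1.
#' @return Smoothed samples, same length as `y`.
#' @export
gaussian_smooth <- function(y, window = 7, sigma = 1) {
  n <- length(y)
  if (window < 1 || window %% 2 != 1)
    stop("window must be odd and >= 1", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (window > n) stop("window is longer than the trace", call. = FALSE)
  h <- (window - 1L) / 2L
  k <- exp(-0.5 * ((-h:h) / sigma)^2)
  num <- numeric(n)
  den <- numeric(n)
  for (j in -h:h) {
    w <- k[j + h + 1L]
    src <- seq.int(max(1L, 1L - j), min(n, n - j))
    dst <- src + j
    num[dst] <- num[dst] + w * y[src]
    den[dst] <- den[dst] + w
  }
  num / den
}

#' Motion correction against the isosbestic channel
#'
#' Predicts the calcium-dependent (465 nm) signal from the calcium-independent
#' (405 nm) signal by ordinary least squares over the whole recording,
#' subtracts the prediction, and adds back the mean 465 nm signal:
#' `corrected = f_ca - (a + b * f_iso) + mean(f_ca)`. The corrected trace has
#' exactly the same mean as the raw calcium channel.
#'
#' If the isosbestic channel has zero variance the fit degenerates; the
#' function falls back to returning the calcium channel unchanged, with a
#' warning.
#'
#' @param rec A `photo_recording` (length >= 3).
#' @param smooth Apply [gaussian_smooth()] to both channels before the
#'   regression (the convention for short trials). Default `FALSE`.
#' @param window,sigma Smoothing parameters when `smooth = TRUE`.
#' @return A `photo_trace` of kind `"corrected"`.
#' @export
motion_correct <- function(rec, smooth = FALSE, window = 7, sigma = 1) {
  stopifnot(inherits(rec, "photo_recording"))
  if (length(rec$t) < 3L) stop("recording too short for motion correction",
                               call. = FALSE)
  f_ca <- rec$f_ca
  f_iso <- rec$f_iso
  smoothing <- "none"
  if (smooth) {
    f_ca <- gaussian_smooth(f_ca, window, sigma)
    f_iso <- gaussian_smooth(f_iso, window, sigma)
    smoothing <- sprintf("gaussian(window=%d,sigma=%g)", window, sigma)
  }
  m_ca <- mean(f_ca)
  m_iso <- mean(f_iso)
  sxx <- sum((f_iso - m_iso)^2)
  if (sxx == 0) {
    warning("isosbestic channel has zero variance; motion correction skipped",
            call. = FALSE)
    corrected <- f_ca
  } else {
    b <- sum((f_iso - m_iso) * (f_ca - m_ca)) / sxx
    a <- m_ca - b * m_iso
    corrected <- f_ca - (a + b * f_iso) + m_ca
  }
  photo_trace(rec$t, corrected, "corrected", smoothing = smoothing,
              meta = rec$meta)
}

# Resolve (trace-or-vector, t) argument pair into a list(t, y, meta, smoothing)
as_ty <- function(x, t) {
  if (inherits(x, "photo_trace"))
    list(t = x$t, y = x$y, meta = x$meta, smoothing = x$smoothing,
         kind = x$kind)
  else {
    if (is.null(t)) stop("t must be supplied when x is a plain vector",
                         call. = FALSE)
    list(t = as.numeric(t), y = as.numeric(x), meta = NULL,
         smoothing = "none", kind = "corrected")
  }
}

#' Fractional fluorescence change (dF/F0)
#'
#' `(F - F0) / F0` at each time point, with `F0` the mean over the baseline
#' window. Typical baselines: 3 minutes to 10 seconds before pellet drop for
#' short trials; ZT6-ZT9 for day-long recordings (ZT3-ZT6 when fasting starts
#' at ZT6).
#'
#' @param x A `photo_trace` or numeric samples.
#' @param baseline Window `c(start, end)` seconds, half-open `(start, end]`;
#'   must contain at least 2 samples.
#' @param t Sample times (seconds), required when `x` is a plain vector.
#' @return A `photo_trace` of kind `"dff"` carrying baseline provenance.
#' @export
compute_dff <- function(x, baseline, t = NULL) {
  d <- as_ty(x, t)
  idx <- window_idx(d$t, baseline)
  if (length(idx) < 2L) stop("baseline window contains fewer than 2 samples",
                             call. = FALSE)
  f0 <- mean(d$y[idx])
  if (f0 == 0) stop("baseline mean F0 is zero; dF/F0 undefined", call. = FALSE)
  photo_trace(d$t, (d$y - f0) / f0, "dff", baseline = baseline,
              smoothing = d$smoothing, meta = d$meta)
}

#' Baseline z-score of a dF/F0 trace (z dF/F0)
#'
#' `(F - M) / S` with `M`, `S` the mean and sample standard deviation
#' (n - 1 denominator) of the signal over the baseline window.
#'
#' @inheritParams compute_dff
#' @return A `photo_trace` of kind `"z"`.
#' @export
compute_zscore <- function(x, baseline, t = NULL) {
  d <- as_ty(x, t)
  idx <- window_idx(d$t, baseline)
  if (length(idx) < 2L) stop("baseline window contains fewer than 2 samples",
                             call. = FALSE)
  m <- mean(d$y[idx])
  s <- sd(d$y[idx])
  if (s == 0) stop("degenerate baseline: zero standard deviation in window",
                   call. = FALSE)
  photo_trace(d$t, (d$y - m) / s, "z", baseline = baseline,
              smoothing = d$smoothing, meta = d$meta)
}

#' Trailing (rolling) mean over a time window preceding each sample
#'
#' `out[i]` is the mean of samples with `t` in `(t[i] - window, t[i]]`.
#' Early samples with incomplete history use the shrinking available window,
#' so day-long summaries are defined from `t = 0`.
#'
#' @param x A `photo_trace` or numeric samples.
#' @param window Window length in minutes. Default 30.
#' @param t Sample times (seconds), required when `x` is a plain vector.
#' @return Same type as the input (`photo_trace` in, `photo_trace` out).
#' @export
trailing_mean <- function(x, window = 30, t = NULL) {
  if (window <= 0) stop("window must be > 0", call. = FALSE)
  d <- as_ty(x, t)
  w_s <- window * 60
  n <- length(d$t)
  cs <- cumsum(d$y)
  # first index j with t[j] > t[i] - w_s  (half-open window)
  j0 <- findInterval(d$t - w_s, d$t) + 1L
  i <- seq_len(n)
  prev <- numeric(n)
  prev[j0 > 1L] <- cs[j0[j0 > 1L] - 1L]
  out <- (cs - prev) / (i - j0 + 1L)
  if (inherits(x, "photo_trace"))
    photo_trace(d$t, out, x$kind, baseline = x$baseline,
                smoothing = paste0(d$smoothing, "+trailing_mean(",
                                   window, "min)"),
                meta = d$meta)
  else out
}

#' Standard preprocessing for a short food-presentation trial
#'
#' Smooths both channels (Gaussian, window 7, sigma 1), motion-corrects,
#' computes dF/F0 and z dF/F0 against the pre-drop baseline
#' (3 minutes to 10 seconds before pellet drop).
#'
#' @param rec A `photo_recording`.
#' @param drop_time Pellet-drop time, seconds.
#' @param baseline Baseline window relative to `drop_time`; default
#'   `c(-180, -10)`.
#' @return List with `corrected`, `dff`, `z` traces and the absolute
#'   baseline window used.
#' @export
preprocess_trial <- function(rec, drop_time, baseline = c(-180, -10)) {
  corrected <- motion_correct(rec, smooth = TRUE)
  bl <- drop_time + baseline
  dff <- compute_dff(corrected, bl)
  z <- compute_zscore(dff, bl)
  list(corrected = corrected, dff = dff, z = z, baseline = bl)
}

#' Standard preprocessing for a day-long recording
#'
#' Motion correction, dF/F0 against the ZT6-ZT9 baseline (ZT3-ZT6 when
#' fasting starts at ZT6), a 30-minute trailing mean to isolate slow
#' dynamics, then z-scoring of the smoothed signal against the same window.
#'
#' @param rec A `photo_recording` whose `meta` anchors ZT.
#' @param fast_onset_zt ZT hour of food removal (used only to pick the
#'   ZT3-ZT6 baseline when fasting starts at ZT6); `NULL` for ad-lib.
#' @param trailing_window Trailing-mean window, minutes. Default 30.
#' @return List with `corrected`, `dff`, `smoothed`, `z` traces, the
#'   absolute baseline window, and `trailing_window`.
#' @export
preprocess_longterm <- function(rec, fast_onset_zt = NULL,
                                trailing_window = 30) {
  meta <- rec$meta
  bl_zt <- if (!is.null(fast_onset_zt) && fast_onset_zt == 6) c(3, 6) else c(6, 9)
  t_max <- max(rec$t)
  bl <- zt_window_seconds(bl_zt[1], bl_zt[2], meta, t_max = t_max)
  corrected <- motion_correct(rec, smooth = FALSE)
  dff <- compute_dff(corrected, bl)
  smoothed <- trailing_mean(dff, window = trailing_window)
  z <- compute_zscore(smoothed, bl)
  list(corrected = corrected, dff = dff, smoothed = smoothed, z = z,
       baseline = bl, trailing_window = trailing_window)
}
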