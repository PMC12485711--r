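# Quantification of state transitions: threshold-crossing time-constant
# estimation for activity falls (food presentation) and rises (food
# removal), fixed-window summaries, hourly ZT bins, paired condition
# contrasts, and the Holm-Sidak step-down adjustment.

#' Threshold-crossing time constant of an activity rise or fall
#'
#' Within the search window the extremum of the baseline-subtracted signal
#' is located (maximum for rises, minimum for falls), and tau is the
#' earliest sample time at which `threshold_fraction` (default 0.638, the
#' printed convention; configurable) of that extremum has occurred. Tau is
#' reported relative to `ref_time` (food-presentation time for falls; fast
#' onset for rises). The estimate is invariant to affine rescaling of the
#' trace because both the extremum and the threshold are baseline-relative.
#'
#' Standard windows: falls are searched from 30 s before to 5 min after
#' food presentation with the pre-drop dF/F0 baseline; rises are searched
#' from ZT11 to ZT18 against the mean signal from ZT11 to ZT12, and
#' reported relative to ZT12 (fast onset).
#'
#' If the trace has been low-pass filtered (e.g. the 30-min trailing mean
#' of long recordings), the crossing time inherits the filter's group
#' delay; pass `filter_delay` (seconds) to subtract it so tau refers to the
#' underlying signal. For a trailing mean this delay is half the window.
#'
#' @param trace A `photo_trace` (or numeric samples with `t` supplied).
#' @param direction `"rise"` or `"fall"`.
#' @param search_window Window `c(start, end)` seconds in which the
#'   extremum and crossing are sought.
#' @param baseline_window Window `c(start, end)` seconds defining the
#'   reference level; must precede the extremum search.
#' @param threshold_fraction Fraction of the extremum defining the
#'   crossing. Default 0.638.
#' @param ref_time Time (seconds) tau is reported relative to. Defaults to
#'   `search_window[1]`.
#' @param filter_delay Known group delay of any smoothing applied to the
#'   trace, seconds, subtracted from the crossing time. Default 0.
#' @param t Sample times when `trace` is a plain vector.
#' @return Object of class `tau_estimate`: `tau` (seconds relative to
#'   `ref_time`), `tau_time` (absolute crossing time), `direction`,
#'   `threshold_fraction`, `extremum_value`, `extremum_time`,
#'   `baseline_value`, `search_window`, `valid`.
#' @export
estimate_tau <- function(trace, direction = c("rise", "fall"),
                         search_window, baseline_window,
                         threshold_fraction = 0.638, ref_time = NULL,
                         filter_delay = 0, t = NULL) {
  direction <- match.arg(direction)
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must lie in (0, 1)", call. = FALSE)
  d <- as_ty(trace, t)
  if (is.null(ref_time)) ref_time <- search_window[1]
  bidx <- window_idx(d$t, baseline_window)
  if (length(bidx) == 0L) stop("baseline window contains no samples",
                               call. = FALSE)
  sidx <- window_idx(d$t, search_window)
  if (length(sidx) == 0L) stop("search window contains no samples",
                               call. = FALSE)
  b <- mean(d$y[bidx])
  dev <- d$y[sidx] - b
  if (direction == "rise") {
    ext_i <- which.max(dev)
    valid <- dev[ext_i] > 0
  } else {
    ext_i <- which.min(dev)
    valid <- dev[ext_i] < 0
  }
  ext <- dev[ext_i]
  out <- list(tau = NA_real_, tau_time = NA_real_, direction = direction,
              threshold_fraction = threshold_fraction,
              extremum_value = ext, extremum_time = d$t[sidx][ext_i],
              baseline_value = b, search_window = search_window,
              valid = valid)
  if (valid) {
    thr <- threshold_fraction * ext
    hit <- if (direction == "rise") dev >= thr else dev <= thr
    k <- which(hit)[1]
    out$tau_time <- d$t[sidx][k]
    out$tau <- out$tau_time - ref_time - filter_delay
  } else {
    warning(sprintf("no %s detected in search window; tau estimate invalid",
                    direction), call. = FALSE)
  }
  structure(out, class = "tau_estimate")
}

#' @export
print.tau_estimate <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<tau_estimate:%s> tau = %.4g s (%.4g h), extremum %.3g at t=%.4g s\n",
                x$direction, x$tau, x$tau / 3600, x$extremum_value,
                x$extremum_time))
  else
    cat(sprintf("<tau_estimate:%s> invalid (no %s in search window)\n",
                x$direction, x$direction))
  invisible(x)
}

#' Convert a threshold-crossing tau to an exponential time constant
#'
#' For a saturating exponential observed over a long window, the
#' threshold-crossing time at fraction `f` equals `T * ln(1/(1-f))`; for
#' `f = 0.638` the factor is about 1.016. This inverts that relation.
#'
#' @param tau Threshold-crossing tau (any time unit).
#' @param threshold_fraction Fraction used for the crossing. Default 0.638.
#' @return Exponential time constant in the same unit.
#' @export
tau_to_exponential <- function(tau, threshold_fraction = 0.638) {
  tau / log(1 / (1 - threshold_fraction))
}

#' Rise time constant of a day-long fasting recording
#'
#' Applies the long-recording pipeline ([preprocess_longterm()]) and
#' estimates the rise tau: search window ZT11-ZT18, baseline ZT11-ZT12,
#' reported in hours relative to fast onset (ZT12). The group delay of the
#' 30-min trailing mean (half the window) is subtracted so tau refers to
#' the underlying activity change.
#'
#' @param rec A `photo_recording` (day-long, meta anchors ZT).
#' @param fast_onset_zt ZT hour of food removal. Default 12.
#' @param search_zt,baseline_zt Search / baseline windows, ZT hours.
#' @param threshold_fraction Passed to [estimate_tau()].
#' @param trailing_window Trailing-mean window, minutes. Default 30.
#' @return A `tau_estimate` with an extra field `tau_h` (tau in hours).
#' @export
estimate_rise_tau <- function(rec, fast_onset_zt = 12,
                              search_zt = c(11, 18), baseline_zt = c(11, 12),
                              threshold_fraction = 0.638,
                              trailing_window = 30) {
  pp <- preprocess_longterm(rec, trailing_window = trailing_window)
  meta <- rec$meta
  t_max <- max(rec$t)
  sw <- zt_window_seconds(search_zt[1], search_zt[2], meta, t_max = t_max)
  bw <- zt_window_seconds(baseline_zt[1], baseline_zt[2], meta, t_max = t_max)
  ref <- zt_to_seconds(fast_onset_zt, meta)
  est <- estimate_tau(pp$z, "rise", search_window = sw, baseline_window = bw,
                      threshold_fraction = threshold_fraction,
                      ref_time = ref, filter_delay = trailing_window * 60 / 2)
  est$tau_h <- est$tau / 3600
  est
}

#' Fall time constant of a short food-presentation trial
#'
#' Applies the short-trial pipeline ([preprocess_trial()]) and estimates
#' the fall tau in the standard window (30 s before to 5 min after food
#' presentation), relative to the pre-drop baseline, reported in seconds
#' from pellet presentation.
#'
#' @param rec A `photo_recording` of a short trial.
#' @param drop_time Pellet-presentation time, seconds.
#' @param threshold_fraction Passed to [estimate_tau()].
#' @return A `tau_estimate` (tau in seconds).
#' @export
estimate_fall_tau <- function(rec, drop_time, threshold_fraction = 0.638) {
  pp <- preprocess_trial(rec, drop_time)
  estimate_tau(pp$z, "fall",
               search_window = drop_time + c(-30, 300),
               baseline_window = pp$baseline,
               threshold_fraction = threshold_fraction,
               ref_time = drop_time)
}

#' Mean trace value in named windows
#'
#' @param trace A `photo_trace`.
#' @param windows Named list of `c(start, end)` windows in seconds
#'   (half-open `(start, end]`).
#' @return Data frame with `window`, `value`, `n_samples`; windows outside
#'   the recording yield `NA` with a warning.
#' @export
window_summary <- function(trace, windows) {
  stopifnot(inherits(trace, "photo_trace"))
  vals <- vapply(windows, function(w) {
    idx <- window_idx(trace$t, w)
    if (length(idx) == 0L) NA_real_ else mean(trace$y[idx])
  }, numeric(1))
  ns <- vapply(windows, function(w) length(window_idx(trace$t, w)),
               integer(1))
  if (any(is.na(vals)))
    warning(sprintf("window(s) outside recording: %s",
                    paste(names(windows)[is.na(vals)], collapse = ", ")),
            call. = FALSE)
  data.frame(window = names(windows), value = vals, n_samples = ns,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hourly ZT bin windows
#'
#' The standard registry for food-removal responses: 1-hour bins
#' `[ZT11,12), ..., [ZT15,16)` (5 bins from ZT11 to ZT16), resolved on the
#' recording clock.
#'
#' @param meta A [session_meta()] (or starting ZT hour).
#' @param from,to First and last ZT hour. Defaults 11 and 16.
#' @return Named list of `c(start, end)` windows in seconds.
#' @export
hourly_zt_bins <- function(meta, from = 11, to = 16) {
  hours <- seq(from, to - 1)
  wins <- lapply(hours, function(h) zt_window_seconds(h, h + 1, meta))
  names(wins) <- sprintf("ZT%g-%g", hours, hours + 1)
  wins
}

#' Pellet-drop window registry
#'
#' `pre3`/`post3`: mean in the 3 minutes before/after pellet drop;
#' `post5`: mean in the 5 minutes after.
#'
#' @param drop_time Pellet-drop time, seconds.
#' @return Named list of windows in seconds.
#' @export
pellet_windows <- function(drop_time) {
  list(pre3 = drop_time + c(-180, 0),
       post3 = drop_time + c(0, 180),
       post5 = drop_time + c(0, 300))
}

#' Paired condition contrast per mouse
#'
#' Computes per-mouse paired differences of a metric (e.g. tau) between two
#' conditions (`conditions[2] - conditions[1]`, e.g. CNO minus vehicle),
#' then the mean and SEM across mice. Mice missing either condition are
#' dropped with a warning.
#'
#' @param summaries Data frame with columns `mouse_id`, `condition`,
#'   `value` (one row per mouse x condition; replicate rows are averaged
#'   within mouse first).
#' @param conditions Character vector of the two condition labels, ordered
#'   `c(reference, treatment)`.
#' @return List with `per_mouse` (data frame `mouse_id`, `diff`), `mean`,
#'   `sem`, `n_mice`.
#' @export
condition_contrast <- function(summaries,
                               conditions = c("vehicle", "cno")) {
  stopifnot(all(c("mouse_id", "condition", "value") %in% names(summaries)))
  if (length(conditions) != 2L)
    stop("conditions must name exactly two condition labels", call. = FALSE)
  s <- summaries[summaries$condition %in% conditions, , drop = FALSE]
  agg <- stats::aggregate(value ~ mouse_id + condition, data = s, FUN = mean)
  wide <- stats::reshape(agg, idvar = "mouse_id", timevar = "condition",
                         direction = "wide")
  ref_col <- paste0("value.", conditions[1])
  trt_col <- paste0("value.", conditions[2])
  for (col in c(ref_col, trt_col))
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  paired <- !is.na(wide[[ref_col]]) & !is.na(wide[[trt_col]])
  if (any(!paired))
    warning(sprintf("dropped unpaired mouse/mice: %s",
                    paste(wide$mouse_id[!paired], collapse = ", ")),
            call. = FALSE)
  wide <- wide[paired, , drop = FALSE]
  if (nrow(wide) == 0L) stop("no paired mice", call. = FALSE)
  d <- wide[[trt_col]] - wide[[ref_col]]
  list(per_mouse = data.frame(mouse_id = wide$mouse_id, diff = d,
                              row.names = NULL),
       mean = mean(d),
       sem = if (length(d) > 1) sd(d) / sqrt(length(d)) else NA_real_,
       n_mice = length(d))
}

#' Holm-Sidak step-down adjustment of p-values
#'
#' Sorts the m p-values ascending and sets adjusted
#' `p_(i) = max_{j <= i} (1 - (1 - p_(j))^(m - j + 1))`, returned in the
#' original order and capped at 1. Adjusted values are monotone in the
#' sorted order and never below the raw p-values.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
holm_sidak_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
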