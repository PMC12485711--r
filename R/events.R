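# Event-locked analysis: refractory filtering of pokes, alignment of
# normalized traces to events, per-mouse averaging, poke rates, decile
# progression through the fast period, and feeding-phase windows.

#' Refractory filter for poke events
#'
#' Keeps an event `e` iff no event with a poke label (either port) occurs in
#' the open interval `(e - refractory, e)`. The test is against all pokes,
#' not only previously kept ones.
#'
#' @param events An `event_log` or a numeric vector of poke times.
#' @param labels Poke labels considered. Default both ports.
#' @param refractory Refractory period, seconds. Default 45.
#' @return Sorted numeric vector of kept event times.
#' @export
refractory_filter <- function(events, labels = POKE_LABELS, refractory = 45) {
  if (refractory < 0) stop("refractory must be >= 0", call. = FALSE)
  tp <- if (inherits(events, "event_log")) event_times(events, labels)
        else sort(as.numeric(events))
  n <- length(tp)
  if (n == 0L) return(numeric(0))
  # j = first index with tp[j] > tp[i] - refractory (open left end)
  j <- findInterval(tp - refractory, tp) + 1L
  i <- seq_len(n)
  # drop iff some strictly earlier poke lies in the window; since tp is
  # sorted, that is equivalent to tp[j] < tp[i] with j <= i - 1
  drop <- j <= i - 1L & tp[pmin(j, i)] < tp
  tp[!drop]
}

#' Event-locked set of trace snippets on a shared relative-time grid
#'
#' Each snippet is cut from the (motion-corrected, Gaussian-smoothed) trace
#' from `pre` seconds before to `post` seconds after the event, then
#' independently re-normalized (dF/F0 followed by z-score) against its own
#' pre-event baseline window. Events whose window is not fully covered by
#' the recording, or whose baseline is degenerate (zero SD), are excluded
#' with a reported count.
#'
#' @param trace A `photo_trace` (typically kind `"corrected"`).
#' @param event_times Event times, seconds.
#' @param pre,post Window extent before/after each event, seconds.
#'   Defaults 45 and 100.
#' @param baseline Per-event baseline window relative to the event,
#'   half-open; default `c(-45, -1)` (45 s to 1 s before the event).
#' @param group_keys Optional per-event grouping keys (e.g. mouse IDs),
#'   recycled to the number of events.
#' @param normalize Re-normalize each snippet (`TRUE`, default) or keep raw
#'   snippet values.
#' @return An object of class `aligned_set`: `rel_t`, `traces` (matrix,
#'   events x samples), `event_times`, `group_keys`, `window`,
#'   `per_event_baseline`, `n_input`, `n_excluded`, `n_degenerate`.
#' @export
align_to_events <- function(trace, event_times, pre = 45, post = 100,
                            baseline = c(-45, -1), group_keys = NULL,
                            normalize = TRUE) {
  stopifnot(inherits(trace, "photo_trace"))
  if (pre <= 0 || post <= 0) stop("pre and post must be > 0", call. = FALSE)
  t <- trace$t
  y <- trace$y
  dt <- median(diff(t))
  n_pre <- round(pre / dt)
  n_post <- round(post / dt)
  rel_t <- (-n_pre:n_post) * dt
  n_ev <- length(event_times)
  keys <- if (is.null(group_keys)) rep("all", n_ev)
          else rep_len(as.character(group_keys), n_ev)

  rows <- list()
  kept_t <- numeric(0)
  kept_k <- character(0)
  n_excluded <- 0L
  n_degenerate <- 0L
  for (e in seq_len(n_ev)) {
    ev <- event_times[e]
    i0 <- findInterval(ev, t)  # nearest sample to the event
    if (i0 >= 1L && i0 < length(t) &&
        abs(t[i0 + 1L] - ev) < abs(t[i0] - ev))
      i0 <- i0 + 1L
    lo <- i0 - n_pre
    hi <- i0 + n_post
    if (i0 < 1L || lo < 1L || hi > length(t)) {
      n_excluded <- n_excluded + 1L
      next
    }
    snip <- y[lo:hi]
    if (normalize) {
      idx <- which(rel_t > baseline[1] & rel_t <= baseline[2])
      f0 <- mean(snip[idx])
      if (length(idx) < 2L || f0 == 0) {
        n_degenerate <- n_degenerate + 1L
        next
      }
      d <- (snip - f0) / f0
      m <- mean(d[idx])
      s <- sd(d[idx])
      if (s == 0) {
        n_degenerate <- n_degenerate + 1L
        next
      }
      snip <- (d - m) / s
    }
    rows[[length(rows) + 1L]] <- snip
    kept_t <- c(kept_t, ev)
    kept_k <- c(kept_k, keys[e])
  }
  if (n_degenerate > 0L)
    warning(sprintf("%d event(s) excluded for degenerate per-event baseline",
                    n_degenerate), call. = FALSE)
  traces <- if (length(rows)) do.call(rbind, rows)
            else matrix(numeric(0), nrow = 0, ncol = length(rel_t))
  structure(list(rel_t = rel_t, traces = traces, event_times = kept_t,
                 group_keys = kept_k, window = c(pre = pre, post = post),
                 per_event_baseline = baseline, n_input = n_ev,
                 n_excluded = n_excluded, n_degenerate = n_degenerate),
            class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("<aligned_set> %d/%d events kept (%d window-excluded, %d degenerate), window -%gs..+%gs\n",
              nrow(x$traces), x$n_input, x$n_excluded, x$n_degenerate,
              x$window["pre"], x$window["post"]))
  invisible(x)
}

#' Mean +/- SEM of an aligned set
#'
#' By default events are pooled across mice (the convention for poke-aligned
#' traces: mean over all pokes from all mice). `by = "mouse"` instead
#' averages within mouse first and computes the SEM across mice.
#'
#' @param aligned An `aligned_set`.
#' @param by `"pooled"` (default) or `"mouse"`.
#' @return Data frame with `rel_t`, `mean`, `sem`, `n`.
#' @export
aligned_mean <- function(aligned, by = c("pooled", "mouse")) {
  by <- match.arg(by)
  if (nrow(aligned$traces) == 0L)
    stop("aligned set is empty; nothing to summarize", call. = FALSE)
  m <- aligned$traces
  if (by == "mouse") {
    groups <- split(seq_len(nrow(m)), aligned$group_keys)
    m <- do.call(rbind, lapply(groups, function(i)
      colMeans(m[i, , drop = FALSE])))
  }
  n <- nrow(m)
  mu <- colMeans(m)
  sem <- if (n > 1) apply(m, 2, sd) / sqrt(n) else rep(NA_real_, ncol(m))
  data.frame(rel_t = aligned$rel_t, mean = mu, sem = sem, n = n)
}

#' Two-stage (per-mouse, then group) averaging
#'
#' Averages trial values within each mouse, then across mice, so that group
#' statistics are on a per-mouse basis. The SEM uses the number of mice.
#' With a single mouse the SEM is reported as `NA` (absent).
#'
#' @param values Numeric vector of per-trial values (or a matrix with one
#'   row per trial, e.g. trial traces).
#' @param mouse_id Per-trial mouse identifiers.
#' @return List with `per_mouse` (named means, or matrix), `mean`, `sem`,
#'   `n_mice`.
#' @export
pool_and_average <- function(values, mouse_id) {
  if (is.matrix(values)) {
    stopifnot(nrow(values) == length(mouse_id))
    groups <- split(seq_len(nrow(values)), mouse_id)
    per <- do.call(rbind, lapply(groups, function(i)
      colMeans(values[i, , drop = FALSE])))
    n <- nrow(per)
    mu <- colMeans(per)
    sem <- if (n > 1) apply(per, 2, sd) / sqrt(n) else rep(NA_real_, ncol(per))
    return(list(per_mouse = per, mean = mu, sem = sem, n_mice = n))
  }
  stopifnot(length(values) == length(mouse_id))
  ok <- !is.na(values)
  if (any(!ok)) {
    warning(sprintf("dropped %d trial(s) with missing values", sum(!ok)),
            call. = FALSE)
    values <- values[ok]
    mouse_id <- mouse_id[ok]
  }
  if (length(values) == 0L) stop("no trials to average", call. = FALSE)
  per <- vapply(split(values, as.character(mouse_id)), mean, numeric(1))
  n <- length(per)
  list(per_mouse = per, mean = mean(per),
       sem = if (n > 1) sd(per) / sqrt(n) else NA_real_, n_mice = n)
}

#' Sliding-window poke rate
#'
#' Mean number of pokes (both ports) per minute over a sliding window,
#' evaluated on a regular grid. The window is centered by default; at the
#' session edges the truncated overlap with the session is used and the
#' count is normalized by the minutes actually covered.
#'
#' @param events An `event_log` or numeric poke times.
#' @param window Window length, minutes. Default 30.
#' @param session Session span `c(start, end)`, seconds. Defaults to the
#'   range of observed events.
#' @param step Grid step, seconds. Default 60.
#' @param anchor `"centered"` (default) or `"trailing"`.
#' @return Data frame with `t_s` and `rate` (pokes/min).
#' @export
poke_rate <- function(events, window = 30, session = NULL, step = 60,
                      anchor = c("centered", "trailing")) {
  anchor <- match.arg(anchor)
  if (window <= 0) stop("window must be > 0", call. = FALSE)
  tp <- if (inherits(events, "event_log")) event_times(events)
        else sort(as.numeric(events))
  if (is.null(session))
    session <- if (length(tp)) range(tp) else c(0, 0)
  grid <- seq(session[1], session[2], by = step)
  w_s <- window * 60
  half <- if (anchor == "centered") w_s / 2 else 0
  lo <- pmax(grid - if (anchor == "centered") half else w_s, session[1])
  hi <- pmin(grid + if (anchor == "centered") half else 0, session[2])
  counts <- findInterval(hi, tp) - findInterval(lo, tp)
  covered_min <- (hi - lo) / 60
  rate <- ifelse(covered_min > 0, counts / covered_min, 0)
  data.frame(t_s = grid, rate = rate)
}

#' Decile split of filtered pokes through the fast period
#'
#' Poke `i` of `N` (1-indexed in time order) has cumulative percentage
#' `100 i / N` and is assigned decile `ceiling((100 i / N) / 10)`, clipped
#' to `[1, 10]`. Returns the mean aligned trace per decile; the presented
#' subset is deciles 1, 4, 7, 10 (four equally-spaced deciles).
#'
#' @param aligned An `aligned_set` of the filtered pokes, in time order.
#' @return Object of class `decile_split`: `decile_index` per poke,
#'   `sizes`, `decile_means` (10 x n_samples matrix, `NA` rows for empty
#'   deciles), `rel_t`, `presented_deciles`.
#' @export
decile_split <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_set"))
  n <- nrow(aligned$traces)
  if (n == 0L) stop("no pokes to split into deciles", call. = FALSE)
  ord <- order(aligned$event_times)
  i <- seq_len(n)
  dec <- pmin(10L, pmax(1L, as.integer(ceiling((100 * i / n) / 10))))
  decile_index <- integer(n)
  decile_index[ord] <- dec
  means <- matrix(NA_real_, nrow = 10, ncol = ncol(aligned$traces))
  for (d in 1:10) {
    rows <- which(decile_index == d)
    if (length(rows))
      means[d, ] <- colMeans(aligned$traces[rows, , drop = FALSE])
  }
  structure(list(decile_index = decile_index,
                 sizes = tabulate(decile_index, 10L),
                 decile_means = means, rel_t = aligned$rel_t,
                 presented_deciles = c(1L, 4L, 7L, 10L)),
            class = "decile_split")
}

#' Per-trial mean activity in feeding-phase windows
#'
#' Windows relative to the annotated feeding events of a trial:
#' * `pre_drop` - 30 to 20 s before pellet delivery (avoids contamination
#'   by pre-drop cues such as the hand over the cage);
#' * `pre_contact` - pellet drop to 1 s before contact;
#' * `pre_bite` - contact to 1 s before the first bite;
#' * `bite` - 10 s following the first bite.
#'
#' Empty windows (e.g. contact within 1 s of the drop) are reported as `NA`
#' (absent), not zero.
#'
#' @param trace A `photo_trace` (typically kind `"dff"`).
#' @param drop,contact,bite Times (seconds) of pellet drop, first contact,
#'   and first bite; must be ordered `drop <= contact <= bite`.
#' @return Named numeric vector `c(pre_drop, pre_contact, pre_bite, bite)`.
#' @export
phase_means <- function(trace, drop, contact, bite) {
  stopifnot(inherits(trace, "photo_trace"))
  if (contact < drop || bite < contact)
    stop("events must be ordered: pellet drop <= contact <= first bite",
         call. = FALSE)
  win_mean <- function(w) {
    idx <- window_idx(trace$t, w)
    if (length(idx) == 0L) NA_real_ else mean(trace$y[idx])
  }
  c(pre_drop = win_mean(c(drop - 30, drop - 20)),
    pre_contact = win_mean(c(drop, contact - 1)),
    pre_bite = win_mean(c(contact, bite - 1)),
    bite = win_mean(c(bite, bite + 10)))
}
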