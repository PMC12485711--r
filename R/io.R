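# CSV interchange for recordings and event logs. Canonical dialects:
#   recordings: t_s, f_ca, f_iso   (UTF-8, header row, '.' decimal)
#   events:     t_s, label, value
# Ground-truth sidecars from the simulator are JSON.

EVENT_LABELS <- c("poke_left", "poke_right", "pellet_drop", "pellet_retrieval",
                  "food_in", "food_out", "water_in", "contact", "first_bite",
                  "injection")

POKE_LABELS <- c("poke_left", "poke_right")

#' Construct a validated two-channel photometry recording
#'
#' @param t Seconds since recording start, strictly increasing.
#' @param f_ca Calcium-dependent (465 nm-evoked) fluorescence, a.u.
#' @param f_iso Calcium-independent isosbestic (405 nm-evoked) fluorescence, a.u.
#' @param meta A [session_meta()].
#' @param sample_rate Hz; inferred from the median time step when `NULL`.
#' @return An object of class `photo_recording` with fields `t`, `f_ca`,
#'   `f_iso`, `sample_rate`, `meta`.
#' @export
photo_recording <- function(t, f_ca, f_iso, meta = session_meta(),
                            sample_rate = NULL) {
  n <- length(t)
  if (n == 0L || length(f_ca) != n || length(f_iso) != n)
    stop("t, f_ca, f_iso must be non-empty and of equal length", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("recording time base must be strictly increasing", call. = FALSE)
  if (any(!is.finite(f_ca)) || any(!is.finite(f_iso)))
    stop("recording contains non-finite fluorescence values", call. = FALSE)
  if (is.null(sample_rate))
    sample_rate <- if (n > 1L) 1 / median(diff(t)) else NA_real_
  structure(list(t = as.numeric(t), f_ca = as.numeric(f_ca),
                 f_iso = as.numeric(f_iso), sample_rate = sample_rate,
                 meta = meta),
            class = "photo_recording")
}

#' @export
print.photo_recording <- function(x, ...) {
  cat(sprintf("<photo_recording> %d samples, %.4g Hz, %.3g h, mouse %s (%s), start ZT%g\n",
              length(x$t), x$sample_rate, diff(range(x$t)) / 3600,
              x$meta$mouse_id, x$meta$condition, x$meta$recording_start_zt))
  invisible(x)
}

#' Write / load a photometry recording CSV
#'
#' The CSV holds columns `t_s`, `f_ca`, `f_iso`; session metadata travels
#' separately (arguments or a sidecar). On load, rows with non-finite
#' fluorescence are dropped with a warning reporting the count.
#'
#' @param rec A `photo_recording`.
#' @param path File path.
#' @return `write_recording` returns `path` invisibly; `load_recording`
#'   returns a validated `photo_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "photo_recording"))
  df <- data.frame(t_s = rec$t, f_ca = rec$f_ca, f_iso = rec$f_iso)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param meta A [session_meta()] describing the session.
#' @param sample_rate Hz; inferred from the median time step when `NULL`.
#' @export
load_recording <- function(path, meta = session_meta(), sample_rate = NULL) {
  if (!file.exists(path)) stop(sprintf("recording file not found: %s", path),
                               call. = FALSE)
  df <- read.csv(path)
  for (col in c("t_s", "f_ca", "f_iso"))
    if (!col %in% names(df))
      stop(sprintf("recording CSV is missing required column `%s`", col),
           call. = FALSE)
  ok <- is.finite(df$t_s) & is.finite(df$f_ca) & is.finite(df$f_iso)
  n_drop <- sum(!ok)
  if (n_drop > 0) {
    warning(sprintf("dropped %d row(s) with non-finite values from %s",
                    n_drop, path), call. = FALSE)
    df <- df[ok, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("recording is empty after dropping non-finite rows",
                           call. = FALSE)
  if (any(diff(df$t_s) <= 0))
    stop("recording time base must be strictly increasing", call. = FALSE)
  photo_recording(df$t_s, df$f_ca, df$f_iso, meta = meta,
                  sample_rate = sample_rate)
}

#' Construct a validated behavioral event log
#'
#' Rows are `(t_s, label, value)` with labels from the closed vocabulary
#' (`poke_left`, `poke_right`, `pellet_drop`, `pellet_retrieval`, `food_in`,
#' `food_out`, `water_in`, `contact`, `first_bite`, `injection`). Rows are
#' stably sorted by time.
#'
#' @param t_s Event times, seconds on the recording time base.
#' @param label Event labels.
#' @param value Optional free field.
#' @return A `data.frame` of class `event_log`.
#' @export
event_log <- function(t_s, label, value = NA_character_) {
  if (length(t_s) != length(label))
    stop("t_s and label must have equal length", call. = FALSE)
  label <- as.character(label)
  bad <- setdiff(unique(label), EVENT_LABELS)
  if (length(bad) > 0)
    stop(sprintf("unknown event label(s): %s; allowed labels are: %s",
                 paste(bad, collapse = ", "),
                 paste(EVENT_LABELS, collapse = ", ")), call. = FALSE)
  df <- data.frame(t_s = as.numeric(t_s), label = label,
                   value = rep_len(as.character(value), length(t_s)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$t_s), , drop = FALSE]  # stable sort
  rownames(df) <- NULL
  class(df) <- c("event_log", "data.frame")
  df
}

#' Write / load an event-log CSV
#'
#' @param events An `event_log`.
#' @param path File path.
#' @return `write_events` returns `path` invisibly; `load_events` returns a
#'   validated, time-sorted `event_log`.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_log"))
  write.csv(as.data.frame(events), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
load_events <- function(path) {
  if (!file.exists(path)) stop(sprintf("event file not found: %s", path),
                               call. = FALSE)
  head1 <- read.csv(path, nrows = 1)
  df <- if ("value" %in% names(head1))
    read.csv(path, colClasses = c(value = "character"))
  else read.csv(path)
  for (col in c("t_s", "label"))
    if (!col %in% names(df))
      stop(sprintf("event CSV is missing required column `%s`", col),
           call. = FALSE)
  if (!"value" %in% names(df)) df$value <- NA_character_
  event_log(df$t_s, df$label, df$value)
}

#' Extract event times for a set of labels
#'
#' @param events An `event_log`.
#' @param labels Labels to keep (default: both nose-poke ports, since
#'   downstream counting combines ports).
#' @return Sorted numeric vector of event times (seconds).
#' @export
event_times <- function(events, labels = POKE_LABELS) {
  sort(events$t_s[events$label %in% labels])
}
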