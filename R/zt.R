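# Zeitgeber-time (ZT) arithmetic. ZT is hours since lights-on; ZT12 is
# lights-off in a 12:12 cycle. A recording anchors ZT through
# meta$recording_start_zt; all window logic supports windows that wrap
# midnight (end < start).

#' Session metadata
#'
#' @param mouse_id Identifier of the animal.
#' @param condition Condition label (e.g. `"ad_lib"`, `"fast"`, `"vehicle"`,
#'   `"cno"`, `"fed"`, `"fasted"`, `"water_deprived"`).
#' @param recording_start_zt Zeitgeber hour in `[0, 24)` at which the
#'   recording starts.
#' @param lights_on_clock Optional local clock time of lights-on (informational).
#' @param acquisition_rate_label Optional label of the acquisition rate
#'   (`"10 Hz"` or `"20 Hz"` time-division multiplexing).
#' @return An object of class `session_meta`.
#' @export
session_meta <- function(mouse_id = "m1", condition = "ad_lib",
                         recording_start_zt = 6, lights_on_clock = NULL,
                         acquisition_rate_label = NULL) {
  if (!is.numeric(recording_start_zt) || length(recording_start_zt) != 1L ||
      is.na(recording_start_zt) || recording_start_zt < 0 ||
      recording_start_zt >= 24)
    stop("recording_start_zt must lie in [0, 24)", call. = FALSE)
  structure(list(
    mouse_id = as.character(mouse_id),
    condition = as.character(condition),
    recording_start_zt = recording_start_zt,
    lights_on_clock = lights_on_clock,
    acquisition_rate_label = acquisition_rate_label
  ), class = "session_meta")
}

#' Convert recording time to Zeitgeber time
#'
#' `ZT(t) = (recording_start_zt + t/3600) mod 24`.
#'
#' @param t_s Seconds since recording start.
#' @param meta A [session_meta()] (or the starting ZT hour as a number).
#' @return ZT hours in `[0, 24)`.
#' @export
zt_at <- function(t_s, meta) {
  start <- if (inherits(meta, "session_meta")) meta$recording_start_zt else meta
  (start + t_s / 3600) %% 24
}

#' Convert a Zeitgeber hour to recording seconds
#'
#' Resolves to the first occurrence of the given ZT hour at or after
#' recording start.
#'
#' @inheritParams zt_at
#' @param zt Zeitgeber hour.
#' @return Seconds since recording start.
#' @export
zt_to_seconds <- function(zt, meta) {
  start <- if (inherits(meta, "session_meta")) meta$recording_start_zt else meta
  ((zt - start) %% 24) * 3600
}

#' Resolve a ZT window to recording seconds
#'
#' A window with `end_zt < start_zt` wraps midnight (e.g. ZT12-ZT2 spans
#' 14 h). The window is placed at its first occurrence at or after recording
#' start and returned as half-open `(start, end]` seconds.
#'
#' @inheritParams zt_at
#' @param start_zt,end_zt Zeitgeber hours delimiting the window.
#' @param t_max Optional recording duration (seconds); if supplied, a window
#'   that starts after the recording ends is an error.
#' @return Numeric `c(start, end)` in seconds since recording start.
#' @export
zt_window_seconds <- function(start_zt, end_zt, meta, t_max = NULL) {
  start_s <- zt_to_seconds(start_zt, meta)
  span_h <- (end_zt - start_zt) %% 24
  if (span_h == 0) span_h <- 24
  end_s <- start_s + span_h * 3600
  if (!is.null(t_max) && start_s >= t_max)
    stop(sprintf("ZT window [%g, %g] lies entirely outside the recording span",
                 start_zt, end_zt), call. = FALSE)
  c(start_s, end_s)
}
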