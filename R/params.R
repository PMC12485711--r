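# Parameter containers for the synthetic-data generator. Each constructor
# validates its arguments once so downstream code can assume sane values.

stop_param <- function(name, msg) {
  stop(sprintf("invalid parameter `%s`: %s", name, msg), call. = FALSE)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_param(name, "must be a single finite value > 0")
  x
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop_param(name, "must be a single finite value >= 0")
  x
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param(name, "must be a single finite value")
  x
}

#' Latent-state parameters for the activity simulator
#'
#' Describes the noiseless population-activity signal s(t): a single-harmonic
#' circadian term, a saturating-exponential rise triggered by food removal
#' (fasting), an exponential fall triggered by food presentation, and optional
#' spontaneous transients.
#'
#' @param circadian_amplitude Amplitude (dF/F units) of the circadian cosine.
#' @param circadian_peak_zt Zeitgeber hour in `[0, 24)` at which the circadian
#'   term peaks.
#' @param fast_rise_amplitude Asymptotic amplitude (dF/F units) of the
#'   fasting-evoked rise.
#' @param fast_rise_tau Time constant of the fasting rise, hours.
#' @param fast_onset_zt Zeitgeber hour at which food is removed.
#' @param food_fall_amplitude Amplitude (dF/F units) of the food-evoked fall.
#' @param food_fall_tau Time constant of the food-evoked fall, seconds.
#' @param transient_amplitude Amplitude of spontaneous calcium transients;
#'   0 disables them.
#' @param transient_decay Decay time of transients, seconds.
#' @return An object of class `state_params`.
#' @seealso [state_preset()] for presets calibrated to published estimates.
#' @export
state_params <- function(circadian_amplitude = 0.1,
                         circadian_peak_zt = 12,
                         fast_rise_amplitude = 0.5,
                         fast_rise_tau = 1.78,
                         fast_onset_zt = 12,
                         food_fall_amplitude = 0.3,
                         food_fall_tau = 7.5,
                         transient_amplitude = 0,
                         transient_decay = 2) {
  check_finite(circadian_amplitude, "circadian_amplitude")
  if (!is.numeric(circadian_peak_zt) || circadian_peak_zt < 0 ||
      circadian_peak_zt >= 24)
    stop_param("circadian_peak_zt", "must lie in [0, 24)")
  check_finite(fast_rise_amplitude, "fast_rise_amplitude")
  check_positive(fast_rise_tau, "fast_rise_tau")
  check_finite(fast_onset_zt, "fast_onset_zt")
  check_finite(food_fall_amplitude, "food_fall_amplitude")
  check_positive(food_fall_tau, "food_fall_tau")
  check_nonneg(transient_amplitude, "transient_amplitude")
  check_positive(transient_decay, "transient_decay")
  structure(list(
    circadian_amplitude = circadian_amplitude,
    circadian_peak_zt = circadian_peak_zt,
    fast_rise_amplitude = fast_rise_amplitude,
    fast_rise_tau = fast_rise_tau,
    fast_onset_zt = fast_onset_zt,
    food_fall_amplitude = food_fall_amplitude,
    food_fall_tau = food_fall_tau,
    transient_amplitude = transient_amplitude,
    transient_decay = transient_decay
  ), class = "state_params")
}

#' Latent-state presets calibrated to published population estimates
#'
#' * `"agrp_fast"` - arcuate AgRP hunger neurons: fasting rise with
#'   time constant 1.78 h; under ad libitum conditions activity peaks at
#'   dark onset and gradually decreases over the dark period.
#' * `"sim2_fast"` - paraventricular Sim2 afferents: faster rise
#'   (0.87 h), ad-lib activity peaking in the early dark phase.
#' * `"food_trial"` - short food-presentation trial in the fasted state:
#'   rapid fall with time constant 7.5 s.
#'
#' @param name Preset name.
#' @param ... Overrides forwarded to [state_params()].
#' @return A `state_params` object.
#' @export
state_preset <- function(name = c("agrp_fast", "sim2_fast", "food_trial"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    agrp_fast  = list(fast_rise_tau = 1.78, circadian_peak_zt = 12),
    sim2_fast  = list(fast_rise_tau = 0.87, circadian_peak_zt = 13),
    food_trial = list(food_fall_tau = 7.5, circadian_amplitude = 0)
  )
  over <- list(...)
  base[names(over)] <- over
  do.call(state_params, base)
}

#' Photometry acquisition-noise parameters
#'
#' Parameters of the two-channel acquisition model: per-channel
#' mono-exponential photobleaching, a shared low-pass (motion) artifact
#' common to both channels up to a gain factor, and white shot noise.
#'
#' @param bleach_halflife_ca,bleach_halflife_iso Bleaching half-life of the
#'   calcium-dependent (465 nm) / isosbestic (405 nm) channel, hours;
#'   `Inf` disables bleaching. Defaults emulate low-duty-cycle
#'   time-division-multiplexed acquisition, which loses only a few percent
#'   of signal per day. Note the validity condition of regression-based
#'   motion correction: within a session the isosbestic channel's variance
#'   must be dominated by the shared artifact, not by its bleach trend,
#'   otherwise the whole-recording regression absorbs slow signal.
#' @param artifact_sd Stationary SD of the shared motion artifact
#'   (arbitrary fluorescence units).
#' @param artifact_gain_iso Gain with which the shared artifact appears on
#'   the isosbestic channel (it enters the calcium channel with gain 1).
#' @param white_noise_sd SD of per-channel white noise (a.u.).
#' @param baseline_ca,baseline_iso Baseline fluorescence of each channel
#'   (a.u., > 0).
#' @param sample_rate Acquisition rate, Hz.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(bleach_halflife_ca = 500,
                         bleach_halflife_iso = 500,
                         artifact_sd = 0.05,
                         artifact_gain_iso = 1,
                         white_noise_sd = 0.01,
                         baseline_ca = 1,
                         baseline_iso = 0.5,
                         sample_rate = 10) {
  for (nm in c("bleach_halflife_ca", "bleach_halflife_iso")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop_param(nm, "must be > 0 (Inf disables bleaching)")
  }
  check_nonneg(artifact_sd, "artifact_sd")
  check_finite(artifact_gain_iso, "artifact_gain_iso")
  check_nonneg(white_noise_sd, "white_noise_sd")
  check_positive(baseline_ca, "baseline_ca")
  check_positive(baseline_iso, "baseline_iso")
  check_positive(sample_rate, "sample_rate")
  structure(list(
    bleach_halflife_ca = bleach_halflife_ca,
    bleach_halflife_iso = bleach_halflife_iso,
    artifact_sd = artifact_sd,
    artifact_gain_iso = artifact_gain_iso,
    white_noise_sd = white_noise_sd,
    baseline_ca = baseline_ca,
    baseline_iso = baseline_iso,
    sample_rate = sample_rate
  ), class = "noise_params")
}

#' Operant-behavior parameters
#'
#' Rates of the inhomogeneous Poisson nose-poke process for a fixed-ratio 1
#' (FR1) session, and the extinction dynamics during the fasting window in
#' which pellet delivery is paused. During fasting the poke intensity is
#' `floor_rate + burst_rate * exp(-(t - fast_start) / extinction_tau)`:
#' an extinction burst that decays as mice learn the new contingency.
#'
#' @param adlib_poke_rate_base Baseline poke rate under ad-libitum FR1,
#'   pokes/min.
#' @param adlib_meal_cluster_rate Rate of meal clusters (bouts of elevated
#'   poking), clusters/h.
#' @param burst_rate Initial extinction-burst poke rate above the floor,
#'   pokes/min.
#' @param extinction_tau Decay time of the extinction burst, hours.
#' @param floor_rate Long-run poke rate during fasting, pokes/min.
#' @param fast_window Zeitgeber hours `c(start, end)` during which pellet
#'   delivery is paused; `end < start` means the window wraps midnight
#'   (default `c(12, 2)`).
#' @param retrieval_delay_mean Mean pellet-retrieval delay, seconds.
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(adlib_poke_rate_base = 0.3,
                            adlib_meal_cluster_rate = 1.5,
                            burst_rate = 3,
                            extinction_tau = 1.5,
                            floor_rate = 0.05,
                            fast_window = c(12, 2),
                            retrieval_delay_mean = 10) {
  check_nonneg(adlib_poke_rate_base, "adlib_poke_rate_base")
  check_nonneg(adlib_meal_cluster_rate, "adlib_meal_cluster_rate")
  check_nonneg(burst_rate, "burst_rate")
  check_positive(extinction_tau, "extinction_tau")
  check_nonneg(floor_rate, "floor_rate")
  if (!is.numeric(fast_window) || length(fast_window) != 2L ||
      any(!is.finite(fast_window)))
    stop_param("fast_window", "must be c(start_zt, end_zt)")
  check_positive(retrieval_delay_mean, "retrieval_delay_mean")
  structure(list(
    adlib_poke_rate_base = adlib_poke_rate_base,
    adlib_meal_cluster_rate = adlib_meal_cluster_rate,
    burst_rate = burst_rate,
    extinction_tau = extinction_tau,
    floor_rate = floor_rate,
    fast_window = fast_window,
    retrieval_delay_mean = retrieval_delay_mean
  ), class = "behavior_params")
}
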