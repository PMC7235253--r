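#' Configuration for the synthetic iEEG cohort generator
#'
#' Bundles every tunable of the simulated virtual-navigation experiment:
#' the task geometry (a 70-unit linear track traversed in three
#' constant-speed thirds, speeds drawn uniformly from `speed_range`, with
#' 1-s linear acceleration ramps at speed changes and a 4-s pre-movement
#' countdown), the LFP model (1/f^alpha background noise with embedded
#' amplitude-modulated oscillatory bouts), and the cohort-level anatomical
#' structure (a logistic single-vs-dual oscillator gradient and a linear
#' anterior-posterior frequency gradient for the high-theta band).
#'
#' @param n_subjects number of simulated subjects.
#' @param electrodes_per_subject hippocampal electrodes per subject.
#' @param n_trials trials per subject session.
#' @param track_length virtual track length (VR units).
#' @param speed_range length-2 numeric, min/max movement speed (VR units/s);
#'   speeds are drawn i.i.d. uniform on this interval, one per track third.
#' @param ramp_duration duration (s) of the linear acceleration ramp
#'   inserted at each speed change.
#' @param countdown_s pre-movement countdown duration (s).
#' @param inter_trial_s gap between consecutive trials (s).
#' @param sampling_rate recording sampling rate (Hz), >= 200.
#' @param noise_exponent spectral slope alpha of the 1/f^alpha background.
#' @param line_noise_amplitude amplitude of an additive 60-Hz mains
#'   component (0 disables it).
#' @param gradient_intercept,gradient_slope high-theta base frequency model:
#'   `f_base = gradient_intercept + gradient_slope * ap_fraction` (Hz and
#'   Hz per unit A-P fraction).
#' @param gradient_noise_sd electrode-level Gaussian scatter (Hz) around the
#'   A-P frequency gradient.
#' @param speed_slope frequency gain of the speed-coupled high band, in Hz
#'   per (VR unit/s); 0 decouples frequency from speed.
#' @param freq_jitter_sd per-bout Gaussian frequency jitter (Hz).
#' @param bout_mean_cycles mean oscillatory bout length in cycles; bout
#'   durations are gamma-distributed (shape 2) with mean
#'   `bout_mean_cycles / f`.
#' @param osc_snr oscillation amplitude as a multiple of the background
#'   noise standard deviation within the oscillation's own band (a
#'   band-limited signal-to-noise ratio).
#' @param p_single_logit length-2 numeric `(beta0, beta1)`:
#'   `P(single oscillator) = plogis(beta0 + beta1 * ap_fraction)`.
#' @param p_single_high probability that a single oscillator carries a
#'   high-theta (>= 4 Hz) rather than low-theta band.
#' @param object_zone length-2 numeric, admissible object positions
#'   (VR units).
#' @param response_error_sd SD (VR units) of the Gaussian response error.
#' @param seed integer master seed; all generator randomness derives from it.
#'
#' @return a list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_subjects = 1, electrodes_per_subject = 2,
#'                   n_trials = 5, seed = 7)
#' cfg$speed_range
#' @export
sim_config <- function(n_subjects = 8,
                       electrodes_per_subject = 5,
                       n_trials = 60,
                       track_length = 70,
                       speed_range = c(2, 12),
                       ramp_duration = 1.0,
                       countdown_s = 4.0,
                       inter_trial_s = 2.0,
                       sampling_rate = 1000,
                       noise_exponent = 2.0,
                       line_noise_amplitude = 0,
                       gradient_intercept = 6.5,
                       gradient_slope = 2.0,
                       gradient_noise_sd = 0.5,
                       speed_slope = 0.1,
                       freq_jitter_sd = 0.2,
                       bout_mean_cycles = 3,
                       osc_snr = 2,
                       p_single_logit = c(-1, 5),
                       p_single_high = 0.93,
                       object_zone = c(12, 58),
                       response_error_sd = 8.2,
                       seed = 1L) {
  cfg <- list(
    n_subjects = n_subjects,
    electrodes_per_subject = electrodes_per_subject,
    n_trials = n_trials,
    track_length = track_length,
    speed_range = speed_range,
    ramp_duration = ramp_duration,
    countdown_s = countdown_s,
    inter_trial_s = inter_trial_s,
    sampling_rate = sampling_rate,
    noise_exponent = noise_exponent,
    line_noise_amplitude = line_noise_amplitude,
    gradient_intercept = gradient_intercept,
    gradient_slope = gradient_slope,
    gradient_noise_sd = gradient_noise_sd,
    speed_slope = speed_slope,
    freq_jitter_sd = freq_jitter_sd,
    bout_mean_cycles = bout_mean_cycles,
    osc_snr = osc_snr,
    p_single_logit = p_single_logit,
    p_single_high = p_single_high,
    object_zone = object_zone,
    response_error_sd = response_error_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$speed_range) == 2L)
  if (!(cfg$speed_range[1] <= cfg$speed_range[2]))
    stop("speed_range must satisfy min <= max")
  if (cfg$speed_range[1] <= 0) stop("speed_range min must be positive")
  if (cfg$track_length <= 0) stop("track_length must be positive")
  if (cfg$sampling_rate < 200) stop("sampling_rate must be >= 200 Hz")
  if (cfg$response_error_sd < 0) stop("response_error_sd must be >= 0")
  if (cfg$object_zone[1] < 0 || cfg$object_zone[2] > cfg$track_length ||
      cfg$object_zone[1] > cfg$object_zone[2])
    stop("object_zone must lie within the track")
  if (cfg$n_trials < 1) stop("n_trials must be >= 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> %d subjects x %d electrodes, %d trials, fs %g Hz\n",
           "  track %g units, speeds U(%g, %g), 1/f^%.1f noise, SNR %g, seed %d\n"),
    x$n_subjects, x$electrodes_per_subject, x$n_trials, x$sampling_rate,
    x$track_length, x$speed_range[1], x$speed_range[2],
    x$noise_exponent, x$osc_snr, x$seed))
  invisible(x)
}

# deterministic per-entity seed derived from the master seed; kept < 2^31
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p) + 1) %% 2147483629
  as.integer(s)
}
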