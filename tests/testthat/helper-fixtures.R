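# shared fixture builders for the test suite

# single-channel recording holding a pure sinusoid (plus optional noise)
sine_recording <- function(freq, fs = 1000, dur = 30, amp = 1,
                           noise_sd = 0, seed = 1) {
  set.seed(seed)
  t <- (0:(dur * fs - 1)) / fs
  x <- amp * sin(2 * pi * freq * t) + stats::rnorm(length(t), 0, noise_sd)
  recording(matrix(x, ncol = 1), fs)
}

# analytic power-law spectrum on the package's standard 0.1-Hz grid
powerlaw_psd <- function(exponent = -2, c0 = 1, fmin = 1, fmax = 30,
                         df = 0.1) {
  f <- seq(fmin, fmax, by = df)
  structure(list(frequency = f, power = c0 * f^exponent,
                 fs = NA, win_s = NA, n_windows = NA),
            class = "power_spectrum")
}

# add a Gaussian bump (in linear power) to an analytic spectrum
add_bump <- function(psd, center, height, sigma = 0.5) {
  bg <- psd$power[which.min(abs(psd$frequency - center))]
  psd$power <- psd$power +
    height * bg * exp(-(psd$frequency - center)^2 / (2 * sigma^2))
  psd
}

# osc_trace built directly from vectors (for bout/epoch tests)
manual_trace <- function(inst_freq, presence, fs, f_lo, f_hi,
                         phase = NULL) {
  structure(list(band = list(f_lo = f_lo, f_hi = f_hi,
                             peak_freq = (f_lo + f_hi) / 2),
                 inst_freq = inst_freq,
                 phase = if (is.null(phase)) rep(0, length(inst_freq))
                         else phase,
                 amplitude = rep(1, length(inst_freq)),
                 presence = presence, fs = fs),
            class = "osc_trace")
}

# osc_trace carrying the generator's ground truth for one band
truth_trace <- function(sim, band_index, f_lo, f_hi, fs) {
  tf <- sim$ground_truth$true_freq[, band_index]
  manual_trace(ifelse(is.na(tf), 0, tf), !is.na(tf), fs, f_lo, f_hi)
}

# small cohort config for fast end-to-end runs
small_config <- function(seed = 1, ...) {
  sim_config(n_subjects = 2, electrodes_per_subject = 3, n_trials = 8,
             sampling_rate = 250, seed = seed, ...)
}
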