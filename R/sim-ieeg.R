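#' Multichannel recording container
#'
#' @param signals numeric matrix, samples in rows, channels in columns.
#' @param fs sampling rate (Hz).
#' @param channel_ids character vector of channel names.
#' @param start_time recording start (s).
#' @return object of class `recording`.
#' @export
recording <- function(signals, fs, channel_ids = NULL, start_time = 0) {
  signals <- as.matrix(signals)
  if (is.null(channel_ids))
    channel_ids <- paste0("ch", seq_len(ncol(signals)))
  stopifnot(length(channel_ids) == ncol(signals), fs > 0)
  colnames(signals) <- channel_ids
  structure(list(signals = signals, fs = fs, channel_ids = channel_ids,
                 start_time = start_time),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$signals), nrow(x$signals), x$fs,
              nrow(x$signals) / x$fs))
  invisible(x)
}

#' 1/f^alpha colored noise by spectral shaping
#'
#' White Gaussian noise is shaped in the frequency domain with gain
#' `f^(-alpha/2)` (DC removed) and normalized to unit standard deviation.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param alpha spectral exponent (power ~ 1/f^alpha).
#' @return numeric vector of length `n`, sd 1.
#' @export
one_over_f_noise <- function(n, fs, alpha = 2) {
  m <- stats::nextn(n, c(2, 3, 5))  # keep the FFT length highly composite
  w <- stats::rnorm(m)
  X <- stats::fft(w)
  k <- 0:(m - 1)
  f_abs <- pmin(k, m - k) * fs / m
  g <- ifelse(f_abs > 0, f_abs^(-alpha / 2), 0)
  x <- Re(stats::fft(X * g, inverse = TRUE) / m)[seq_len(n)]
  x / stats::sd(x)
}

#' Oscillator specification for one simulated electrode
#'
#' Declares the one or two narrowband oscillations an electrode carries.
#' Dual bands must be separated by at least 0.5 Hz between the upper edge
#' of the lower band and the lower edge of the upper band, mirroring the
#' dual-oscillator classification rule.
#'
#' @param base_freq numeric (length 1 or 2), bout carrier frequency per
#'   band (Hz).
#' @param f_lo,f_hi band edges per base frequency (Hz); default
#'   `base_freq - 1` / `base_freq + 2`.
#' @param speed_coupled logical per band: does instantaneous frequency
#'   follow movement speed?
#' @return object of class `electrode_spec`.
#' @export
electrode_spec <- function(base_freq, f_lo = base_freq - 1,
                           f_hi = base_freq + 2,
                           speed_coupled = base_freq >= 4) {
  nb <- length(base_freq)
  stopifnot(nb %in% 1:2, length(f_lo) == nb, length(f_hi) == nb,
            length(speed_coupled) == nb)
  bands <- data.frame(f_lo = f_lo, f_hi = f_hi, base = base_freq,
                      speed_coupled = speed_coupled)
  bands <- bands[order(bands$base), , drop = FALSE]
  if (any(bands$f_lo <= 1) || any(bands$f_hi >= 20))
    stop("oscillation bands must lie within (1, 20) Hz")
  if (any(bands$f_lo >= bands$f_hi) || any(bands$base < bands$f_lo) ||
      any(bands$base > bands$f_hi))
    stop("base frequency must lie inside its band")
  if (nb == 2 && bands$f_lo[2] - bands$f_hi[1] < 0.5)
    stop("dual bands must be separated by >= 0.5 Hz (band edges closer ",
         "than the dual-oscillator classification gap)")
  structure(list(bands = bands), class = "electrode_spec")
}

#' Simulate one electrode's LFP with embedded oscillatory bouts
#'
#' The signal is unit-variance 1/f^alpha noise plus, per declared band, a
#' train of amplitude-modulated sinusoidal bouts.  Bout durations are
#' gamma-distributed (shape 2) with mean `bout_mean_cycles / base_freq`
#' seconds, separated by exponential gaps of the same mean (about 50% duty
#' cycle).  Within a bout the instantaneous frequency is
#' `base + speed_slope * speed(t)` (speed-coupled bands only) plus a
#' per-bout Gaussian jitter, clamped to the band.  Bout envelopes carry
#' one-cycle Hann tapers at each edge to avoid spectral splatter.
#'
#' @param spec an [electrode_spec()].
#' @param trials behavior log from [simulate_behavior()] (drives the speed
#'   profile); `NULL` for a task-free recording of `duration_s` seconds.
#' @param config a [sim_config()].
#' @param seed integer seed (default derived from `config$seed`).
#' @param duration_s recording length when `trials` is `NULL`.
#' @return list with `recording` (single-channel [recording()]) and
#'   `ground_truth`: `bands` (data frame), `bouts` (data frame:
#'   `band_index`, `start_s`, `end_s`, `mean_freq_hz`, `n_cycles`) and
#'   `true_freq` (matrix samples x bands, `NA` outside bouts).
#' @export
simulate_ieeg <- function(spec, trials, config, seed = NULL,
                          duration_s = NULL) {
  stopifnot(inherits(spec, "electrode_spec"))
  validate_sim_config(config)
  set.seed(if (is.null(seed)) derive_seed(config$seed, 202L) else as.integer(seed))
  fs <- config$sampling_rate
  if (is.null(trials)) {
    if (is.null(duration_s)) stop("duration_s required when trials is NULL")
    n <- round(duration_s * fs)
    sp <- numeric(n)
  } else {
    n <- round((max(trials$t_end_s) + 2) * fs)
    sp <- speed_profile(trials, fs, n, config$ramp_duration)
  }

  x <- one_over_f_noise(n, fs, config$noise_exponent)
  noise_ref <- x
  if (config$line_noise_amplitude > 0)
    x <- x + config$line_noise_amplitude *
      sin(2 * pi * 60 * (seq_len(n) - 1) / fs)

  nb <- nrow(spec$bands)
  true_freq <- matrix(NA_real_, n, nb)
  bouts <- list()
  for (b in seq_len(nb)) {
    bb <- spec$bands[b, ]
    # oscillation amplitude is osc_snr times the background noise level
    # within the band, so spectral contrast is controlled per band (a
    # ratio against the broadband SD would swamp the 1/f spectrum)
    bf <- signal::butter(2, c(bb$f_lo, bb$f_hi) / (fs / 2), type = "pass")
    amp <- config$osc_snr *
      stats::sd(signal::filtfilt(bf, noise_ref))
    # one phase-continuous oscillator per band: the carrier runs for the
    # whole recording (frequency tracking speed where coupled), and bouts
    # are amplitude gating of that carrier -- this keeps the spectral peak
    # narrowband instead of smearing it with per-bout phase resets
    f_track <- rep(bb$base, n) +
      if (bb$speed_coupled) config$speed_slope * sp else 0
    env <- numeric(n)
    mean_dur <- config$bout_mean_cycles / bb$base
    b_start <- b_end <- b_freq <- b_cyc <- numeric(0)
    t <- stats::rexp(1, 1 / mean_dur)
    while (t < n / fs) {
      dur <- stats::rgamma(1, shape = 2, scale = mean_dur / 2)
      i0 <- floor(t * fs) + 1L
      i1 <- min(n, i0 + max(2L, round(dur * fs)) - 1L)
      if (i1 > n - 2L) break
      idx <- i0:i1
      jit <- stats::rnorm(1, 0, config$freq_jitter_sd)
      f <- pmin(pmax(f_track[idx] + jit, bb$f_lo), bb$f_hi)
      f_track[idx] <- f
      len <- length(idx)
      # half-cycle Hann edges, at most a quarter of the bout: longer
      # tapers leave short bouts with almost none of their nominal power
      taper <- min(round(fs / (2 * bb$base)), floor(len / 4))
      e <- rep(1, len)
      if (taper > 1) {
        ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = taper)))
        e[1:taper] <- ramp
        e[(len - taper + 1):len] <- rev(ramp)
      }
      env[idx] <- e
      true_freq[idx, b] <- f
      b_start <- c(b_start, (i0 - 1) / fs)
      b_end <- c(b_end, i1 / fs)
      b_freq <- c(b_freq, mean(f))
      b_cyc <- c(b_cyc, sum(f) / fs)
      t <- i1 / fs + stats::rexp(1, 1 / mean_dur)
    }
    phase <- 2 * pi * cumsum(f_track) / fs + stats::runif(1, 0, 2 * pi)
    x <- x + amp * env * cos(phase)
    bouts[[b]] <- data.frame(band_index = b, start_s = b_start,
                             end_s = b_end, mean_freq_hz = b_freq,
                             n_cycles = b_cyc)
  }
  bouts <- do.call(rbind, bouts)
  list(
    recording = recording(matrix(x, ncol = 1), fs),
    ground_truth = list(bands = spec$bands, bouts = bouts,
                        true_freq = true_freq)
  )
}

#' Ground-truth mean oscillation frequency per trial epoch
#'
#' Averages the generator's per-sample true frequency over each
#' constant-speed epoch (ramps excluded), giving the oracle against which
#' recovered epoch mode frequencies can be compared.
#'
#' @param ground_truth from [simulate_ieeg()].
#' @param trials behavior log.
#' @param fs sampling rate (Hz).
#' @param band_index which band of the electrode.
#' @param ramp_duration ramp length (s) excluded from epochs 2-3.
#' @return data frame `trial_id`, `epoch_index`, `speed`, `true_freq_hz`
#'   (`NA` where the epoch contains no bout samples).
#' @export
true_epoch_frequency <- function(ground_truth, trials, fs, band_index = 1,
                                 ramp_duration = 1.0) {
  tf <- ground_truth$true_freq[, band_index]
  out <- trials[, c("trial_id", "epoch_index")]
  out$speed <- trials$speed_vru_s
  out$true_freq_hz <- NA_real_
  for (r in seq_len(nrow(trials))) {
    t0 <- trials$t_start_s[r]
    if (trials$epoch_index[r] > 1) t0 <- t0 + ramp_duration
    i0 <- floor(t0 * fs) + 1L
    i1 <- min(length(tf), floor(trials$t_end_s[r] * fs))
    if (i1 < i0) next
    v <- tf[i0:i1]
    if (any(!is.na(v))) out$true_freq_hz[r] <- mean(v, na.rm = TRUE)
  }
  rownames(out) <- NULL
  out
}
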