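#' Constant-speed analysis windows of a trial
#'
#' Returns the three constant-speed windows of a trial.  With
#' `exclude_ramps` (the default) the linear-acceleration second that
#' follows each speed change is removed from the start of the affected
#' epoch, so windows contain strictly constant-speed movement; ramps are
#' only present where the speed actually changed.
#'
#' @param trial data frame of one trial's three epoch rows (behavior-log
#'   schema of [simulate_behavior()]).
#' @param exclude_ramps drop the ramp second from epochs 2-3.
#' @param ramp_duration ramp length (s).
#' @return data frame `epoch_index`, `t_start_s`, `t_end_s`, `speed`.
#' @export
parse_epochs <- function(trial, exclude_ramps = TRUE, ramp_duration = 1.0) {
  if (nrow(trial) != 3)
    stop("malformed trial: expected exactly 3 epochs, got ", nrow(trial))
  trial <- trial[order(trial$epoch_index), ]
  t0 <- trial$t_start_s
  if (exclude_ramps) {
    for (i in 2:3) {
      if (trial$speed_vru_s[i] != trial$speed_vru_s[i - 1])
        t0[i] <- t0[i] + ramp_duration
    }
  }
  data.frame(epoch_index = trial$epoch_index, t_start_s = t0,
             t_end_s = trial$t_end_s, speed = trial$speed_vru_s)
}

#' Mode frequency of an oscillation within a time window
#'
#' Histograms the instantaneous frequency over present samples in the
#' window into 0.1-Hz bins aligned to 0 Hz and returns the center of the
#' most populated bin (ties broken toward the lower bin).  Returns `NA`
#' when less than `min_cycles` cycles of presence (at the band center
#' frequency) fall inside the window.
#'
#' @param trace a gated `osc_trace`.
#' @param window numeric length 2, window start/end (s).
#' @param bin histogram bin width (Hz).
#' @param min_cycles minimum presence time expressed in cycles.
#' @return mode frequency (Hz) or `NA`.
#' @export
epoch_mode_frequency <- function(trace, window, bin = 0.1, min_cycles = 2) {
  fs <- trace$fs
  i0 <- max(1L, floor(window[1] * fs) + 1L)
  i1 <- min(length(trace$presence), floor(window[2] * fs))
  if (i1 < i0) return(NA_real_)
  idx <- i0:i1
  pres <- idx[trace$presence[idx]]
  f_center <- (trace$band$f_lo + trace$band$f_hi) / 2
  if (length(pres) / fs < min_cycles / f_center) return(NA_real_)
  mode_frequency(trace$inst_freq[pres], bin)
}

# histogram mode: 0-aligned bins of width `bin`, ties to the lower bin,
# returns the bin center
mode_frequency <- function(freqs, bin = 0.1) {
  b <- floor(freqs / bin)
  tab <- table(b)
  top <- names(tab)[tab == max(tab)]
  (min(as.numeric(top)) + 0.5) * bin
}

#' Epoch-frequency table for one electrode band
#'
#' Applies [parse_epochs()] and [epoch_mode_frequency()] across a behavior
#' log, producing one row per (trial, epoch).
#'
#' @param trace a gated `osc_trace`.
#' @param trials behavior log (one subject).
#' @param electrode_id,label identifiers copied into the output.
#' @param exclude_ramps,ramp_duration see [parse_epochs()].
#' @return data frame: `electrode_id`, `label`, `trial_id`, `epoch_index`,
#'   `speed`, `mode_freq_hz` (`NA` where undefined).
#' @export
epoch_frequency_table <- function(trace, trials,
                                  electrode_id = NA_character_,
                                  label = NA_character_,
                                  exclude_ramps = TRUE,
                                  ramp_duration = 1.0) {
  rows <- lapply(split(trials, trials$trial_id), function(tr) {
    ep <- parse_epochs(tr, exclude_ramps, ramp_duration)
    data.frame(
      electrode_id = electrode_id, label = label,
      trial_id = tr$trial_id[1], epoch_index = ep$epoch_index,
      speed = ep$speed,
      mode_freq_hz = vapply(seq_len(3), function(i)
        epoch_mode_frequency(trace, c(ep$t_start_s[i], ep$t_end_s[i])),
        numeric(1)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$trial_id, out$epoch_index), ]
}

#' Subsample one movement epoch per trial
#'
#' Uniformly selects a single non-missing epoch from each trial so that
#' speed-frequency correlations are built from independent observations;
#' trials whose epochs are all missing are dropped.  Deterministic under
#' `seed`.
#'
#' @param epoch_freq data frame from [epoch_frequency_table()] (one
#'   electrode band).
#' @param seed integer seed.
#' @return one row per surviving trial.
#' @export
subsample_epochs <- function(epoch_freq, seed) {
  if (!nrow(epoch_freq)) stop("empty epoch-frequency table")
  set.seed(as.integer(seed))
  picked <- lapply(split(epoch_freq, epoch_freq$trial_id), function(tr) {
    ok <- which(!is.na(tr$mode_freq_hz))
    if (!length(ok)) return(NULL)
    tr[ok[sample.int(length(ok), 1)], , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  if (is.null(out))
    out <- epoch_freq[0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Speed-frequency correlation for one electrode band
#'
#' Pearson correlation between movement speed and epoch mode frequency
#' over subsampled epochs, with a two-sided p from the t transform on
#' n - 2 degrees of freedom.
#'
#' @param rows subsampled epoch rows ([subsample_epochs()] output).
#' @param n_min minimum number of epochs.
#' @return list: `r`, `p`, `n_epochs`, `flagged` (`TRUE` when undefined:
#'   too few epochs or zero variance).
#' @export
speed_frequency_correlation <- function(rows, n_min = 10) {
  n <- nrow(rows)
  if (n < n_min)
    return(list(r = NA_real_, p = NA_real_, n_epochs = n, flagged = TRUE))
  if (stats::var(rows$speed) == 0 || stats::var(rows$mode_freq_hz) == 0)
    return(list(r = NA_real_, p = NA_real_, n_epochs = n, flagged = TRUE))
  ct <- stats::cor.test(rows$speed, rows$mode_freq_hz, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_epochs = n,
       flagged = FALSE)
}

#' Behavioral accuracy of recall trials
#'
#' Error is the absolute distance between response and object position; a
#' trial is correct when the error is strictly below `threshold` VR units.
#' Trials without a response are excluded.
#'
#' @param trials behavior log (epoch rows; one row per trial is derived).
#' @param threshold correctness threshold (VR units).
#' @return list: `per_trial` (data frame `trial_id`, `error`, `correct`)
#'   and `fraction_correct`.
#' @export
behavioral_accuracy <- function(trials, threshold = 11.5) {
  one <- trials[trials$epoch_index == 1 & trials$trial_type == "recall", ]
  one <- one[!is.na(one$response_pos_vru), ]
  err <- abs(one$response_pos_vru - one$object_pos_vru)
  per_trial <- data.frame(trial_id = one$trial_id, error = err,
                          correct = err < threshold)
  list(per_trial = per_trial,
       fraction_correct = mean(per_trial$correct))
}
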