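#' Simulate the virtual-navigation behavior log
#'
#' Generates the event log of a session on a linear virtual track.  Each
#' trial begins with a countdown, after which the subject is moved down the
#' track in three constant-speed thirds; the speed of each third is drawn
#' i.i.d. uniform on `config$speed_range`, and each speed change is smoothed
#' by a linear acceleration ramp of `config$ramp_duration` seconds (no ramp
#' is inserted when consecutive speeds are equal).  The object position is
#' uniform on `config$object_zone`; the response position is the object
#' position plus Gaussian error truncated to the track.
#'
#' @param config a [sim_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return a data frame with one row per (trial, epoch): columns
#'   `trial_id`, `trial_type` (`"learn"` for the first two trials,
#'   `"recall"` thereafter), `epoch_index` (1-3), `t_start_s`, `t_end_s`
#'   (session-absolute seconds; epoch 1 starts when movement starts, epochs
#'   2-3 start at the track-third boundary and so include the ramp),
#'   `speed_vru_s`, `object_pos_vru`, `response_pos_vru`, `response_time_s`.
#' @examples
#' cfg <- sim_config(n_trials = 4, seed = 1)
#' head(simulate_behavior(cfg))
#' @export
simulate_behavior <- function(config, seed = NULL) {
  validate_sim_config(config)
  set.seed(if (is.null(seed)) derive_seed(config$seed, 101L) else as.integer(seed))
  L3 <- config$track_length / 3
  rows <- vector("list", config$n_trials)
  t0 <- 0
  for (k in seq_len(config$n_trials)) {
    v <- stats::runif(3, config$speed_range[1], config$speed_range[2])
    obj <- stats::runif(1, config$object_zone[1], config$object_zone[2])
    err <- stats::rnorm(1, 0, config$response_error_sd)
    resp <- min(max(obj + err, 0), config$track_length)

    kin <- trial_kinematics(v, L3, config$ramp_duration)
    t_move <- t0 + config$countdown_s
    resp_time <- t_move + position_to_time(resp, kin)

    rows[[k]] <- data.frame(
      trial_id = k,
      trial_type = if (k <= 2) "learn" else "recall",
      epoch_index = 1:3,
      t_start_s = t_move + kin$epoch_start,
      t_end_s = t_move + kin$epoch_end,
      speed_vru_s = v,
      object_pos_vru = obj,
      response_pos_vru = resp,
      response_time_s = resp_time,
      stringsAsFactors = FALSE
    )
    t0 <- t_move + kin$epoch_end[3] + config$inter_trial_s
  }
  do.call(rbind, rows)
}

# Piecewise-constant/linear kinematics of one trial, times relative to
# movement onset.  Returns epoch boundary times and the motion segments
# (t0, t1, p0, v0, v1) needed to invert position -> time.
trial_kinematics <- function(v, third_len, ramp) {
  segs <- list()
  t <- 0; p <- 0
  epoch_start <- numeric(3); epoch_end <- numeric(3)
  for (i in 1:3) {
    epoch_start[i] <- t
    rem <- third_len
    if (i > 1 && v[i] != v[i - 1]) {
      d_ramp <- (v[i - 1] + v[i]) / 2 * ramp
      if (d_ramp >= third_len)
        stop("acceleration ramp overruns a track third; shorten ramp_duration")
      segs[[length(segs) + 1]] <-
        list(t0 = t, t1 = t + ramp, p0 = p, v0 = v[i - 1], v1 = v[i])
      t <- t + ramp; p <- p + d_ramp; rem <- rem - d_ramp
    }
    dt <- rem / v[i]
    segs[[length(segs) + 1]] <-
      list(t0 = t, t1 = t + dt, p0 = p, v0 = v[i], v1 = v[i])
    t <- t + dt; p <- p + rem
    epoch_end[i] <- t
  }
  list(epoch_start = epoch_start, epoch_end = epoch_end, segments = segs)
}

# invert position to movement-relative time along the segment list
position_to_time <- function(pos, kin) {
  for (s in kin$segments) {
    d <- (s$v0 + s$v1) / 2 * (s$t1 - s$t0)
    if (pos <= s$p0 + d + 1e-9) {
      dp <- pos - s$p0
      if (s$v0 == s$v1) return(s$t0 + dp / s$v0)
      a <- (s$v1 - s$v0) / (s$t1 - s$t0)
      # solve p0 + v0*dt + a*dt^2/2 = pos
      dt <- (-s$v0 + sqrt(s$v0^2 + 2 * a * dp)) / a
      return(s$t0 + dt)
    }
  }
  kin$epoch_end[3]
}

#' Instantaneous movement speed sampled on the recording clock
#'
#' Reconstructs the speed profile (VR units/s) implied by a behavior log:
#' zero outside movement, constant within each track third, and linearly
#' interpolated over the `ramp_duration` acceleration window that follows
#' each speed change.
#'
#' @param trials behavior log from [simulate_behavior()].
#' @param fs sampling rate (Hz).
#' @param n_samples length of the output vector.
#' @param ramp_duration ramp length in seconds (must match the generator).
#' @return numeric vector of length `n_samples`.
#' @export
speed_profile <- function(trials, fs, n_samples, ramp_duration = 1.0) {
  sp <- numeric(n_samples)
  for (tr in split(trials, trials$trial_id)) {
    tr <- tr[order(tr$epoch_index), ]
    for (i in 1:3) {
      i0 <- tr$t_start_s[i]; i1 <- tr$t_end_s[i]; v <- tr$speed_vru_s[i]
      a <- max(1L, floor(i0 * fs) + 1L)
      b <- min(n_samples, ceiling(i1 * fs))
      if (b < a) next
      idx <- a:b
      tt <- (idx - 1) / fs
      keep <- tt >= i0 & tt < i1
      idx <- idx[keep]; tt <- tt[keep]
      if (!length(idx)) next
      sp[idx] <- v
      if (i > 1 && tr$speed_vru_s[i] != tr$speed_vru_s[i - 1]) {
        vprev <- tr$speed_vru_s[i - 1]
        rsel <- tt < i0 + ramp_duration
        if (any(rsel))
          sp[idx[rsel]] <- vprev + (v - vprev) * (tt[rsel] - i0) / ramp_duration
      }
    }
  }
  sp
}
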