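#' Generate a full synthetic cohort
#'
#' Builds a multi-subject data set with the anatomical and functional
#' structure the downstream analysis is designed to detect: electrode A-P
#' fractions spread over \[0.1, 0.9\]; probability of being a single (vs
#' dual) oscillator following a logistic curve in A-P position
#' (`p_single_logit`); high-theta base frequency following the linear A-P
#' gradient `gradient_intercept + gradient_slope * ap` plus electrode-level
#' scatter; low-theta bands near 3 Hz; only high-theta bands speed-coupled.
#' Hemispheres alternate L/R; subregions are sampled from
#' CA1/CA2/DG/SUB.
#'
#' @param config a [sim_config()].
#' @param signals if `TRUE`, simulate the LFP of every electrode (slow for
#'   large cohorts); if `FALSE`, return metadata and ground truth only.
#' @param out_dir optional directory: writes `events.csv`,
#'   `electrodes.tsv` and `ground_truth.json` (plus per-subject signal CSVs
#'   when `write_signals = TRUE`).
#' @param write_signals write raw signals as CSV (large files; plain-text
#'   fallback format).
#' @return list with elements `electrodes` (data frame: `subject_id`,
#'   `electrode_id`, `hemisphere`, `subregion`, `ap_fraction`,
#'   `class_true`, `base_low_hz`, `base_high_hz`), `trials` (behavior log
#'   with `subject_id`), `recordings` (per-subject [recording()]s, or
#'   `NULL`), `ground_truth` (per electrode: bands, bouts, epoch
#'   frequencies), and `config`.
#' @examples
#' coh <- make_cohort(sim_config(n_subjects = 1, electrodes_per_subject = 2,
#'                               n_trials = 3, seed = 4), signals = FALSE)
#' coh$electrodes
#' @export
make_cohort <- function(config, signals = TRUE, out_dir = NULL,
                        write_signals = FALSE) {
  validate_sim_config(config)
  if (config$n_subjects < 1) stop("n_subjects must be >= 1")
  set.seed(derive_seed(config$seed, 303L))

  vmax <- config$speed_range[2]
  subregions <- c("CA1", "CA2", "DG", "SUB")
  elec_rows <- list()
  trials_all <- list()
  recordings <- if (signals) list() else NULL
  ground_truth <- list()

  for (s in seq_len(config$n_subjects)) {
    trials <- simulate_behavior(config, seed = derive_seed(config$seed, 100L, s))
    trials_sub <- cbind(subject_id = s, trials)
    trials_all[[s]] <- trials_sub

    set.seed(derive_seed(config$seed, 400L, s))
    ne <- config$electrodes_per_subject
    ap <- stats::runif(ne, 0.1, 0.9)
    p_single <- stats::plogis(config$p_single_logit[1] +
                                config$p_single_logit[2] * ap)
    is_single <- stats::runif(ne) < p_single
    base_high <- config$gradient_intercept + config$gradient_slope * ap +
      stats::rnorm(ne, 0, config$gradient_noise_sd)
    base_low <- stats::runif(ne, 2.5, 3.5)
    single_high <- stats::runif(ne) < config$p_single_high
    sub_reg <- sample(subregions, ne, replace = TRUE,
                      prob = c(0.5, 0.1, 0.2, 0.2))

    sig_list <- list(); ids <- character(ne)
    for (e in seq_len(ne)) {
      # keep the dual-band gap >= 0.5 Hz between edges (widths 1 Hz below
      # base, 1 Hz + speed excursion above)
      bh <- min(max(base_high[e], base_low[e] + 2.5, 5), 12.5)
      if (is_single[e] && !single_high[e]) {
        base <- base_low[e]; coupled <- FALSE
      } else if (is_single[e]) {
        base <- bh; coupled <- TRUE
      } else {
        base <- c(base_low[e], bh); coupled <- c(FALSE, TRUE)
      }
      f_hi <- base + 1 + ifelse(coupled, config$speed_slope * vmax, 0)
      spec <- electrode_spec(base, f_lo = base - 1, f_hi = f_hi,
                             speed_coupled = coupled)
      eid <- sprintf("S%d_E%d", s, e)
      ids[e] <- eid
      elec_rows[[length(elec_rows) + 1]] <- data.frame(
        subject_id = s, electrode_id = eid,
        hemisphere = if (e %% 2 == 1) "L" else "R",
        subregion = sub_reg[e], ap_fraction = ap[e],
        class_true = if (is_single[e]) "single" else "dual",
        base_low_hz = if (length(base) == 2 || !coupled[1]) base[1] else NA_real_,
        base_high_hz = if (any(coupled)) bh else NA_real_,
        stringsAsFactors = FALSE)
      gt <- list(bands = spec$bands)
      if (signals) {
        sim <- simulate_ieeg(spec, trials, config,
                             seed = derive_seed(config$seed, 500L, s, e))
        sig_list[[e]] <- sim$recording$signals[, 1]
        gt$bouts <- sim$ground_truth$bouts
        gt$epoch_freq <- lapply(seq_len(nrow(spec$bands)), function(b)
          true_epoch_frequency(sim$ground_truth, trials,
                               config$sampling_rate, b,
                               config$ramp_duration))
      }
      ground_truth[[eid]] <- gt
    }
    if (signals)
      recordings[[s]] <- recording(do.call(cbind, sig_list),
                                   config$sampling_rate, channel_ids = ids)
  }

  cohort <- list(
    electrodes = do.call(rbind, elec_rows),
    trials = do.call(rbind, trials_all),
    recordings = recordings,
    ground_truth = ground_truth,
    config = config
  )
  if (!is.null(out_dir)) write_cohort(cohort, out_dir, write_signals)
  cohort
}

#' Write a cohort to plain-text files
#'
#' Events go to `events.csv`, electrode metadata to `electrodes.tsv`,
#' ground truth (bands and bouts) to `ground_truth.json`; raw signals
#' optionally to one CSV per subject (plain-text signal format).
#'
#' @param cohort from [make_cohort()].
#' @param out_dir output directory (created if absent).
#' @param write_signals also write raw signal CSVs.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir, write_signals = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$trials, file.path(out_dir, "events.csv"),
                   row.names = FALSE)
  utils::write.table(cohort$electrodes,
                     file.path(out_dir, "electrodes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  gt <- lapply(cohort$ground_truth, function(g)
    list(bands = g$bands, bouts = g$bouts))
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       dataframe = "columns", digits = NA)
  if (write_signals && !is.null(cohort$recordings)) {
    for (s in seq_along(cohort$recordings)) {
      utils::write.csv(as.data.frame(cohort$recordings[[s]]$signals),
                       file.path(out_dir, sprintf("signals_S%d.csv", s)),
                       row.names = FALSE)
    }
  }
  invisible(out_dir)
}
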