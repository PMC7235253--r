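#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> preprocess -> detect -> classify -> bouts ->
#' speed-frequency -> cohort statistics and writes every results table to
#' `out_dir`.  All randomness derives from `config$seed`, so rerunning
#' with the same configuration reproduces the outputs byte-identically.
#'
#' Outputs written (tab-separated unless noted): `bands.tsv` (per-band
#' detections), `electrodes.tsv` (classification table), `bouts.tsv`,
#' `bout_summary.tsv`, `epoch_freq.tsv`, `correlations.tsv`, `stats.tsv`
#' (+ `stats.json`), and `manifest.json` (seed, config hash, versions).
#' Each table carries a header comment line with the seed and config hash.
#'
#' @param config a [sim_config()].
#' @param out_dir results directory (created if needed).
#' @param reference re-referencing scheme passed to [rereference()];
#'   simulated channels are independent, so the default is `"none"`.
#' @return invisibly, a list with all in-memory tables and `stats`.
#' @export
run_all <- function(config, out_dir, reference = "none") {
  validate_sim_config(config)
  cohort <- make_cohort(config, signals = TRUE)
  if (!nrow(cohort$trials)) stop("empty cohort")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fs <- config$sampling_rate

  band_rows <- list(); elec_rows <- list()
  bout_rows <- list(); epoch_rows <- list(); corr_rows <- list()
  mask_pairs <- list()

  for (s in seq_len(config$n_subjects)) {
    rec <- cohort$recordings[[s]]
    rec <- rereference(rec, reference)
    rec <- notch_filter(rec)
    mask <- exclude_artifacts(rec)
    trials <- cohort$trials[cohort$trials$subject_id == s, ]

    for (j in seq_len(ncol(rec$signals))) {
      eid <- rec$channel_ids[j]
      x <- rec$signals[, j]
      det <- detect_oscillations(x, fs, mask = mask[, j])
      cls <- classify_oscillator(det$bands)
      meta <- cohort$electrodes[cohort$electrodes$electrode_id == eid, ]

      if (nrow(cls$bands)) {
        band_rows[[eid]] <- cbind(electrode_id = eid, cls$bands,
                                  stringsAsFactors = FALSE)
      }
      elec_rows[[eid]] <- data.frame(
        subject_id = meta$subject_id, electrode_id = eid,
        hemisphere = meta$hemisphere, subregion = meta$subregion,
        ap_fraction = meta$ap_fraction,
        region = split_region(meta$ap_fraction),
        oscillator_class = cls$class,
        flagged = cls$flagged,
        stringsAsFactors = FALSE)

      pres_by_label <- list()
      for (b in seq_len(nrow(cls$bands))) {
        band <- cls$bands[b, ]
        tr <- instantaneous_trace(x, band, fs)
        tr <- gate_presence(tr, x, det$fit, mask = mask[, j])
        pres_by_label[[band$label]] <- tr$presence
        bout_rows[[paste(eid, b)]] <-
          extract_bouts(tr, electrode_id = eid, label = band$label)
        ef <- epoch_frequency_table(tr, trials, electrode_id = eid,
                                    label = band$label,
                                    ramp_duration = config$ramp_duration)
        epoch_rows[[paste(eid, b)]] <- ef
        sub <- subsample_epochs(ef, seed = derive_seed(config$seed, 900L, s, j, b))
        cr <- speed_frequency_correlation(sub)
        corr_rows[[paste(eid, b)]] <- data.frame(
          electrode_id = eid, label = band$label,
          peak_hz = band$peak_freq,
          r = cr$r, p = cr$p, n_epochs = cr$n_epochs,
          flagged = cr$flagged, stringsAsFactors = FALSE)
      }
      if (cls$class == "dual" &&
          all(c("low", "high") %in% names(pres_by_label)))
        mask_pairs[[eid]] <- list(low = pres_by_label$low,
                                  high = pres_by_label$high)
    }
  }

  band_table <- do.call(rbind, band_rows)
  elec_table <- do.call(rbind, elec_rows)
  bout_table <- do.call(rbind, bout_rows)
  epoch_table <- do.call(rbind, epoch_rows)
  corr_table <- do.call(rbind, corr_rows)
  rownames(band_table) <- rownames(elec_table) <- rownames(bout_table) <-
    rownames(epoch_table) <- rownames(corr_table) <- NULL

  # deduplicate nearby electrodes with similar frequencies
  peak_lists <- lapply(elec_table$electrode_id, function(eid)
    band_table$peak_freq[band_table$electrode_id == eid])
  dedup_in <- elec_table
  dedup_in$peak_freqs <- peak_lists
  kept <- deduplicate_electrodes(dedup_in)
  elec_table$kept <- elec_table$electrode_id %in% kept$electrode_id

  stats <- cohort_statistics(elec_table, band_table, bout_table,
                             corr_table, cohort$trials, mask_pairs,
                             seed = derive_seed(config$seed, 990L))
  bsum <- mean_bout_cycles(bout_table)

  seed <- config$seed
  hash <- config_hash(config)
  write_table <- function(df, file) {
    path <- file.path(out_dir, file)
    con <- file(path, "w")
    writeLines(sprintf("# seed=%d config_hash=%s", seed, hash), con)
    utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
  }
  write_table(band_table, "bands.tsv")
  write_table(elec_table[, setdiff(names(elec_table), "peak_freqs")],
              "electrodes.tsv")
  write_table(bout_table, "bouts.tsv")
  write_table(bsum, "bout_summary.tsv")
  write_table(epoch_table, "epoch_freq.tsv")
  write_table(corr_table, "correlations.tsv")
  write_table(stats$table, "stats.tsv")
  jsonlite::write_json(stats$list, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = seed, config_hash = hash,
         r_version = as.character(getRversion()),
         package_version = "0.1.0"),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)

  invisible(list(bands = band_table, electrodes = elec_table,
                 bouts = bout_table, bout_summary = bsum,
                 epoch_freq = epoch_table, correlations = corr_table,
                 stats = stats$list, out_dir = out_dir))
}

# md5 of the canonical JSON encoding of a config
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

# group-level statistics assembled from the pipeline tables
cohort_statistics <- function(elec_table, band_table, bout_table,
                              corr_table, trials, mask_pairs, seed = 1) {
  keep <- elec_table$kept & !elec_table$flagged
  et <- elec_table[keep, ]
  bt <- band_table[band_table$electrode_id %in% et$electrode_id, ]
  ct <- corr_table[corr_table$electrode_id %in% et$electrode_id, ]
  out <- list()

  acc <- behavioral_accuracy(trials)
  out$accuracy_pct <- 100 * acc$fraction_correct

  out$n_electrodes <- nrow(et)
  out$n_single <- sum(et$oscillator_class == "single")
  out$single_fraction <- out$n_single / out$n_electrodes

  lg <- tryCatch(
    oscillator_logistic(et$ap_fraction, et$oscillator_class),
    error = function(e) NULL)
  if (!is.null(lg)) {
    out$logistic_beta1 <- lg$beta1
    out$logistic_p <- lg$p
  }

  # A-P gradient over high-theta single oscillators
  singles <- et$electrode_id[et$oscillator_class == "single"]
  hs <- bt[bt$electrode_id %in% singles & bt$label == "high", ]
  hs <- merge(hs, et[, c("electrode_id", "ap_fraction", "hemisphere",
                         "subregion")], by = "electrode_id")
  names(hs)[names(hs) == "peak_freq"] <- "peak_hz"
  if (nrow(hs) >= 3) {
    gc_all <- gradient_correlation(hs, by = "all")
    out$gradient_r <- gc_all$r
    out$gradient_p <- gc_all$p
    if (length(unique(hs$hemisphere)) == 2 &&
        length(unique(hs$subregion)) >= 2) {
      ht <- hemisphere_tests(hs)
      out$hemisphere_t <- unname(ht$freq_t$statistic)
      out$hemisphere_t_p <- ht$freq_t$p.value
      out$position_ranksum_p <- ht$position_ranksum$p.value
      out$subregion_anova_p <- ht$subregion_anova$p
    }
  }

  # prevalence of significant positive speed-frequency correlations
  hs_corr <- ct[ct$electrode_id %in% singles & ct$label == "high" &
                  !ct$flagged, ]
  lo_corr <- ct[ct$label == "low" & !ct$flagged, ]
  k_hi <- sum(hs_corr$r > 0 & hs_corr$p < 0.05)
  n_hi <- nrow(hs_corr)
  if (n_hi > 0) {
    out$high_sig_k <- k_hi
    out$high_sig_n <- n_hi
    out$high_sig_fraction <- k_hi / n_hi
    out$binomial_p <- binomial_prevalence_test(k_hi, n_hi)
  }
  k_lo <- sum(lo_corr$r > 0 & lo_corr$p < 0.05)
  n_lo <- nrow(lo_corr)
  if (n_lo > 0) {
    out$low_sig_fraction <- k_lo / n_lo
    if (n_hi > 0) {
      zt <- proportion_z_test(k_hi, n_hi, k_lo, n_lo)
      out$prop_z <- zt$z
      out$prop_z_p <- zt$p
    }
  }

  # bout-length contrasts
  bsum <- mean_bout_cycles(
    bout_table[bout_table$electrode_id %in% et$electrode_id, ])
  hi <- bsum$mean_cycles[bsum$label == "high"]
  lo <- bsum$mean_cycles[bsum$label == "low"]
  if (length(hi)) out$mean_bout_cycles_high <- mean(hi)
  if (length(lo)) out$mean_bout_cycles_low <- mean(lo)
  if (length(hi) >= 2 && length(lo) >= 2) {
    cb <- compare_bout_groups(hi, lo)
    out$bout_t <- cb$t; out$bout_t_df <- cb$df; out$bout_t_p <- cb$p
  }

  # two-way ANOVA on subject x region x band prevalence cells
  cells <- make_subject_cells(et, ct)
  if (nrow(cells) >= 4 && stats::var(cells$value) > 0) {
    an <- speedfreq_anova(cells)
    out$anova_interaction_p <- an$p[an$term == "region:band"]
  }

  # dual-oscillator structure
  duals <- et$electrode_id[et$oscillator_class == "dual"]
  db <- bt[bt$electrode_id %in% duals, ]
  if (length(duals) >= 5) {
    fl <- fh <- numeric(0)
    for (d in duals) {
      pk <- sort(db$peak_freq[db$electrode_id == d])
      if (length(pk) == 2) { fl <- c(fl, pk[1]); fh <- c(fh, pk[2]) }
    }
    if (length(fl) >= 5) {
      hp <- harmonic_permutation_test(fl, fh, seed = seed)
      out$harmonic_r <- hp$r
      out$harmonic_p <- hp$p
    }
  }
  if (length(mask_pairs) >= 5) {
    co <- suppressWarnings(cooccurrence_test(mask_pairs))
    out$cooccurrence_median <- stats::median(co$statistics)
    out$cooccurrence_p <- co$p
  }

  tab <- data.frame(statistic = names(out),
                    value = vapply(out, function(v)
                      as.numeric(v)[1], numeric(1)))
  list(list = out, table = tab)
}

#' Subject-level prevalence cells for the two-way ANOVA
#'
#' For each subject x region (anterior/posterior) x band (low/high) cell,
#' the value is the fraction of that subject's electrode bands with a
#' significant positive speed-frequency correlation (r > 0, p < 0.05).
#'
#' @param elec_table classification table (`subject_id`, `electrode_id`,
#'   `region`).
#' @param corr_table correlation table (`electrode_id`, `label`, `r`, `p`).
#' @return data frame `subject_id`, `region`, `band`, `value`.
#' @export
make_subject_cells <- function(elec_table, corr_table) {
  m <- merge(corr_table,
             elec_table[, c("electrode_id", "subject_id", "region")],
             by = "electrode_id")
  m <- m[!m$flagged & !is.na(m$p), ]
  if (!nrow(m))
    return(data.frame(subject_id = integer(), region = character(),
                      band = character(), value = numeric()))
  m$sig <- as.numeric(m$r > 0 & m$p < 0.05)
  agg <- stats::aggregate(sig ~ subject_id + region + label, data = m,
                          FUN = mean)
  names(agg)[names(agg) == "label"] <- "band"
  names(agg)[names(agg) == "sig"] <- "value"
  agg
}

#' Validate pipeline input tables
#'
#' Schema and sanity checks on a behavior log and electrode metadata
#' table; returns a machine-readable issue list rather than failing.
#'
#' @param trials behavior log data frame.
#' @param electrodes electrode metadata data frame.
#' @param sampling_rate optional recording sampling rate to check.
#' @return data frame `check`, `message` (zero rows when clean).
#' @export
validate_inputs <- function(trials = NULL, electrodes = NULL,
                            sampling_rate = NULL) {
  issues <- list()
  add <- function(check, msg)
    issues[[length(issues) + 1]] <<- data.frame(check = check,
                                                message = msg)
  if (!is.null(trials)) {
    need <- c("trial_id", "epoch_index", "t_start_s", "t_end_s",
              "speed_vru_s")
    miss <- setdiff(need, names(trials))
    if (length(miss)) add("events_schema",
                          paste("missing columns:",
                                paste(miss, collapse = ", ")))
    else {
      cnt <- table(trials$trial_id)
      bad <- names(cnt)[cnt != 3]
      if (length(bad)) add("epochs_per_trial",
                           paste("epochs != 3 for trial(s):",
                                 paste(bad, collapse = ", ")))
      if (any(trials$t_end_s <= trials$t_start_s))
        add("epoch_times", "epoch with t_end_s <= t_start_s")
      if (any(trials$speed_vru_s <= 0))
        add("speeds", "nonpositive movement speed")
    }
  }
  if (!is.null(electrodes)) {
    need <- c("subject_id", "electrode_id", "hemisphere", "ap_fraction")
    miss <- setdiff(need, names(electrodes))
    if (length(miss)) add("electrodes_schema",
                          paste("missing columns:",
                                paste(miss, collapse = ", ")))
    else {
      if (any(electrodes$ap_fraction < 0 | electrodes$ap_fraction > 1))
        add("ap_fraction", "ap out of range [0, 1]")
      if (!all(electrodes$hemisphere %in% c("L", "R")))
        add("hemisphere", "hemisphere not in {L, R}")
    }
  }
  if (!is.null(sampling_rate)) {
    if (sampling_rate < 200)
      add("sampling_rate", "sampling rate below 200 Hz")
    else if (!sampling_rate %in% c(1000, 2000))
      add("sampling_rate",
          "nonstandard sampling rate (1000 or 2000 Hz expected); resample")
  }
  if (!length(issues))
    return(data.frame(check = character(), message = character()))
  do.call(rbind, issues)
}
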