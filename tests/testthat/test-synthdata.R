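test_that("behavior simulation respects task geometry and speed bounds", {
  cfg <- sim_config(n_trials = 100, seed = 7)
  tr <- simulate_behavior(cfg)
  expect_equal(nrow(tr), 300)
  expect_true(all(table(tr$trial_id) == 3))
  expect_true(all(tr$speed_vru_s >= 2 & tr$speed_vru_s <= 12))
  expect_true(all(tr$object_pos_vru >= 12 & tr$object_pos_vru <= 58))
  expect_true(all(tr$t_end_s > tr$t_start_s))
  # epochs are ordered and contiguous within a trial
  for (t in split(tr, tr$trial_id)) {
    expect_equal(t$t_start_s[2:3], t$t_end_s[1:2])
  }
})

test_that("degenerate speed range gives constant speeds and exact thirds", {
  cfg <- sim_config(n_trials = 5, speed_range = c(5, 5), seed = 3)
  tr <- simulate_behavior(cfg)
  expect_true(all(tr$speed_vru_s == 5))
  # no speed change -> no ramp: every epoch lasts (70/3)/5 s
  expect_equal(tr$t_end_s - tr$t_start_s, rep(70 / 3 / 5, 15))
})

test_that("ramp kinematics follow the 1-s linear acceleration model", {
  kin <- hippotheta:::trial_kinematics(c(2, 12, 2), 70 / 3, 1)
  d1 <- kin$epoch_end[1] - kin$epoch_start[1]
  expect_equal(d1, (70 / 3) / 2)
  # ramp covers (2+12)/2 = 7 units in 1 s, remainder at 12
  expect_equal(kin$epoch_end[2] - kin$epoch_start[2],
               1 + (70 / 3 - 7) / 12)
  expect_equal(kin$epoch_end[3] - kin$epoch_start[3],
               1 + (70 / 3 - 7) / 2)
})

test_that("zero response error yields perfectly accurate recall", {
  cfg <- sim_config(n_trials = 20, response_error_sd = 0, seed = 5)
  tr <- simulate_behavior(cfg)
  acc <- behavioral_accuracy(tr)
  expect_true(all(acc$per_trial$error == 0))
  expect_equal(acc$fraction_correct, 1)
})

test_that("behavior simulation is deterministic under the seed", {
  cfg <- sim_config(n_trials = 10, seed = 42)
  expect_identical(simulate_behavior(cfg), simulate_behavior(cfg))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(response_error_sd = -1), "response_error_sd")
  expect_error(sim_config(speed_range = c(0, 5)), "positive")
  expect_error(sim_config(speed_range = c(8, 5)), "min <= max")
  expect_error(sim_config(sampling_rate = 100), "200")
  expect_error(sim_config(track_length = -1), "track_length")
})

test_that("pure shaped noise has the configured spectral slope", {
  cfg <- sim_config(osc_snr = 0, noise_exponent = 2, seed = 9)
  es <- electrode_spec(8)
  sim <- simulate_ieeg(es, NULL, cfg, seed = 21, duration_s = 200)
  psd <- compute_psd(sim$recording$signals[, 1], cfg$sampling_rate)
  fit <- fit_background(psd)
  expect_lt(abs(fit$slope - (-2)), 0.15)
})

test_that("a single injected band dominates the 2-14 Hz spectrum", {
  cfg <- sim_config(seed = 1)
  es <- electrode_spec(8, f_lo = 7, f_hi = 9, speed_coupled = FALSE)
  sim <- simulate_ieeg(es, NULL, cfg, seed = 4, duration_s = 200)
  psd <- compute_psd(sim$recording$signals[, 1], 1000)
  # compare against the local 1/f trend: argmax of elevation in 2-14 Hz
  fit <- fit_background(psd)
  sel <- psd$frequency >= 2 & psd$frequency <= 14
  elev <- log10(psd$power[sel]) -
    (fit$intercept + fit$slope * log10(psd$frequency[sel]))
  pk <- psd$frequency[sel][which.max(elev)]
  expect_lt(abs(pk - 8), 0.5)
})

test_that("dual specs produce two ground-truth bands and two local maxima", {
  cfg <- sim_config(seed = 2)
  es <- electrode_spec(c(3, 8), f_lo = c(2, 7), f_hi = c(4, 9),
                       speed_coupled = c(FALSE, FALSE))
  sim <- simulate_ieeg(es, NULL, cfg, seed = 6, duration_s = 200)
  expect_equal(nrow(sim$ground_truth$bands), 2)
  det <- detect_oscillations(sim$recording$signals[, 1], 1000)
  expect_true(any(det$bands$f_lo <= 3 & det$bands$f_hi >= 3))
  expect_true(any(det$bands$f_lo <= 8 & det$bands$f_hi >= 8))
})

test_that("electrode specs reject out-of-range and overlapping bands", {
  expect_error(electrode_spec(0.8, f_lo = 0.5, f_hi = 1.5), "within")
  expect_error(electrode_spec(19.5, f_lo = 18, f_hi = 20.5), "within")
  expect_error(electrode_spec(c(3, 5), f_lo = c(2, 4.2), f_hi = c(4, 6)),
               "0.5 Hz")
})

test_that("ground-truth bout cycle counts equal duration times mean frequency", {
  cfg <- sim_config(seed = 8)
  es <- electrode_spec(8, f_lo = 7, f_hi = 9)
  sim <- simulate_ieeg(es, NULL, cfg, seed = 13, duration_s = 60)
  gb <- sim$ground_truth$bouts
  expect_gt(nrow(gb), 10)
  fs <- cfg$sampling_rate
  expect_true(all(abs(gb$n_cycles -
                        (gb$end_s - gb$start_s) * gb$mean_freq_hz) <=
                    gb$mean_freq_hz / fs + 1e-9))
  # frequencies stay inside the declared band
  tf <- sim$ground_truth$true_freq[, 1]
  expect_true(all(tf[!is.na(tf)] >= 7 & tf[!is.na(tf)] <= 9))
})

test_that("with zero jitter the true epoch frequency is affine in speed", {
  cfg <- sim_config(n_trials = 15, sampling_rate = 250, speed_slope = 0.1,
                    freq_jitter_sd = 0, seed = 31)
  tr <- simulate_behavior(cfg)
  es <- electrode_spec(8, f_lo = 7, f_hi = 9.5, speed_coupled = TRUE)
  sim <- simulate_ieeg(es, tr, cfg, seed = 32)
  gt <- true_epoch_frequency(sim$ground_truth, tr, 250)
  ok <- !is.na(gt$true_freq_hz)
  expect_gt(sum(ok), 20)
  # affine up to the sample-grid discretization of epoch boundaries
  expect_equal(cor(gt$speed[ok], gt$true_freq_hz[ok]), 1, tolerance = 1e-4)
})

test_that("ieeg simulation is deterministic and rejects missing duration", {
  cfg <- sim_config(seed = 3)
  es <- electrode_spec(8)
  a <- simulate_ieeg(es, NULL, cfg, seed = 5, duration_s = 30)
  b <- simulate_ieeg(es, NULL, cfg, seed = 5, duration_s = 30)
  expect_identical(a$recording$signals, b$recording$signals)
  expect_error(simulate_ieeg(es, NULL, cfg), "duration_s")
})

test_that("cohorts carry anatomical structure and write plain-text files", {
  cfg <- sim_config(n_subjects = 4, electrodes_per_subject = 5,
                    n_trials = 3, seed = 17)
  coh <- make_cohort(cfg, signals = FALSE)
  el <- coh$electrodes
  expect_equal(nrow(el), 20)
  expect_true(all(el$ap_fraction >= 0.1 & el$ap_fraction <= 0.9))
  expect_true(all(el$hemisphere %in% c("L", "R")))
  expect_true(all(el$subregion %in% c("CA1", "CA2", "DG", "SUB")))
  expect_true(all(el$class_true %in% c("single", "dual")))
  # minimal cohort runs
  mini <- make_cohort(sim_config(n_subjects = 1, electrodes_per_subject = 1,
                                 n_trials = 2, sampling_rate = 250,
                                 seed = 2))
  expect_equal(ncol(mini$recordings[[1]]$signals), 1)
  # writing
  d <- tempfile()
  write_cohort(coh, d)
  expect_true(file.exists(file.path(d, "events.csv")))
  expect_true(file.exists(file.path(d, "electrodes.tsv")))
  expect_true(file.exists(file.path(d, "ground_truth.json")))
  unlink(d, recursive = TRUE)
})

test_that("posterior bias in single oscillators follows the logistic model", {
  # beta1 = +5: posterior half should carry more single oscillators
  hits <- 0
  for (sd in 1:15) {
    cfg <- sim_config(n_subjects = 12, electrodes_per_subject = 5,
                      p_single_logit = c(-1, 5), seed = sd)
    el <- make_cohort(cfg, signals = FALSE)$electrodes
    post <- el$class_true[el$ap_fraction >= 0.4] == "single"
    ant <- el$class_true[el$ap_fraction < 0.4] == "single"
    hits <- hits + (mean(post) > mean(ant))
  }
  expect_gte(hits / 15, 0.9)
})
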