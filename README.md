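# hippotheta

Analysis of narrowband theta oscillations in human hippocampal
intracranial EEG (iEEG), with a seeded synthetic-cohort generator for
validation.

Human hippocampal recordings during virtual navigation show narrowband
oscillations between 2 and 14 Hz — a low-theta band (< 4 Hz) and a
high-theta band (>= 4 Hz) — superimposed on a steep 1/f background.
Individual electrodes express either one oscillation (*single
oscillators*) or two (*dual oscillators*), and oscillation properties
vary along the hippocampal anterior–posterior (A–P) axis: posterior
contacts tend to carry fast single oscillations whose precise frequency
tracks movement speed. `hippotheta` is for electrophysiologists who want
to run this analysis chain end to end and validate every stage against
ground truth.

## What it computes

**Detection.** The power spectrum of each channel (Welch, 4-s Hann
windows, artifact-aware) is compared against a robust line fit of
log10(power) on log10(frequency): oscillation bands are contiguous
frequency runs whose power exceeds the fitted background by one residual
SD, searched over 2–14 Hz. For each band the analytic signal of the
band-passed trace yields instantaneous frequency `f(t)`, phase, and a
presence mask; a sample counts as oscillatory only while `f(t)` stays in
the band, its 10-s window shows a local spectral peak above threshold,
and its instantaneous band power exceeds the in-band background power.

**Classification.** Electrodes with two bands whose edges differ by
>= 0.5 Hz are dual oscillators; closer bands merge. Band labels split at
4 Hz. Positions are normalized A–P fractions (anterior/posterior cut at
0.40); nearby electrodes with similar frequencies are deduplicated.

**Quantification.** Oscillatory bouts are maximal present runs measured
in cycles (`duration x mean frequency`). Per trial epoch (three
constant-speed track thirds, ramps excluded) the oscillation frequency
is the mode of the `f(t)` histogram in 0.1-Hz bins; per electrode,
speed–frequency coupling is the Pearson correlation between epoch speed
and epoch frequency over one randomly chosen epoch per trial.

**Cohort statistics.** Exact binomial prevalence tests, two-proportion
z-tests, logistic regression of oscillator class on A–P position,
frequency-gradient correlations, hemisphere t/rank-sum tests, subregion
ANOVA, a two-way region x band ANOVA on subject-level prevalence cells
(Type II sums of squares), a seeded permutation test for harmonic
structure at dual oscillators, and a signed-rank co-occurrence test.

**Synthetic cohorts.** `sim_config()` + `make_cohort()` generate
multi-subject data sets — 1/f LFP with amplitude-gated narrowband
oscillators, a logistic single/dual gradient and a linear A–P frequency
gradient, speed-coupled high theta, and the full behavior log of the
constant-speed-thirds navigation task — reproducibly from one seed.

## Worked example

Simulate one dual-oscillator electrode (3-Hz low theta plus speed-coupled
8-Hz high theta, 60 trials) and analyze it:

```r
library(hippotheta)

cfg <- sim_config(n_trials = 60, sampling_rate = 1000, osc_snr = 4,
                  freq_jitter_sd = 0.1, seed = 7)
trials <- simulate_behavior(cfg)
spec <- electrode_spec(c(3, 8), f_lo = c(2, 7), f_hi = c(4, 9.4),
                       speed_coupled = c(FALSE, TRUE))
sim <- simulate_ieeg(spec, trials, cfg, seed = 7)

det <- detect_oscillations(sim$recording$signals[, 1], fs = 1000)
det$bands[, c("f_lo", "f_hi", "peak_freq", "peak_elev")]
#>   f_lo f_hi peak_freq peak_elev
#> 1  2.7  3.6       3.0     0.758
#> 2  7.7  9.7       8.2     0.567

cls <- classify_oscillator(det$bands)
cls$class; cls$bands$label
#> [1] "dual"
#> [1] "low"  "high"

hi <- det$traces[[which(cls$bands$label == "high")]]
mean_bout_cycles(extract_bouts(hi, "S1_E1", "high"))
#>   electrode_id label mean_cycles n_bouts
#> 1        S1_E1  high     3.95701     992

ef <- epoch_frequency_table(hi, trials, "S1_E1", "high")
speed_frequency_correlation(subsample_epochs(ef, seed = 7))
#> speed-frequency: r = 0.33, p = 0.0093 (n = 60 epochs)

behavioral_accuracy(trials)$fraction_correct
#> [1] 0.897  # 89.7% of recall trials within 11.5 track units
```

The detector finds both injected bands (peaks at 3.0 and 8.2 Hz standing
0.76 and 0.57 log10 units above the 1/f fit), classifies the electrode
as a dual oscillator, measures high-theta bouts of ~4 cycles, and
recovers a significant positive speed–frequency correlation — the
signature of movement-locked high theta.

For a whole cohort, `run_all(sim_config(seed = 1), "results_dir")`
executes simulate → preprocess → detect → classify → bouts →
speed-frequency → statistics and writes every results table (band,
classification, bout, epoch-frequency, correlation and statistics
tables, each stamped with the seed and config hash).

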