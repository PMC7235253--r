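#' Exact binomial prevalence test
#'
#' One-sided upper-tail probability that at least `k` of `n` electrodes
#' show a significant effect when each is significant with probability
#' `alpha` under the null: `P(X >= k)`, `X ~ Binomial(n, alpha)`.
#'
#' @param k number of significant electrodes.
#' @param n number of electrodes tested.
#' @param alpha per-electrode significance level.
#' @return the exact tail probability.
#' @examples
#' binomial_prevalence_test(13, 19)  # far below 1e-5
#' @export
binomial_prevalence_test <- function(k, n, alpha = 0.05) {
  if (n < 1) stop("n must be >= 1")
  stopifnot(k >= 0, k <= n)
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, alpha, lower.tail = FALSE)
}

#' Two-proportion z-test
#'
#' Pooled two-proportion z statistic comparing `k1/n1` against `k2/n2`,
#' with a one-sided (upper-tail, `p1 > p2`) or two-sided normal p.
#'
#' @param k1,n1 successes and size of the first sample.
#' @param k2,n2 successes and size of the second sample.
#' @param one_sided use the one-sided upper tail (default).
#' @return list: `z`, `p`, `flagged` (`TRUE` when the pooled proportion is
#'   degenerate at 0 or 1).
#' @export
proportion_z_test <- function(k1, n1, k2, n2, one_sided = TRUE) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  p_pool <- (k1 + k2) / (n1 + n2)
  if (p_pool <= 0 || p_pool >= 1)
    return(list(z = NA_real_, p = NA_real_, flagged = TRUE))
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  z <- (k1 / n1 - k2 / n2) / se
  p <- if (one_sided) stats::pnorm(z, lower.tail = FALSE)
       else 2 * stats::pnorm(-abs(z))
  list(z = z, p = p, flagged = FALSE)
}

#' Logistic regression of oscillator class on A-P position
#'
#' Maximum-likelihood logistic fit of single (1) versus dual (0)
#' oscillator status on A-P fraction, with the Wald p-value for the slope.
#' Perfect separation is flagged and no p is reported.
#'
#' @param ap_fractions numeric A-P fractions.
#' @param classes character (`"single"`/`"dual"`) or 0/1 vector.
#' @return list: `beta0`, `beta1`, `p`, `flagged`.
#' @export
oscillator_logistic <- function(ap_fractions, classes) {
  y <- if (is.character(classes) || is.factor(classes))
    as.integer(as.character(classes) == "single") else as.integer(classes)
  if (length(unique(y)) < 2)
    stop("both oscillator classes must be present")
  if (length(y) < 10) stop("need at least 10 electrodes")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ap_fractions, family = stats::binomial()),
    warning = function(w) {
      sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  separated <- sep_warn && max(abs(co[, "Estimate"])) > 15
  list(beta0 = co[1, 1], beta1 = co[2, 1],
       p = if (separated) NA_real_ else co[2, 4],
       flagged = separated)
}

#' A-P frequency gradient correlation
#'
#' Pearson correlation between peak oscillation frequency and A-P
#' fraction, optionally stratified by hemisphere.  Strata with fewer than
#' `n_min` electrodes are skipped with a warning.
#'
#' @param table data frame with `peak_hz`, `ap_fraction` and (for
#'   stratified output) `hemisphere`.
#' @param by strata to evaluate: any of `"all"`, `"L"`, `"R"`.
#' @param n_min minimum electrodes per stratum.
#' @return data frame `stratum`, `r`, `p`, `n`.
#' @export
gradient_correlation <- function(table, by = c("all", "L", "R"), n_min = 3) {
  out <- list()
  for (stratum in by) {
    d <- if (stratum == "all") table else
      table[table$hemisphere == stratum, , drop = FALSE]
    if (nrow(d) < n_min) {
      warning("stratum ", stratum, " skipped: fewer than ", n_min,
              " electrodes")
      next
    }
    ct <- stats::cor.test(d$ap_fraction, d$peak_hz, method = "pearson")
    out[[stratum]] <- data.frame(stratum = stratum,
                                 r = unname(ct$estimate),
                                 p = ct$p.value, n = nrow(d))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hemisphere and subregion comparisons
#'
#' Three standard checks of anatomical balance and lateralization:
#' an unpaired t-test of peak frequency between left and right
#' hemispheres, a Wilcoxon rank-sum test of electrode A-P positions
#' between hemispheres, and a one-way ANOVA of peak frequency across
#' hippocampal subregions.
#'
#' @param table data frame with `peak_hz`, `ap_fraction`, `hemisphere`,
#'   `subregion`.
#' @return list: `freq_t` (htest), `position_ranksum` (htest),
#'   `subregion_anova` (list `F`, `df`, `p`).
#' @export
hemisphere_tests <- function(table) {
  if (length(unique(table$hemisphere)) < 2)
    stop("both hemispheres must be represented")
  l <- table[table$hemisphere == "L", ]
  r <- table[table$hemisphere == "R", ]
  freq_t <- stats::t.test(l$peak_hz, r$peak_hz, var.equal = TRUE)
  ranksum <- stats::wilcox.test(l$ap_fraction, r$ap_fraction, exact = FALSE)
  av <- stats::aov(peak_hz ~ subregion, data = table)
  s <- summary(av)[[1]]
  list(freq_t = freq_t, position_ranksum = ranksum,
       subregion_anova = list(F = s[["F value"]][1],
                              df = c(s[["Df"]][1], s[["Df"]][2]),
                              p = s[["Pr(>F)"]][1]))
}

#' Two-way ANOVA of speed-frequency prevalence across region and band
#'
#' Factorial ANOVA with interaction on subject-level cell values (one
#' value per subject x region x band cell, e.g. each subject's fraction of
#' electrodes with a significant positive speed-frequency correlation).
#' Type II sums of squares accommodate unbalanced tables.
#'
#' @param cells data frame with `value`, `region`
#'   (anterior/posterior), `band` (low/high) and optionally `subject_id`.
#' @return data frame `term`, `F`, `df`, `p` for region, band and their
#'   interaction; attribute `flagged` is `TRUE` when all values are
#'   identical (degenerate).
#' @export
speedfreq_anova <- function(cells) {
  stopifnot(all(c("value", "region", "band") %in% names(cells)))
  if (stats::var(cells$value) == 0) {
    out <- data.frame(term = c("region", "band", "region:band"),
                      F = NA_real_, df = NA_real_, p = NA_real_)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  cells$region <- factor(cells$region)
  cells$band <- factor(cells$band)
  fit <- stats::lm(value ~ region * band, data = cells)
  a2 <- car::Anova(fit, type = 2)
  terms <- c("region", "band", "region:band")
  out <- data.frame(term = terms,
                    F = a2[terms, "F value"],
                    df = a2[terms, "Df"],
                    p = a2[terms, "Pr(>F)"])
  attr(out, "flagged") <- FALSE
  rownames(out) <- NULL
  out
}

#' Permutation test for a harmonic relation at dual oscillators
#'
#' Tests whether the high- and low-theta frequencies of dual oscillators
#' are correlated (as they would be if the fast band were a harmonic of
#' the slow one).  The observed Pearson r across electrodes is compared
#' against a null built by shuffling the high-frequency assignment, with
#' the add-one two-sided p convention.
#'
#' @param f_low,f_high paired frequencies (Hz), one entry per dual
#'   oscillator.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list: `r`, `p`, `n_perm`.
#' @export
harmonic_permutation_test <- function(f_low, f_high, n_perm = 10000,
                                      seed = 1) {
  stopifnot(length(f_low) == length(f_high))
  n <- length(f_low)
  if (n < 5) stop("need at least 5 dual-oscillator pairs")
  r_obs <- stats::cor(f_low, f_high)
  set.seed(as.integer(seed))
  r_perm <- replicate(n_perm, stats::cor(f_low, sample(f_high)))
  p <- (1 + sum(abs(r_perm) >= abs(r_obs))) / (n_perm + 1)
  list(r = r_obs, p = p, n_perm = n_perm)
}

#' Co-occurrence of the two oscillations at dual oscillators
#'
#' Per electrode, the statistic is the excess joint presence probability
#' `P(both present) - P(low) * P(high)`; positive values mean the two
#' bands tend to occur simultaneously.  The group-level test is a
#' two-sided Wilcoxon signed-rank of the per-electrode statistics against
#' zero.  Electrodes with zero presence in either band are excluded with a
#' warning.
#'
#' @param mask_pairs list of electrodes; each element a list with logical
#'   vectors `low` and `high` (presence masks of equal length).
#' @return list: `statistics` (per electrode), `p` (signed-rank), `n`.
#' @export
cooccurrence_test <- function(mask_pairs) {
  stats_vec <- numeric(0)
  for (mp in mask_pairs) {
    stopifnot(length(mp$low) == length(mp$high))
    p_lo <- mean(mp$low); p_hi <- mean(mp$high)
    if (p_lo == 0 || p_hi == 0) {
      warning("electrode with zero presence in one band excluded")
      next
    }
    stats_vec <- c(stats_vec, mean(mp$low & mp$high) - p_lo * p_hi)
  }
  if (!length(stats_vec))
    return(list(statistics = numeric(0), p = NA_real_, n = 0L))
  wt <- stats::wilcox.test(stats_vec, mu = 0, exact = TRUE)
  list(statistics = stats_vec, p = wt$p.value, n = length(stats_vec))
}
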