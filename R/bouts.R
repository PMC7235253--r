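#' Extract oscillatory bouts from a gated presence mask
#'
#' A bout is a maximal run of consecutive samples during which the
#' oscillation is present.  Its frequency is the mean instantaneous
#' frequency over the run and its length in cycles is duration times that
#' mean frequency.  Runs shorter than `min_samples` samples are dropped as
#' numerically meaningless.
#'
#' @param trace a gated `osc_trace`.
#' @param electrode_id,label identifiers copied into the output.
#' @param min_samples minimum run length in samples.
#' @return data frame: `electrode_id`, `label`, `start_s`, `end_s`,
#'   `mean_freq_hz`, `n_cycles` (zero rows when nothing is present).
#' @export
extract_bouts <- function(trace, electrode_id = NA_character_,
                          label = NA_character_, min_samples = 2) {
  fs <- trace$fs
  r <- rle(as.logical(trace$presence))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & r$lengths >= min_samples
  if (!any(sel))
    return(data.frame(electrode_id = character(), label = character(),
                      start_s = numeric(), end_s = numeric(),
                      mean_freq_hz = numeric(), n_cycles = numeric()))
  s <- starts[sel]; e <- ends[sel]
  mf <- vapply(seq_along(s), function(i)
    mean(trace$inst_freq[s[i]:e[i]]), numeric(1))
  dur <- (e - s + 1L) / fs
  data.frame(electrode_id = electrode_id, label = label,
             start_s = (s - 1L) / fs, end_s = e / fs,
             mean_freq_hz = mf, n_cycles = dur * mf,
             stringsAsFactors = FALSE)
}

#' Mean bout length in cycles per group
#'
#' @param bout_table from [extract_bouts()] (rows from several electrodes
#'   may be stacked).
#' @param by grouping columns, default electrode x band label.
#' @return data frame of group keys plus `mean_cycles` and `n_bouts`.
#' @export
mean_bout_cycles <- function(bout_table, by = c("electrode_id", "label")) {
  if (!nrow(bout_table))
    return(cbind(bout_table[0, by, drop = FALSE],
                 mean_cycles = numeric(0), n_bouts = integer(0)))
  agg <- stats::aggregate(bout_table$n_cycles,
                          by = bout_table[by], FUN = mean)
  names(agg)[ncol(agg)] <- "mean_cycles"
  cnt <- stats::aggregate(bout_table$n_cycles,
                          by = bout_table[by], FUN = length)
  agg$n_bouts <- cnt$x
  agg
}

#' Average values from nearby electrodes
#'
#' Electrodes of one subject lying within `radius` of each other along the
#' A-P axis (transitive closure) contribute a single averaged value, so a
#' subject with a tight cluster of contacts is not over-counted in group
#' statistics.
#'
#' @param values numeric vector, one per electrode.
#' @param ap_fractions A-P positions, same length.
#' @param radius clustering radius (A-P fraction).
#' @return data frame `value` (cluster means), `ap_fraction` (cluster mean
#'   positions), `n_electrodes`.
#' @export
average_nearby <- function(values, ap_fractions, radius = 0.10) {
  stopifnot(length(values) == length(ap_fractions))
  n <- length(values)
  if (n == 0)
    return(data.frame(value = numeric(), ap_fraction = numeric(),
                      n_electrodes = integer()))
  ord <- order(ap_fractions)
  cluster <- integer(n)
  cl <- 1L
  cluster[ord[1]] <- cl
  if (n > 1) {
    for (i in 2:n) {
      if (ap_fractions[ord[i]] - ap_fractions[ord[i - 1]] >= radius) cl <- cl + 1L
      cluster[ord[i]] <- cl
    }
  }
  data.frame(
    value = as.numeric(tapply(values, cluster, mean)),
    ap_fraction = as.numeric(tapply(ap_fractions, cluster, mean)),
    n_electrodes = as.integer(tapply(values, cluster, length)))
}

#' Compare mean bout cycles between two groups
#'
#' Two-sample pooled-variance t-test (two-sided), matching integer
#' degrees of freedom `n1 + n2 - 2`.  When both groups are constant and
#' equal the statistic is 0 and p is 1 by convention.
#'
#' @param x,y numeric vectors of per-electrode (or per-site) mean cycles.
#' @return list: `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
compare_bout_groups <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need at least 2 values per group")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  df <- n1 + n2 - 2
  if (sp2 == 0) {
    t <- if (mean(x) == mean(y)) 0 else Inf * sign(mean(x) - mean(y))
    p <- if (t == 0) 1 else 0
  } else {
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(t = t, df = df, p = p, mean_x = mean(x), mean_y = mean(y))
}
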