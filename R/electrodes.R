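#' Normalize an electrode's anterior-posterior position
#'
#' Maps the MRI slice containing an electrode onto the \[0, 1\] hippocampal
#' axis, 0 being the anterior tip and 1 the posterior tip.
#'
#' @param slice_index coronal slice containing the contact.
#' @param first_slice,last_slice first and last slices containing the
#'   hippocampus.
#' @return A-P fraction in \[0, 1\].
#' @examples
#' normalize_ap(25, 20, 60)  # 0.125
#' @export
normalize_ap <- function(slice_index, first_slice, last_slice) {
  if (first_slice >= last_slice)
    stop("first_slice must be smaller than last_slice")
  if (any(slice_index < first_slice | slice_index > last_slice))
    stop("slice_index outside [first_slice, last_slice]")
  (slice_index - first_slice) / (last_slice - first_slice)
}

#' Split the hippocampal axis into anterior and posterior
#'
#' @param ap_fraction A-P fraction in \[0, 1\].
#' @param cut division point; positions at or beyond it are posterior.
#' @return character vector, `"anterior"` or `"posterior"`.
#' @export
split_region <- function(ap_fraction, cut = 0.40) {
  stopifnot(all(ap_fraction >= 0 & ap_fraction <= 1))
  ifelse(ap_fraction >= cut, "posterior", "anterior")
}

#' Classify an electrode as a single or dual oscillator
#'
#' An electrode with two detected bands whose nearest edges differ by at
#' least `min_gap` Hz is a dual oscillator; otherwise the bands are merged
#' (span of their union) and the electrode is a single oscillator.  Band
#' labels follow the peak frequency: low theta below 4 Hz, high theta at
#' or above 4 Hz.  If more than two bands are supplied, the two with the
#' largest peak power are kept.  Zero bands yields a flagged record
#' (class `"none"`) to be excluded from analyses.
#'
#' @param bands data frame with `f_lo`, `f_hi`, `peak_freq` (optionally
#'   `peak_power`).
#' @param min_gap minimum edge separation (Hz) for a dual oscillator.
#' @param low_high_cut peak-frequency boundary between low and high theta.
#' @return list: `class` (`"single"`, `"dual"` or `"none"`), `bands`
#'   (possibly merged, with a `label` column), `flagged`.
#' @examples
#' classify_oscillator(data.frame(f_lo = c(2.5, 6), f_hi = c(3.5, 9),
#'                                peak_freq = c(3, 8)))
#' @export
classify_oscillator <- function(bands, min_gap = 0.5, low_high_cut = 4) {
  if (is.null(bands) || nrow(bands) == 0)
    return(list(class = "none",
                bands = cbind(bands[0, , drop = FALSE],
                              label = character(0)),
                flagged = TRUE))
  bands <- bands[order(bands$f_lo), , drop = FALSE]
  if (nrow(bands) > 2) {
    # rank by elevation above the 1/f fit where available: raw power
    # always favors the lowest-frequency band on a 1/f spectrum
    strength <- if (!is.null(bands$peak_elev)) bands$peak_elev
                else bands$peak_power
    if (is.null(strength))
      stop("more than two bands require peak_elev or peak_power to rank them")
    keep <- order(strength, decreasing = TRUE)[1:2]
    bands <- bands[sort(keep), , drop = FALSE]
  }
  if (nrow(bands) == 2) {
    gap <- bands$f_lo[2] - bands$f_hi[1]
    if (gap >= min_gap) {
      cls <- "dual"
    } else {
      # span of the union; keep the peak of the wider constituent
      wider <- which.max(bands$f_hi - bands$f_lo)
      bands <- data.frame(f_lo = bands$f_lo[1], f_hi = bands$f_hi[2],
                          peak_freq = bands$peak_freq[wider],
                          peak_power = if (!is.null(bands$peak_power))
                            max(bands$peak_power) else NA_real_,
                          peak_elev = if (!is.null(bands$peak_elev))
                            max(bands$peak_elev) else NA_real_)
      cls <- "single"
    }
  } else {
    cls <- "single"
  }
  bands$label <- ifelse(bands$peak_freq < low_high_cut, "low", "high")
  rownames(bands) <- NULL
  list(class = cls, bands = bands, flagged = FALSE)
}

#' Drop redundant nearby electrodes with similar oscillation frequencies
#'
#' Within each (subject, hemisphere) group, electrodes closer than
#' `ap_radius` along the A-P axis whose band peak frequencies agree within
#' `freq_tol` Hz (any band pair, for dual oscillators) are considered
#' redundant: the relation is closed transitively and only the electrode
#' with the lowest `electrode_id` in each cluster is kept.
#'
#' @param records data frame with columns `subject_id`, `hemisphere`,
#'   `electrode_id`, `ap_fraction`, and `peak_freqs` (list column of
#'   numeric vectors, one entry per band).
#' @param ap_radius A-P distance (fraction) below which electrodes count
#'   as nearby.
#' @param freq_tol frequency agreement tolerance (Hz).
#' @return the filtered data frame (original row order preserved).
#' @export
deduplicate_electrodes <- function(records, ap_radius = 0.10, freq_tol = 2) {
  stopifnot(all(c("subject_id", "hemisphere", "electrode_id",
                  "ap_fraction", "peak_freqs") %in% names(records)))
  drop <- rep(FALSE, nrow(records))
  grp <- interaction(records$subject_id, records$hemisphere, drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2) next
    # union-find over the redundancy relation
    parent <- seq_along(idx)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a >= b) next
      ia <- idx[a]; ib <- idx[b]
      if (abs(records$ap_fraction[ia] - records$ap_fraction[ib]) >= ap_radius)
        next
      fa <- records$peak_freqs[[ia]]; fb <- records$peak_freqs[[ib]]
      if (any(abs(outer(fa, fb, "-")) <= freq_tol)) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
    roots <- vapply(seq_along(idx), find, integer(1))
    for (r in unique(roots)) {
      members <- idx[roots == r]
      if (length(members) > 1) {
        keep <- members[order(records$electrode_id[members])][1]
        drop[setdiff(members, keep)] <- TRUE
      }
    }
  }
  records[!drop, , drop = FALSE]
}
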