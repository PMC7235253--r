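#' Re-reference a multichannel recording
#'
#' @param rec a [recording()].
#' @param scheme `"common_average"` (subtract the cross-channel mean per
#'   sample), `"none"` (identity), or `"weighted"` (subtract a weighted
#'   cross-channel mean; weights are normalized to sum to 1).
#' @param weights per-channel weight vector for `scheme = "weighted"`.
#' @return a re-referenced [recording()].
#' @export
rereference <- function(rec, scheme = c("common_average", "none", "weighted"),
                        weights = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(rec, "recording"), ncol(rec$signals) >= 1)
  if (scheme == "none") return(rec)
  if (scheme == "common_average") {
    ref <- rowMeans(rec$signals)
  } else {
    if (is.null(weights) || length(weights) != ncol(rec$signals))
      stop("weights must match the number of channels")
    w <- weights / sum(weights)
    ref <- as.vector(rec$signals %*% w)
  }
  rec$signals <- rec$signals - ref
  rec
}

#' Zero-phase Butterworth notch filter for line noise
#'
#' A 4th-order Butterworth band-stop (default 58-62 Hz) applied
#' forward-backward (`filtfilt`), so passband components suffer no phase
#' distortion.
#'
#' @param rec a [recording()].
#' @param freq notch center frequency (Hz), default 60.
#' @param half_width half-width of the stopband (Hz).
#' @param order Butterworth order.
#' @return filtered [recording()].
#' @export
notch_filter <- function(rec, freq = 60, half_width = 2, order = 4) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$fs / 2
  if (freq >= nyq) stop("notch frequency must be below the Nyquist frequency")
  lo <- max(freq - half_width, 0.1)
  hi <- min(freq + half_width, nyq * 0.99)
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "stop")
  rec$signals <- apply(rec$signals, 2, function(x)
    as.numeric(signal::filtfilt(bf, x)))
  rec
}

#' Flag putative artifact samples
#'
#' Marks samples whose amplitude z-score or first-difference (gradient)
#' z-score exceeds `z_thresh`, then dilates each flagged sample by
#' `dilate_s` seconds on both sides.  Masked samples are excluded from all
#' downstream PSD, presence and bout computations; sample values are never
#' altered.
#'
#' @param rec a [recording()].
#' @param z_thresh z-score threshold (amplitude and gradient).
#' @param dilate_s dilation half-width in seconds.
#' @return logical matrix (samples x channels), `TRUE` = excluded.
#' @export
exclude_artifacts <- function(rec, z_thresh = 5, dilate_s = 0.25) {
  stopifnot(inherits(rec, "recording"), nrow(rec$signals) > 0)
  half <- round(dilate_s * rec$fs)
  mask <- apply(rec$signals, 2, function(x) {
    s <- stats::sd(x)
    if (s == 0) {
      warning("constant channel: empty artifact mask")
      return(rep(FALSE, length(x)))
    }
    za <- abs(x - mean(x)) / s
    d <- c(0, diff(x))
    sd_d <- stats::sd(d)
    zg <- if (sd_d > 0) abs(d - mean(d)) / sd_d else rep(0, length(x))
    bad <- za > z_thresh | zg > z_thresh
    dilate_mask(bad, half)
  })
  matrix(mask, nrow = nrow(rec$signals),
         dimnames = list(NULL, rec$channel_ids))
}

# binary dilation of a logical vector by `half` samples on each side
# (interval-coverage trick, O(n))
dilate_mask <- function(bad, half) {
  if (!any(bad) || half == 0) return(bad)
  n <- length(bad)
  idx <- which(bad)
  lo <- pmax(1L, idx - half)
  hi <- pmin(n, idx + half)
  cover <- cumsum(tabulate(lo, n + 1L) - tabulate(hi + 1L, n + 1L))
  cover[seq_len(n)] > 0
}

#' Run-length encode an artifact mask as JSON
#'
#' @param mask logical matrix from [exclude_artifacts()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask_json <- function(mask, path) {
  enc <- lapply(seq_len(ncol(mask)), function(j) {
    r <- rle(as.logical(mask[, j]))
    list(lengths = r$lengths, values = r$values)
  })
  names(enc) <- colnames(mask)
  jsonlite::write_json(enc, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
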