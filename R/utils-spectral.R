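#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Returns the complex analytic signal `x + i*H(x)` of a real vector, from
#' which instantaneous phase (`Arg`) and amplitude (`Mod`) are read off.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n0 <- length(x)
  if (n0 < 2L) stop("signal too short for analytic transform")
  # pad to a highly composite length: R's mixed-radix FFT degrades badly
  # on lengths with large prime factors
  n <- stats::nextn(n0, c(2, 3, 5))
  if (n > n0) x <- c(x, numeric(n - n0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  a <- stats::fft(X * h, inverse = TRUE) / n
  a[seq_len(n0)]
}

#' Unwrap a phase sequence
#'
#' Adds multiples of 2*pi so successive differences stay within (-pi, pi].
#' @param p numeric vector of wrapped phases (radians).
#' @return unwrapped phase vector.
#' @keywords internal
unwrap_phase <- function(p) {
  d <- diff(p)
  jumps <- -round(d / (2 * pi))
  p + c(0, cumsum(jumps)) * 2 * pi
}

# Welch power spectral density with Hann windows, optional artifact mask.
# Only full windows drawn from contiguous unmasked runs contribute.  The FFT
# is zero-padded so the frequency grid has spacing `df` Hz.
welch_psd <- function(x, fs, win_s = 4, overlap = 0.5, df = 0.1,
                      mask = NULL, fmin = 1, fmax = 30) {
  n <- length(x)
  if (is.null(mask)) mask <- rep(FALSE, n)
  stopifnot(length(mask) == n)
  L <- round(win_s * fs)
  step <- max(1L, round(L * (1 - overlap)))
  nfft <- max(L, round(fs / df))
  w <- signal::hanning(L)
  scale <- fs * sum(w^2)

  keep <- !mask
  runs <- rle(keep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  acc <- NULL
  nwin <- 0L
  for (k in seq_along(runs$values)) {
    if (!runs$values[k] || runs$lengths[k] < L) next
    s0 <- starts[k]
    offs <- seq(0L, runs$lengths[k] - L, by = step)
    for (o in offs) {
      seg <- x[(s0 + o):(s0 + o + L - 1L)]
      seg <- (seg - mean(seg)) * w
      X <- stats::fft(c(seg, numeric(nfft - L)))
      p <- Mod(X)^2 / scale
      acc <- if (is.null(acc)) p else acc + p
      nwin <- nwin + 1L
    }
  }
  if (nwin == 0L) stop("insufficient unmasked data for PSD estimation")
  p <- acc / nwin
  nhalf <- floor(nfft / 2)
  freq <- (0:nhalf) * fs / nfft
  p <- p[1:(nhalf + 1L)]
  # one-sided density: double everything except DC (and Nyquist when present)
  dbl <- rep(2, nhalf + 1L)
  dbl[1L] <- 1
  if (nfft %% 2L == 0L) dbl[nhalf + 1L] <- 1
  p <- p * dbl
  sel <- freq >= fmin & freq <= fmax
  structure(
    list(frequency = freq[sel], power = p[sel], fs = fs,
         win_s = win_s, n_windows = nwin),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf(
    "<power_spectrum> %d frequencies over %.1f-%.1f Hz (%d Welch windows of %gs)\n",
    length(x$frequency), min(x$frequency), max(x$frequency),
    x$n_windows, x$win_s))
  invisible(x)
}
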