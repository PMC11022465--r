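# Shared signal-processing primitives. Butterworth filtering delegates to
# the 'signal' package (zero-phase via filtfilt); the Welch periodogram and
# prominence-based peak picking are implemented here.

.butter_filt <- function(x, rate, cutoff, type) {
  w <- cutoff / (rate / 2)
  if (any(w <= 0) || any(w >= 1)) {
    stop("cutoff must lie inside (0, Nyquist)", call. = FALSE)
  }
  bf <- signal::butter(2, w, type = type)
  # odd-reflection padding so the zero-initial-condition transients of
  # filtfilt decay inside the pad, not inside the data
  n <- length(x)
  p <- min(n - 1L, ceiling(6 * rate / min(cutoff)))
  if (p > 0) {
    left <- 2 * x[1] - x[(p + 1):2]
    right <- 2 * x[n] - x[(n - 1):(n - p)]
    y <- as.numeric(signal::filtfilt(bf, c(left, x, right)))
    y[(p + 1):(p + n)]
  } else {
    as.numeric(signal::filtfilt(bf, x))
  }
}

lowpass_filter <- function(x, rate, cutoff = 0.25) {
  .butter_filt(x, rate, cutoff, "low")
}

bandpass_filter <- function(x, rate, lo = 0.5, hi = 3) {
  .butter_filt(x, rate, c(lo, hi), "pass")
}

moving_average <- function(x, width) {
  w <- max(1L, as.integer(width))
  f <- stats::filter(x, rep(1 / w, w), sides = 2)
  f[is.na(f)] <- x[is.na(f)]
  as.numeric(f)
}

#' Find local maxima by topographic prominence
#'
#' Local maxima whose prominence (height above the higher of the two
#' saddle minima separating the peak from higher terrain) reaches
#' `prominence`, thinned so that retained peaks are at least `min_sep`
#' seconds apart (keeping the higher of two close peaks).
#'
#' @param x numeric signal.
#' @param rate sampling rate in Hz.
#' @param prominence minimum prominence (signal units).
#' @param min_sep minimum separation between retained peaks (s).
#' @param min_height minimum peak height; defaults to `prominence` so that
#'   small fluctuations sitting between deep valleys are not picked up.
#' @return Integer vector of peak sample indices.
#' @export
find_signal_peaks <- function(x, rate, prominence = 0.5, min_sep = 0.4,
                              min_height = prominence) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    p <- cand[i]; h <- x[p]
    l <- p
    while (l > 1 && x[l] <= h) l <- l - 1L
    lmin <- if (x[l] > h) min(x[l:p]) else min(x[1:p])
    r <- p
    while (r < n && x[r] <= h) r <- r + 1L
    rmin <- if (x[r] > h) min(x[p:r]) else min(x[p:n])
    keep[i] <- (h - max(lmin, rmin)) >= prominence
  }
  pk <- cand[keep]
  if (length(pk) > 1) {
    res <- pk[1]
    for (p in pk[-1]) {
      if ((p - res[length(res)]) / rate >= min_sep) {
        res <- c(res, p)
      } else if (x[p] > x[res[length(res)]]) {
        res[length(res)] <- p
      }
    }
    pk <- res
  }
  pk
}

#' Welch power spectral density
#'
#' Averaged modified periodogram with Hamming windows and 50% overlap.
#' Scaling is such that the integral of the density over frequency equals
#' the signal variance (density normalization), so a sinusoid of amplitude
#' A concentrates power A^2/2 around its frequency.
#'
#' @param x numeric signal (demeaned internally).
#' @param rate sampling rate in Hz.
#' @param nperseg segment length in samples (default: 8 segments).
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, rate, nperseg = NULL) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- max(64L, 2L^floor(log2(n / 4)))
  nperseg <- min(nperseg, n)
  x <- x - mean(x)
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  u <- sum(w^2)
  acc <- numeric(floor(nperseg / 2) + 1L)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg))^2
    acc <- acc + sp[seq_along(acc)]
  }
  psd <- acc / (length(starts) * u * rate)
  # one-sided: double all bins except DC (and Nyquist if present)
  psd[-1] <- 2 * psd[-1]
  if (nperseg %% 2 == 0) psd[length(psd)] <- psd[length(psd)] / 2
  freq <- (seq_along(psd) - 1) * rate / nperseg
  list(freq = freq, psd = psd)
}

# amplitude of the harmonic at frequency f0 via local DFT projection
harmonic_amplitude <- function(x, rate, f0) {
  n <- length(x)
  t <- (seq_len(n) - 1) / rate
  x <- x - mean(x)
  2 * sqrt(mean(x * cos(2 * pi * f0 * t))^2 +
             mean(x * sin(2 * pi * f0 * t))^2)
}
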