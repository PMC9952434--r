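#' Time-domain HRV indices
#'
#' Mean RR over unflagged intervals and the corresponding heart rate.
#'
#' @param tach A [tachogram()].
#' @return Named list `mean_rr` (ms) and `hr` (bpm = 60000 / mean RR).
#' @export
time_domain <- function(tach) {
  stopifnot(inherits(tach, "tachogram"))
  rr <- tach$rr_ms[!tach$ectopic]
  if (length(rr) < 2) abort_typed("cardiovag_no_beats", "fewer than 2 valid intervals")
  m <- mean(rr)
  list(mean_rr = m, hr = 60000 / m)
}

#' Power spectral density of the RR series
#'
#' Ectopic-flagged intervals are removed, the remaining RR values are
#' resampled on an even grid by cubic spline (the spline bridges the gaps),
#' linearly detrended, Hann-windowed and transformed with a single-segment
#' FFT periodogram. Normalization is Parseval-consistent: the integral of
#' the one-sided PSD equals the (window-weighted) variance of the detrended
#' series.
#'
#' @param tach A [tachogram()].
#' @param resample_fs Even-sampling rate for the RR series (Hz).
#' @param lf_band,hf_band Frequency bands (Hz) integrated for the LF and HF
#'   powers.
#' @return Object of class `spectral_result`: `frequencies` (Hz), `psd`
#'   (ms^2/Hz), `lf_power`, `hf_power` (ms^2), `lf_hf_ratio` (NA with
#'   attribute `undefined` when HF power is zero) and `meta`.
#' @export
rr_psd <- function(tach, resample_fs = 4,
                   lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.40)) {
  stopifnot(inherits(tach, "tachogram"))
  keep <- !tach$ectopic
  t <- tach$t_s[keep]
  rr <- tach$rr_ms[keep]
  span <- diff(range(t))
  if (span < 30) abort_typed("cardiovag_too_short", "RR series spans less than 30 s")
  if (span < 60) warn_typed("cardiovag_quality", "RR series spans less than 60 s; LF resolution is marginal")
  if (length(rr) < 30) abort_typed("cardiovag_too_short", "fewer than 30 valid intervals")

  grid <- seq(t[1], t[length(t)], by = 1 / resample_fs)
  x <- stats::spline(t, rr, xout = grid, method = "fmm")$y
  x <- stats::lm.fit(cbind(1, seq_along(x)), x)$residuals
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  xw <- x * w
  X <- stats::fft(xw)
  nf <- floor(n / 2) + 1
  psd <- (abs(X[seq_len(nf)])^2) / (resample_fs * sum(w^2))
  # one-sided doubling (DC and Nyquist are unique)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[nf] <- 1
  psd <- psd * dbl
  freq <- (seq_len(nf) - 1) * resample_fs / n

  res <- structure(
    list(frequencies = freq, psd = psd,
         lf_power = NA_real_, hf_power = NA_real_, lf_hf_ratio = NA_real_,
         meta = list(resample_fs = resample_fs, window = "hann",
                     detrend = "linear", n = n, span_s = span,
                     lf_band = lf_band, hf_band = hf_band,
                     detrended_var = stats::var(x))),
    class = "spectral_result"
  )
  res$lf_power <- band_power(res, lf_band)
  res$hf_power <- band_power(res, hf_band)
  if (res$hf_power > 0) {
    res$lf_hf_ratio <- res$lf_power / res$hf_power
  } else {
    attr(res$lf_hf_ratio, "undefined") <- TRUE
  }
  res
}

#' Integrate a PSD over a frequency band
#'
#' Trapezoidal integration with the band edges interpolated onto the PSD
#' grid, so powers are additive over disjoint bands sharing an edge.
#'
#' @param spec A `spectral_result` from [rr_psd()].
#' @param band Numeric length-2: `c(f1, f2)` in Hz.
#' @return Band power (ms^2).
#' @export
band_power <- function(spec, band) {
  stopifnot(inherits(spec, "spectral_result"), length(band) == 2)
  f <- spec$frequencies
  p <- spec$psd
  lo <- max(band[1], f[1])
  hi <- min(band[2], f[length(f)])
  if (hi <= lo) {
    warn_typed("cardiovag_quality", "empty frequency band; returning 0")
    return(0)
  }
  inner <- f > lo & f < hi
  fx <- c(lo, f[inner], hi)
  px <- c(stats::approx(f, p, xout = lo)$y, p[inner], stats::approx(f, p, xout = hi)$y)
  sum(diff(fx) * (head(px, -1) + tail(px, -1)) / 2)
}
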