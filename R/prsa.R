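#' Anchor points by the increment rule
#'
#' An anchor is a sample strictly larger than its predecessor (for an RR
#' series: a beat-to-beat deceleration). Anchors within `L` samples of
#' either end are discarded, since a full two-sided window cannot be formed;
#' anchors whose window contains a flagged sample are discarded too.
#'
#' @param series Numeric beat-indexed series.
#' @param L Half-window length (beats).
#' @param flags Optional logical vector: samples to keep out of any window
#'   (e.g. ectopic intervals).
#' @return Integer anchor indices (possibly empty).
#' @export
find_anchors_increment <- function(series, L, flags = NULL) {
  n <- length(series)
  if (n < 2) abort_typed("cardiovag_bad_input", "series too short")
  idx <- which(series[-1] > series[-n]) + 1L
  filter_anchors(idx, n, L, flags)
}

#' Anchor points by the averaged-comparison rule
#'
#' A sample i is an anchor when the mean of the `M` values starting at i
#' (inclusive) strictly exceeds the mean of the `M` values before i:
#' `mean(x[i..i+M-1]) > mean(x[i-M..i-1])`. Used for the repolarization
#' branch with `M = 9`. Edge and flag exclusions as in
#' [find_anchors_increment()].
#'
#' @param series Numeric beat-indexed series.
#' @param M Averaging span (beats).
#' @param L Half-window length (beats).
#' @param flags Optional logical exclusion vector.
#' @return Integer anchor indices (possibly empty).
#' @export
find_anchors_averaged <- function(series, M, L, flags = NULL) {
  n <- length(series)
  if (n < 2 * M + 1) abort_typed("cardiovag_bad_input", "series shorter than 2M + 1")
  cs <- c(0, cumsum(series))
  cand <- seq(M + 1L, n - M + 1L)
  fwd <- (cs[cand + M] - cs[cand]) / M        # mean over i .. i+M-1
  bwd <- (cs[cand] - cs[cand - M]) / M        # mean over i-M .. i-1
  idx <- cand[fwd > bwd]
  filter_anchors(idx, n, L, flags)
}

# shared edge/flag exclusion: window of anchor a spans a-L .. a+L-1
filter_anchors <- function(idx, n, L, flags) {
  idx <- idx[idx - L >= 1L & idx + L - 1L <= n]
  if (!is.null(flags) && any(flags)) {
    bad <- which(flags)
    idx <- idx[vapply(idx, function(a) !any(bad >= a - L & bad <= a + L - 1L), logical(1))]
  }
  as.integer(idx)
}

#' Phase-rectified signal averaging
#'
#' Aligns the `2L`-sample windows around all anchors and averages them
#' pointwise: `curve[k] = mean over anchors a of series[a + k]` for
#' `k = -L .. L-1` (anchor at `k = 0`).
#'
#' @param series Numeric beat-indexed series.
#' @param anchors Integer anchor indices (each with a full window inside the
#'   series).
#' @param L Half-window length.
#' @return Object of class `prsa_result`: `curve` (length `2L`), `k`
#'   (offsets `-L .. L-1`), `anchor_count`, `anchors`, `defined`.
#' @export
prsa_average <- function(series, anchors, L) {
  k <- seq(-L, L - 1L)
  if (length(anchors) == 0) {
    return(structure(list(curve = rep(NA_real_, 2 * L), k = k,
                          anchor_count = 0L, anchors = integer(0),
                          defined = FALSE, L = L),
                     class = "prsa_result"))
  }
  if (any(anchors - L < 1L) || any(anchors + L - 1L > length(series))) {
    abort_typed("cardiovag_bad_input", "anchor without a full 2L window")
  }
  win <- outer(anchors, k, `+`)
  curve <- colMeans(matrix(series[win], nrow = length(anchors)))
  structure(list(curve = curve, k = k, anchor_count = length(anchors),
                 anchors = as.integer(anchors), defined = TRUE, L = L),
            class = "prsa_result")
}

#' @export
print.prsa_result <- function(x, ...) {
  cat(sprintf("<prsa_result> L = %d, %d anchors%s\n", x$L, x$anchor_count,
              if (!x$defined) " (undefined curve)" else ""))
  invisible(x)
}

curve_at <- function(res, k) res$curve[match(k, res$k)]

#' Deceleration capacity from a PRSA curve
#'
#' `DC = (X0 + X1 - X_-1 - X_-2) / 4`, where X0 is the curve value at the
#' anchor, X1 the value immediately after, and X_-1, X_-2 the two values
#' before.
#'
#' @param res A `prsa_result` with `L >= 2`.
#' @return DC in the units of the input series (ms for an RR series), or
#'   `NA` when the curve is undefined.
#' @export
deceleration_capacity <- function(res) {
  stopifnot(inherits(res, "prsa_result"))
  if (!res$defined) return(NA_real_)
  if (res$L < 2) abort_typed("cardiovag_bad_input", "DC needs L >= 2")
  (curve_at(res, 0) + curve_at(res, 1) - curve_at(res, -1) - curve_at(res, -2)) / 4
}

#' Oscillation amplitude (max minus min) of a PRSA curve
#'
#' The headline scalar of the repolarization branch: the amplitude of the
#' averaged oscillation, `max(curve) - min(curve)`.
#'
#' @param res A `prsa_result`.
#' @return Non-negative amplitude in the units of the input series (degrees
#'   for a T-angle series), or `NA` when the curve is undefined.
#' @export
prd_from_curve <- function(res) {
  stopifnot(inherits(res, "prsa_result"))
  if (!res$defined) return(NA_real_)
  max(res$curve) - min(res$curve)
}

#' Deceleration capacity of heart rate from a tachogram
#'
#' Increment-rule anchors on the RR series (windows containing an ectopic
#' interval dropped), PRSA with half-window `L`, then the DC statistic.
#'
#' @param tach A [tachogram()].
#' @param L Half-window length (default 12, resolving the 0.04--0.15 Hz
#'   oscillations of interest).
#' @param exclude_prolongation_frac Optional artifact guard: anchors whose
#'   RR prolongation exceeds this fraction are dropped (off by default).
#' @return List with `dc` (ms), `prsa` (the `prsa_result`).
#' @export
dc_from_tachogram <- function(tach, L = 12, exclude_prolongation_frac = NULL) {
  stopifnot(inherits(tach, "tachogram"))
  rr <- tach$rr_ms
  anchors <- find_anchors_increment(rr, L, flags = tach$ectopic)
  if (!is.null(exclude_prolongation_frac) && length(anchors)) {
    ok <- rr[anchors] / rr[anchors - 1L] <= 1 + exclude_prolongation_frac
    anchors <- anchors[ok]
  }
  res <- prsa_average(rr, anchors, L)
  list(dc = deceleration_capacity(res), prsa = res)
}
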