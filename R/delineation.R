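#' Detect R peaks on the vectorcardiogram
#'
#' Energy-based detector in the Pan-Tompkins family, operating on the
#' spatial vector magnitude `sqrt(Vx^2 + Vy^2 + Vz^2)`: the squared
#' magnitude is smoothed with a short moving average, compared against an
#' adaptive threshold (a fraction of the rolling local maximum), and each
#' supra-threshold run is refined to the local magnitude maximum. A
#' physiological refractory period suppresses double detections.
#'
#' @param vcg A [vcg_signal()].
#' @param refractory_s Minimum separation between accepted peaks (s).
#' @param threshold_frac Threshold as a fraction of the rolling maximum.
#' @param smooth_ms Moving-average width for the energy signal (ms).
#' @param search_s Span of the rolling-maximum window (s).
#' @return Integer vector of strictly increasing R-peak sample indices.
#' @export
detect_r_peaks <- function(vcg, refractory_s = 0.25, threshold_frac = 0.4,
                           smooth_ms = 15, search_s = 2) {
  stopifnot(inherits(vcg, "vcg_signal"))
  fs <- vcg$fs
  n <- length(vcg$v_x)
  if (n < 10 * fs) abort_typed("cardiovag_too_short", "need at least 10 s of signal")
  mag <- vcg_magnitude(vcg)
  if (max(mag) == 0) abort_typed("cardiovag_no_beats", "no beats: signal is identically zero")

  w <- max(1L, ms_to_samples(smooth_ms, fs))
  energy <- as.numeric(stats::filter(mag^2, rep(1 / w, w), sides = 2))
  energy[is.na(energy)] <- 0

  # adaptive threshold: fraction of the rolling local max (blocked rolling
  # max: each sample sees the max over its own and both neighbour blocks)
  bw <- max(1L, as.integer(round(search_s * fs / 2)))
  nb <- ceiling(n / bw)
  blk <- vapply(seq_len(nb), function(b) {
    max(energy[seq((b - 1) * bw + 1, min(b * bw, n))])
  }, numeric(1))
  blk_ext <- pmax(blk, c(blk[-1], blk[nb]), c(blk[1], blk[-nb]))
  thr <- threshold_frac * rep(blk_ext, each = bw)[seq_len(n)]

  above <- energy > thr
  if (!any(above)) abort_typed("cardiovag_no_beats", "no beats found above threshold")
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  peaks <- mapply(function(s, e) s - 1L + which.max(mag[s:e]), starts, ends)

  # refractory: keep the larger of any two peaks closer than refractory_s
  refr <- refractory_s * fs
  keep <- integer(0)
  for (p in peaks) {
    if (length(keep) == 0 || p - keep[length(keep)] >= refr) {
      keep <- c(keep, p)
    } else if (mag[p] > mag[keep[length(keep)]]) {
      keep[length(keep)] <- p
    }
  }
  if (length(keep) < 5) abort_typed("cardiovag_no_beats", "fewer than 5 beats found")
  as.integer(keep)
}

#' Build an RR tachogram from R-peak indices
#'
#' `rr_i = (r_i - r_{i-1}) * 1000 / fs` ms; beat times are cumulative from
#' the first interval.
#'
#' @param r_indices Strictly increasing R-peak sample indices.
#' @param fs Sampling rate (Hz).
#' @return A [tachogram()] (one row per interval).
#' @export
build_tachogram <- function(r_indices, fs) {
  if (length(r_indices) < 2) abort_typed("cardiovag_bad_input", "need at least 2 peaks")
  if (any(diff(r_indices) <= 0)) abort_typed("cardiovag_bad_input", "r_indices must be strictly increasing")
  rr <- diff(r_indices) * 1000 / fs
  tach <- tachogram(rr, t_s = (r_indices[-1] - r_indices[1]) / fs)
  attr(tach, "fs") <- fs
  attr(tach, "r_indices") <- as.integer(r_indices)
  tach
}

#' Flag ectopic intervals by the 20 % rule
#'
#' Sequential scan: interval i is flagged ectopic when it differs by more
#' than `threshold` (strict inequality) from the most recent unflagged
#' interval; flagged intervals do not update the reference. The reference
#' is initialized to the median of the first five intervals, so a recording
#' that happens to open on an ectopic interval cannot poison the scan.
#' Idempotent: re-running on its own output changes nothing.
#'
#' @param tach A [tachogram()].
#' @param threshold Relative deviation threshold (default 0.20).
#' @return The tachogram with its `ectopic` column set by the rule.
#' @export
flag_ectopic <- function(tach, threshold = 0.20) {
  stopifnot(inherits(tach, "tachogram"))
  rr <- tach$rr_ms
  n <- length(rr)
  flags <- logical(n)
  ref <- stats::median(utils::head(rr, 5))
  for (i in seq_len(n)) {
    if (abs(rr[i] - ref) / ref > threshold) {
      flags[i] <- TRUE
    } else {
      ref <- rr[i]
    }
  }
  if (mean(flags) > 0.20) {
    warn_typed("cardiovag_quality",
               sprintf("%.0f%% of intervals flagged ectopic", 100 * mean(flags)))
  }
  tach$ectopic <- flags
  tach
}

#' Assign per-beat T-wave windows
#'
#' QRS-anchored window rule: onset `Ton_i = QRS_i + 90 ms`; end
#' `Tend_i = QRS_i + min(360 ms, 2/3 RR_i)` for `RR_i < 720 ms`, and
#' `QRS_i + 360 ms` for `RR_i >= 720 ms`. The QRS mark is the R peak and
#' `RR_i` is the interval preceding beat i (both configurable). Beats whose
#' window would leave the recording or overlap the next QRS are marked
#' invalid, as is the first beat (no preceding RR).
#'
#' @param r_indices R-peak sample indices.
#' @param tach The [tachogram()] built from the same indices (for RR values
#'   and ectopic flags).
#' @param fs Sampling rate (Hz).
#' @param n_samples Recording length in samples.
#' @param config Delineation configuration block (see [default_config()]).
#' @return `beat_annotations` data.frame: `beat`, `r_sample`, `qrs_on`,
#'   `qrs_off`, `t_on`, `t_end`, `rr_ms`, `ectopic`, `valid`.
#' @export
assign_twave_windows <- function(r_indices, tach, fs, n_samples,
                                 config = default_config()$delineation) {
  nb <- length(r_indices)
  qrs_half <- ms_to_samples(config$qrs_halfwidth_ms, fs)
  # interval i of the tachogram ends at beat i+1; "preceding RR" of beat k
  # is interval k-1, "following" is interval k
  rr_of_beat <- rep(NA_real_, nb)
  ect_of_beat <- rep(FALSE, nb)
  if (identical(config$rr_mode, "preceding")) {
    rr_of_beat[-1] <- tach$rr_ms
    ect_of_beat[-1] <- tach$ectopic
  } else {
    rr_of_beat[-nb] <- tach$rr_ms
    ect_of_beat[-nb] <- tach$ectopic
  }
  t_on <- r_indices + ms_to_samples(config$twave_on_ms, fs)
  tend_ms <- ifelse(rr_of_beat < config$twave_rr_cut_ms,
                    pmin(config$twave_max_ms, config$twave_rr_frac * rr_of_beat),
                    config$twave_max_ms)
  t_end <- r_indices + vapply(tend_ms, function(m) {
    if (is.na(m)) NA_integer_ else ms_to_samples(m, fs)
  }, integer(1))
  next_qrs_on <- c(r_indices[-1] - qrs_half, n_samples + 1L)
  valid <- !is.na(t_end) & t_end <= n_samples & t_end < next_qrs_on & t_on < t_end
  structure(
    data.frame(beat = seq_len(nb), r_sample = as.integer(r_indices),
               qrs_on = as.integer(r_indices - qrs_half),
               qrs_off = as.integer(r_indices + qrs_half),
               t_on = as.integer(t_on), t_end = as.integer(t_end),
               rr_ms = rr_of_beat, ectopic = ect_of_beat,
               valid = valid & !is.na(valid)),
    class = c("beat_annotations", "data.frame")
  )
}

#' Delineate a vectorcardiogram
#'
#' Convenience wrapper: R-peak detection, tachogram construction, ectopic
#' flagging and T-window assignment under one configuration.
#'
#' @param vcg A [vcg_signal()].
#' @param config Configuration list, see [default_config()].
#' @return List with `r_indices`, `tachogram`, `annotations`.
#' @export
delineate <- function(vcg, config = default_config()) {
  dcfg <- config$delineation
  r <- detect_r_peaks(vcg, dcfg$refractory_s, dcfg$threshold_frac,
                      dcfg$smooth_ms, dcfg$search_s)
  tach <- build_tachogram(r, vcg$fs)
  tach <- flag_ectopic(tach, dcfg$ectopic_threshold)
  ann <- assign_twave_windows(r, tach, vcg$fs, length(vcg$v_x), dcfg)
  list(r_indices = r, tachogram = tach, annotations = ann)
}
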