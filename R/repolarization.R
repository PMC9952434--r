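#' Average T-wave vector over a window
#'
#' Component-wise arithmetic mean of (Vx, Vy, Vz) over the sample window.
#' Windows shorter than 3 samples or with mean-vector norm below the
#' validity floor yield an invalid vector (low-amplitude T waves defeat
#' angle estimation and are excluded rather than propagated).
#'
#' @param vcg A [vcg_signal()].
#' @param t_on,t_end Window bounds in samples (inclusive).
#' @param floor_uv Minimum valid mean-vector norm (uV).
#' @return List `v` (length-3 mean vector), `norm`, `valid`.
#' @export
average_twave_vector <- function(vcg, t_on, t_end, floor_uv = 2) {
  n <- length(vcg$v_x)
  if (t_on < 1 || t_end > n || t_end - t_on + 1 < 3) {
    return(list(v = c(NA_real_, NA_real_, NA_real_), norm = NA_real_, valid = FALSE))
  }
  idx <- t_on:t_end
  v <- c(mean(vcg$v_x[idx]), mean(vcg$v_y[idx]), mean(vcg$v_z[idx]))
  nrm <- sqrt(sum(v^2))
  list(v = v, norm = nrm, valid = is.finite(nrm) && nrm >= floor_uv)
}

#' Angle between two vectors
#'
#' `acos` of the normalized dot product, clamped to [-1, 1], in degrees.
#' Symmetric and invariant to positive rescaling of either vector; always
#' in [0, 180] (the dot-product construction carries no sign).
#'
#' @param u,v Numeric length-3 vectors (non-zero).
#' @return Angle in degrees.
#' @export
consecutive_angle <- function(u, v) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0 || !is.finite(nu) || !is.finite(nv)) {
    abort_typed("cardiovag_bad_input", "zero-norm vector has no defined angle")
  }
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Running median filter
#'
#' Centered running median with window `order + 1` taps (made odd if needed
#' so the window has a unique center), reflect-padded at the edges. Output
#' is bounded by the input range everywhere.
#'
#' @param series Numeric series.
#' @param order Filter order (default 10, i.e. an 11-tap window).
#' @return Filtered series, same length.
#' @export
median_filter_series <- function(series, order = 10) {
  w <- order + 1L
  if (w %% 2 == 0) w <- w + 1L
  n <- length(series)
  if (n <= order) abort_typed("cardiovag_too_short", "series not longer than the filter order")
  h <- (w - 1L) / 2L
  padded <- c(series[(h + 1):2], series, series[(n - 1):(n - h)])
  out <- stats::runmed(padded, w, endrule = "keep")
  out[(h + 1):(h + n)]
}

#' Beat-to-beat T-wave-vector angle series
#'
#' For every pair of consecutive valid beats, computes the angle between
#' their average T-wave vectors (dT, degrees); pairs straddling an ectopic
#' or invalid beat are dropped rather than bridged, and the beat-time axis
#' keeps real timestamps so the oscillation frequency content is preserved.
#' The series is then median-filtered; the filtered series is what feeds
#' the phase-rectified averaging.
#'
#' @param vcg A [vcg_signal()].
#' @param annotations `beat_annotations` from [assign_twave_windows()].
#' @param config `prd` configuration block (median order, T-vector floor,
#'   L, M), see [default_config()].
#' @return `angle_series` data.frame: `beat` (later beat of the pair),
#'   `t_s`, `dt_raw_deg`, `dt_filt_deg`.
#' @export
build_angle_series <- function(vcg, annotations, config = default_config()$prd) {
  ann <- annotations
  usable <- ann$valid & !ann$ectopic
  tvecs <- vector("list", nrow(ann))
  for (i in which(usable)) {
    tvecs[[i]] <- average_twave_vector(vcg, ann$t_on[i], ann$t_end[i],
                                       floor_uv = config$tvec_floor_uv)
    if (!tvecs[[i]]$valid) usable[i] <- FALSE
  }
  pairs <- which(usable[-nrow(ann)] & usable[-1])  # i and i+1 both usable
  need <- 2 * config$L + 1
  if (length(pairs) < need) {
    abort_typed("cardiovag_too_short",
                sprintf("only %d valid consecutive T-vector pairs; need at least %d",
                        length(pairs), need))
  }
  dt <- vapply(pairs, function(i) consecutive_angle(tvecs[[i]]$v, tvecs[[i + 1]]$v),
               numeric(1))
  t_s <- (ann$r_sample[pairs + 1] - ann$r_sample[1]) / vcg$fs
  structure(
    data.frame(beat = pairs + 1L, t_s = t_s, dt_raw_deg = dt,
               dt_filt_deg = median_filter_series(dt, config$median_order)),
    class = c("angle_series", "data.frame")
  )
}

#' Periodic repolarization dynamics from an angle series
#'
#' Averaged-comparison anchors (span `M`) on the filtered dT series, PRSA
#' with half-window `L`, then the oscillation amplitude (max - min of the
#' averaged curve).
#'
#' @param angles An `angle_series` from [build_angle_series()].
#' @param L Half-window length (default 20, resolving 0.025--0.1 Hz).
#' @param M Averaging span for the anchor rule (default 9).
#' @return List with `prd` (degrees), `prsa` (the `prsa_result`).
#' @export
prd_from_angles <- function(angles, L = 20, M = 9) {
  x <- angles$dt_filt_deg
  anchors <- find_anchors_averaged(x, M = M, L = L)
  res <- prsa_average(x, anchors, L)
  list(prd = prd_from_curve(res), prsa = res)
}
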