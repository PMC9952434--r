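#' Specification of a synthetic RR tachogram
#'
#' The RR series is a mean level plus LF and HF sinusoidal modulation plus
#' white beat-to-beat jitter, with optional isolated ectopic beats (an early
#' beat followed by a compensatory pause). Defaults emulate a resting
#' healthy adult: mean RR 800 ms and band powers of roughly 720 ms^2 in each
#' of the LF (0.04--0.15 Hz) and HF (0.15--0.4 Hz) bands.
#'
#' @param mean_rr Mean RR interval (ms).
#' @param lf_amp,lf_freq LF modulation amplitude (ms) and frequency (Hz,
#'   conventionally in 0.04--0.15).
#' @param hf_amp,hf_freq HF modulation amplitude (ms) and frequency (Hz,
#'   conventionally in 0.15--0.4).
#' @param lf_phase,hf_phase Phases (rad); `NA` draws them from the seed.
#' @param jitter_sd White beat-to-beat noise SD (ms).
#' @param ectopic_rate Per-beat probability of inserting an ectopic.
#' @param duration Target record length (s).
#' @param seed Integer RNG seed.
#' @return Object of class `tachogram_spec`.
#' @export
tachogram_spec <- function(mean_rr = 800, lf_amp = 38, lf_freq = 0.10,
                           hf_amp = 38, hf_freq = 0.25,
                           lf_phase = NA, hf_phase = NA,
                           jitter_sd = 10, ectopic_rate = 0.02,
                           duration = 120, seed = 1L) {
  if (mean_rr <= 0) abort_typed("cardiovag_bad_spec", "mean_rr must be positive")
  if (lf_amp < 0 || hf_amp < 0 || jitter_sd < 0) {
    abort_typed("cardiovag_bad_spec", "amplitudes must be non-negative")
  }
  if (!(lf_freq < hf_freq)) abort_typed("cardiovag_bad_spec", "lf_freq must be below hf_freq")
  if (ectopic_rate < 0 || ectopic_rate >= 1) {
    abort_typed("cardiovag_bad_spec", "ectopic_rate must be in [0, 1)")
  }
  structure(as.list(environment()), class = "tachogram_spec")
}

#' Construct a tachogram
#'
#' @param rr_ms RR intervals (ms), one per beat.
#' @param t_s Cumulative beat times (s); default `cumsum(rr_ms) / 1000`.
#' @param ectopic Logical flag per beat (ectopic / artifact intervals are
#'   excluded from averages downstream).
#' @return A `tachogram` data.frame with columns `beat`, `t_s`, `rr_ms`,
#'   `ectopic`.
#' @export
tachogram <- function(rr_ms, t_s = cumsum(rr_ms) / 1000, ectopic = rep(FALSE, length(rr_ms))) {
  if (any(rr_ms <= 0)) abort_typed("cardiovag_bad_input", "all RR intervals must be positive")
  if (any(diff(t_s) <= 0)) abort_typed("cardiovag_bad_input", "beat times must be strictly increasing")
  structure(
    data.frame(beat = seq_along(rr_ms), t_s = t_s, rr_ms = rr_ms, ectopic = ectopic),
    class = c("tachogram", "data.frame")
  )
}

#' Generate a synthetic RR tachogram
#'
#' Beat i at cumulative time t_i has
#' `rr_i = mean_rr + lf_amp sin(2 pi lf_freq t_i + phi_L) +
#'  hf_amp sin(2 pi hf_freq t_i + phi_H) + jitter`. Ectopic beats are
#' inserted as isolated RR shortenings of 30--50 % followed by a
#' compensatory pause of the same magnitude (both intervals carry the
#' ground-truth ectopic flag). Deterministic under the spec's seed.
#'
#' @param spec A [tachogram_spec()].
#' @return A [tachogram()] with attribute `n_ectopic_events` (number of
#'   inserted early beats).
#' @export
generate_tachogram <- function(spec) {
  stopifnot(inherits(spec, "tachogram_spec"))
  set.seed(spec$seed)
  phi_l <- if (is.na(spec$lf_phase)) stats::runif(1, 0, 2 * pi) else spec$lf_phase
  phi_h <- if (is.na(spec$hf_phase)) stats::runif(1, 0, 2 * pi) else spec$hf_phase
  rr <- numeric(0)
  t <- 0
  while (t < spec$duration - 1e-9) {
    rr_i <- spec$mean_rr +
      spec$lf_amp * sin(2 * pi * spec$lf_freq * t + phi_l) +
      spec$hf_amp * sin(2 * pi * spec$hf_freq * t + phi_h) +
      stats::rnorm(1, 0, spec$jitter_sd)
    if (rr_i <= 0) abort_typed("cardiovag_bad_spec", "spec produces a non-positive RR interval")
    if (rr_i <= 200) {
      # physiological floor; also guards the beat clock against stalling
      abort_typed("cardiovag_bad_spec", "spec produces RR intervals at or below 200 ms")
    }
    rr <- c(rr, rr_i)
    t <- t + rr_i / 1000
  }
  n <- length(rr)
  flags <- rep(FALSE, n)
  n_events <- 0L
  if (spec$ectopic_rate > 0 && n > 2) {
    draws <- stats::runif(n) < spec$ectopic_rate
    for (i in seq(2, n - 1)) {
      # isolated events only: skip if the neighbourhood is already perturbed
      if (draws[i] && !flags[i - 1] && !flags[i]) {
        s <- stats::runif(1, 0.3, 0.5)
        delta <- s * rr[i]
        rr[i] <- rr[i] - delta
        rr[i + 1] <- rr[i + 1] + delta
        flags[i] <- TRUE
        flags[i + 1] <- TRUE
        n_events <- n_events + 1L
      }
    }
  }
  if (any(rr <= 200)) {
    abort_typed("cardiovag_bad_spec", "spec produces RR intervals at or below 200 ms")
  }
  out <- tachogram(rr, ectopic = flags)
  attr(out, "n_ectopic_events") <- n_events
  attr(out, "phases") <- c(lf = phi_l, hf = phi_h)
  out
}

unit3 <- function(v) v / sqrt(sum(v^2))

# Rotate unit vector u by theta (deg) about unit axis w (assumed orthogonal
# to u): Rodrigues formula with the parallel term vanishing.
rotate_about <- function(u, w, theta_deg) {
  th <- theta_deg * pi / 180
  cross <- c(w[2] * u[3] - w[3] * u[2],
             w[3] * u[1] - w[1] * u[3],
             w[1] * u[2] - w[2] * u[1])
  u * cos(th) + cross * sin(th)
}

#' Specification of synthetic beat morphology
#'
#' Beats are sums of Gaussians per axis: a three-lobe QRS (Q, R, S) with a
#' fixed spatial amplitude vector, a P wave before and a T wave after the
#' QRS with fixed spatial directions. The T-wave direction of beat i is the
#' base direction rigidly rotated by
#' `twave_osc_amp * sin(2 pi twave_osc_freq t_i)` about a fixed axis
#' orthogonal to it -- a pure angle modulation that leaves T amplitude
#' untouched, isolating the signal that periodic repolarization dynamics
#' measures.
#'
#' Defaults emulate a healthy adult with concordant repolarization: the P,
#' QRS and T spatial axes share one direction (small spatial QRS-T angle),
#' QRS magnitude 1.45 mV, T magnitude 0.4 mV with the T peak 320 ms after
#' the R wave, and 1 uV RMS additive channel noise (research-grade
#' electrodes at rest). Axis discordance is deliberately absent: it would
#' add morphological angle noise that masks the injected oscillation (see
#' the methods vignette for the full rationale).
#'
#' @param qrs_amp Length-3 QRS main-lobe amplitude per axis (uV).
#' @param qrs_width_ms Gaussian SD of the R lobe (ms).
#' @param t_dir Base T-wave spatial direction (unit 3-vector).
#' @param t_amp,t_width_ms,t_offset_ms T amplitude (uV), Gaussian SD (ms),
#'   and center relative to the R peak (ms).
#' @param p_dir,p_amp,p_width_ms,p_offset_ms P-wave analogues (offset is
#'   negative: before the R peak).
#' @param twave_osc_amp Amplitude of the beat-to-beat T-vector rotation
#'   (degrees).
#' @param twave_osc_freq Frequency of the rotation (Hz, conventionally
#'   0.025--0.1).
#' @param noise_sd Additive white noise SD per surface channel (uV).
#' @param baseline_offset Length-4 per-channel baseline offset (uV), order
#'   (R, L, F, B).
#' @param fs Sampling rate (Hz).
#' @return Object of class `morphology_spec`.
#' @export
morphology_spec <- function(qrs_amp = 1450 * unit3(c(0.6, 0.7, -0.4)),
                            qrs_width_ms = 12,
                            t_dir = unit3(c(0.6, 0.7, -0.4)),
                            t_amp = 400, t_width_ms = 45, t_offset_ms = 320,
                            p_dir = unit3(c(0.6, 0.7, -0.4)),
                            p_amp = 80, p_width_ms = 20, p_offset_ms = -160,
                            twave_osc_amp = 8, twave_osc_freq = 0.05,
                            noise_sd = 1, baseline_offset = c(0, 0, 0, 0),
                            fs = 250) {
  if (twave_osc_amp < 0) abort_typed("cardiovag_bad_spec", "twave_osc_amp must be non-negative")
  if (abs(sqrt(sum(t_dir^2)) - 1) > 1e-8) {
    abort_typed("cardiovag_bad_spec", "t_dir must have unit norm")
  }
  if (fs < 2000 / qrs_width_ms / 2) {
    abort_typed("cardiovag_bad_spec", "fs too low for the QRS template width")
  }
  structure(as.list(environment()), class = "morphology_spec")
}

# accumulate Gaussian lobes into per-axis vectors by reference-style local
# mutation (three vectors, local windows) to keep cohort generation cheap
make_accumulator <- function(n, fs) {
  x <- numeric(n); y <- numeric(n); z <- numeric(n)
  add <- function(center_s, sd_s, amp_vec) {
    lo <- max(1L, floor((center_s - 4 * sd_s) * fs) + 1L)
    hi <- min(n, ceiling((center_s + 4 * sd_s) * fs) + 1L)
    if (lo > hi) return(invisible(NULL))
    tt <- (seq.int(lo, hi) - 1) / fs
    g <- exp(-(tt - center_s)^2 / (2 * sd_s^2))
    x[lo:hi] <<- x[lo:hi] + amp_vec[1] * g
    y[lo:hi] <<- y[lo:hi] + amp_vec[2] * g
    z[lo:hi] <<- z[lo:hi] + amp_vec[3] * g
    invisible(NULL)
  }
  list(add = add, result = function() rbind(x, y, z))
}

#' Generate a synthetic vectorcardiogram from a tachogram
#'
#' Places P-QRS-T templates at the beat times of the tachogram; the T-wave
#' direction of each beat is rotated per the morphology's low-frequency
#' oscillation. Ground truth (R-peak samples, per-beat T directions and
#' rotation angles, inter-beat angles) is attached for downstream
#' validation.
#'
#' @param tach A [tachogram()].
#' @param morph A [morphology_spec()].
#' @param t_start Time of the first R peak (s).
#' @return A [vcg_signal()] with attribute `ground_truth`: list with
#'   `r_times`, `r_samples`, `theta_deg` (per-beat rotation angle),
#'   `dtheta_deg` (true angle between consecutive T vectors), `t_dirs`
#'   (3 x n), `tachogram`.
#' @export
generate_vcg <- function(tach, morph, t_start = 0.6) {
  stopifnot(inherits(tach, "tachogram"), inherits(morph, "morphology_spec"))
  if (nrow(tach) < 2) abort_typed("cardiovag_bad_input", "tachogram must be non-empty")
  span_ms <- (morph$t_offset_ms + 3 * morph$t_width_ms) +
    (abs(morph$p_offset_ms) + 3 * morph$p_width_ms)
  # ectopic shortenings may transiently overlap neighbouring waves (as in
  # real recordings); reject only templates wider than the typical beat
  if (span_ms >= stats::median(tach$rr_ms)) {
    abort_typed("cardiovag_bad_spec", "beat template is wider than the typical RR interval")
  }
  fs <- morph$fs
  r_times <- t_start + tach$t_s - tach$t_s[1]
  nb <- length(r_times)
  n <- ceiling((r_times[nb] + 0.6) * fs)
  acc <- make_accumulator(n, fs)

  # fixed rotation axis orthogonal to the base T direction
  u <- morph$t_dir
  e <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  w <- unit3(c(u[2] * e[3] - u[3] * e[2],
               u[3] * e[1] - u[1] * e[3],
               u[1] * e[2] - u[2] * e[1]))
  theta <- morph$twave_osc_amp * sin(2 * pi * morph$twave_osc_freq * r_times)
  t_dirs <- vapply(theta, function(th) rotate_about(u, w, th), numeric(3))

  sq <- morph$qrs_width_ms / 1000
  for (k in seq_len(nb)) {
    c_k <- r_times[k]
    acc$add(c_k, sq, morph$qrs_amp)                                  # R
    acc$add(c_k - 2.2 * sq, 0.6 * sq, -0.20 * morph$qrs_amp)         # Q
    acc$add(c_k + 2.2 * sq, 0.6 * sq, -0.30 * morph$qrs_amp)         # S
    acc$add(c_k + morph$p_offset_ms / 1000, morph$p_width_ms / 1000,
            morph$p_amp * morph$p_dir)
    acc$add(c_k + morph$t_offset_ms / 1000, morph$t_width_ms / 1000,
            morph$t_amp * t_dirs[, k])
  }
  sig <- acc$result()
  out <- vcg_signal(sig[1, ], sig[2, ], sig[3, ], fs = fs)
  attr(out, "ground_truth") <- list(
    r_times = r_times,
    r_samples = as.integer(floor(r_times * fs + 0.5)) + 1L,
    theta_deg = theta,
    dtheta_deg = abs(diff(theta)),
    t_dirs = t_dirs,
    tachogram = tach
  )
  out
}

#' Project a vectorcardiogram onto Wilson-tetrahedron surface leads
#'
#' Forward model inverting the lead-difference transform: produces channel
#' potentials (common-average referenced) whose lead differences map back to
#' the input components exactly, then adds per-channel baseline offset and
#' white noise. Together with [wilson_to_vcg()] this gives a round-trippable
#' synthesis/analysis pair (directions recovered exactly in the noise-free
#' case; magnitudes up to the transform's positive per-sample gain).
#'
#' @param vcg A [vcg_signal()].
#' @param morph A [morphology_spec()] (for noise, offsets, fs).
#' @param coeffs Coefficient list from [vcg_coefficients()].
#' @return A [multilead_ecg()]. Uses the current RNG state for noise.
#' @export
project_to_wilson <- function(vcg, morph = morphology_spec(),
                              coeffs = vcg_coefficients()) {
  stopifnot(inherits(vcg, "vcg_signal"))
  v <- vcg_matrix(vcg)
  m_inv <- solve(coeffs$matrix_scale * coeffs$matrix)
  d <- m_inv %*% v
  v_r <- -(d[1, ] + d[2, ] + d[3, ]) / 4
  ch <- list(v_r = v_r, v_l = v_r + d[1, ], v_f = v_r + d[2, ], v_b = v_r + d[3, ])
  n <- length(v_r)
  off <- morph$baseline_offset
  for (i in seq_along(ch)) {
    ch[[i]] <- ch[[i]] + off[i]
    if (morph$noise_sd > 0) ch[[i]] <- ch[[i]] + stats::rnorm(n, 0, morph$noise_sd)
  }
  multilead_ecg(ch$v_r, ch$v_l, ch$v_f, ch$v_b, fs = vcg$fs)
}

#' Generate one synthetic recording
#'
#' Seeds the RNG from the tachogram spec, then runs
#' [generate_tachogram()] -> [generate_vcg()] -> [project_to_wilson()].
#'
#' @param tach_spec A [tachogram_spec()].
#' @param morph A [morphology_spec()].
#' @param coeffs Transform coefficients.
#' @return List with `ecg` (surface recording), `vcg` (true
#'   vectorcardiogram), `tachogram` (true RR series) and `ground_truth`.
#' @export
generate_recording <- function(tach_spec, morph = morphology_spec(),
                               coeffs = vcg_coefficients()) {
  tach <- generate_tachogram(tach_spec)
  vcg <- generate_vcg(tach, morph)
  ecg <- project_to_wilson(vcg, morph, coeffs)
  list(ecg = ecg, vcg = vcg, tachogram = tach,
       ground_truth = attr(vcg, "ground_truth"))
}

#' Specification of a paired rest/stress cohort
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param rest,stress Lists with elements `tach` (a [tachogram_spec()]) and
#'   `morph` (a [morphology_spec()]) describing each condition.
#' @param master_seed Integer; per-subject, per-condition seeds are derived
#'   deterministically from it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 17,
                        rest = list(tach = tachogram_spec(), morph = morphology_spec()),
                        stress = list(tach = tachogram_spec(), morph = morphology_spec()),
                        master_seed = 1L) {
  if (n_subjects < 2) abort_typed("cardiovag_bad_spec", "n_subjects must be >= 2")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a paired rest/stress cohort
#'
#' Each subject gets independent seeds (derived from `master_seed`) for the
#' rest and stress recordings; all other condition parameters come from the
#' cohort spec. Optionally writes each recording as CSV with a JSON ground
#' truth sidecar plus a cohort manifest.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Directory to write files to, or `NULL` for in-memory only.
#' @return List with `subjects` (per subject: `id`, `rest`, `stress`
#'   recordings as from [generate_recording()]) and `spec`.
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  base <- (spec$master_seed %% 1000000L) * 1000L
  subjects <- lapply(seq_len(spec$n_subjects), function(s) {
    rest_spec <- spec$rest$tach
    rest_spec$seed <- base + 2L * s
    stress_spec <- spec$stress$tach
    stress_spec$seed <- base + 2L * s + 1L
    list(id = sprintf("S%02d", s),
         rest = generate_recording(rest_spec, spec$rest$morph),
         stress = generate_recording(stress_spec, spec$stress$morph))
  })
  cohort <- list(subjects = subjects, spec = spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(n_subjects = spec$n_subjects, master_seed = spec$master_seed,
                     files = list())
    for (sub in subjects) {
      for (cond in c("rest", "stress")) {
        stem <- file.path(out_dir, paste0(sub$id, "_", cond))
        write_recording(sub[[cond]]$ecg, paste0(stem, ".csv"))
        gt <- sub[[cond]]$ground_truth
        jsonlite::write_json(
          list(r_samples = gt$r_samples, rr_ms = gt$tachogram$rr_ms,
               ectopic = gt$tachogram$ectopic, theta_deg = gt$theta_deg,
               dtheta_deg = gt$dtheta_deg),
          paste0(stem, "_truth.json"), digits = NA)
        manifest$files[[paste0(sub$id, "_", cond)]] <- basename(paste0(stem, ".csv"))
      }
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  cohort
}
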