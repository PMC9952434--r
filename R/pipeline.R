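#' Extract the full biomarker panel from one recording
#'
#' Runs preprocessing (zero-phase band-pass, isoline removal, common-average
#' re-reference), the Wilson-to-VCG transform, beat delineation with the
#' 20 % ectopic rule and the QRS-anchored T-window rule, then computes mean
#' RR, heart rate, LF and HF power, LF/HF, deceleration capacity and
#' periodic repolarization dynamics. Deterministic for fixed input and
#' configuration.
#'
#' @param x A [multilead_ecg()] or a path to a recording CSV.
#' @param config Configuration list, see [default_config()].
#' @param keep_intermediates If `TRUE`, attach the preprocessed ECG, VCG,
#'   delineation, spectra, PRSA results and angle series as attribute
#'   `intermediates`.
#' @return One-row `data.frame` (the biomarker panel): `mean_rr`, `hr`,
#'   `lf`, `hf`, `lf_hf`, `dc`, `prd`, plus quality columns `n_beats`,
#'   `ectopic_frac`, `dc_anchors`, `prd_anchors`.
#' @export
analyze_recording <- function(x, config = default_config(),
                              keep_intermediates = FALSE) {
  ecg <- if (inherits(x, "multilead_ecg")) x else {
    read_recording(x, fs = if (is.null(config$signal$fs)) NULL else config$signal$fs,
                   columns = config$signal$columns)
  }
  pre <- preprocess_ecg(ecg, config)
  coeffs <- vcg_coefficients(config$vcg$coeff_file)
  vcg <- wilson_to_vcg(pre, coeffs)
  dl <- delineate(vcg, config)
  td <- time_domain(dl$tachogram)
  sp <- rr_psd(dl$tachogram, config$hrv$resample_fs,
               config$hrv$lf_band, config$hrv$hf_band)
  dc <- dc_from_tachogram(dl$tachogram, L = config$dc$L,
                          exclude_prolongation_frac = config$dc$exclude_prolongation_frac)
  angles <- build_angle_series(vcg, dl$annotations, config$prd)
  prd <- prd_from_angles(angles, L = config$prd$L, M = config$prd$M)

  panel <- data.frame(
    mean_rr = td$mean_rr, hr = td$hr,
    lf = sp$lf_power, hf = sp$hf_power, lf_hf = as.numeric(sp$lf_hf_ratio),
    dc = dc$dc, prd = prd$prd,
    n_beats = length(dl$r_indices),
    ectopic_frac = mean(dl$tachogram$ectopic),
    dc_anchors = dc$prsa$anchor_count,
    prd_anchors = prd$prsa$anchor_count
  )
  if (keep_intermediates) {
    attr(panel, "intermediates") <- list(
      preprocessed = pre, vcg = vcg, delineation = dl, spectrum = sp,
      dc_prsa = dc$prsa, angle_series = angles, prd_prsa = prd$prsa
    )
  }
  panel
}

#' Extract biomarker panels for a whole cohort
#'
#' @param cohort A cohort from [generate_cohort()] (or any list of subjects
#'   with `id`, `rest$ecg`, `stress$ecg`).
#' @param config Configuration list.
#' @return `data.frame` with one row per subject x condition, columns
#'   `subject`, `condition` and the panel columns of [analyze_recording()].
#' @export
analyze_cohort <- function(cohort, config = default_config()) {
  rows <- lapply(cohort$subjects, function(sub) {
    do.call(rbind, lapply(c("rest", "stress"), function(cond) {
      panel <- analyze_recording(sub[[cond]]$ecg, config)
      cbind(data.frame(subject = sub$id, condition = cond), panel)
    }))
  })
  do.call(rbind, rows)
}

#' Paired rest/stress comparison of biomarker panels
#'
#' For each biomarker: condition means with standard errors, Shapiro-Wilk
#' normality of the paired differences, and a paired t-test. Subjects
#' missing either condition are dropped. Degenerate cases (zero-variance
#' differences) are flagged rather than reported as spuriously extreme
#' p-values. A Holm-adjusted column is printed alongside the raw p-values
#' as a clearly-labelled extension (the headline analysis is unadjusted).
#'
#' @param panels `data.frame` from [analyze_cohort()], or a list
#'   `(rest, stress)` of panel data.frames with a `subject` column.
#' @param biomarkers Character vector of panel columns to compare.
#' @return `paired_comparison` data.frame: `biomarker`, `n`, `mean_rest`,
#'   `se_rest`, `mean_stress`, `se_stress`, `shapiro_p`, `p_value`,
#'   `p_holm`, `test`, `degenerate`.
#' @export
compare_conditions <- function(panels,
                               biomarkers = c("mean_rr", "hr", "lf", "hf",
                                              "lf_hf", "dc", "prd")) {
  if (is.data.frame(panels)) {
    rest <- panels[panels$condition == "rest", ]
    stress <- panels[panels$condition == "stress", ]
  } else {
    rest <- panels$rest
    stress <- panels$stress
  }
  ids <- intersect(rest$subject, stress$subject)
  dropped <- setdiff(union(rest$subject, stress$subject), ids)
  if (length(dropped)) {
    message("dropping subjects missing a condition: ", paste(dropped, collapse = ", "))
  }
  if (length(ids) < 2) abort_typed("cardiovag_bad_input", "need >= 2 complete pairs")
  rest <- rest[match(ids, rest$subject), ]
  stress <- stress[match(ids, stress$subject), ]

  one <- function(bm) {
    a <- rest[[bm]]
    b <- stress[[bm]]
    ok <- is.finite(a) & is.finite(b)
    a <- a[ok]; b <- b[ok]
    n <- length(a)
    d <- b - a
    degenerate <- n < 2 || stats::sd(d) == 0
    sw <- if (!degenerate && n >= 3) tryCatch(stats::shapiro.test(d)$p.value,
                                              error = function(e) NA_real_) else NA_real_
    p <- if (degenerate) NA_real_ else stats::t.test(b, a, paired = TRUE)$p.value
    data.frame(
      biomarker = bm, n = n,
      mean_rest = mean(a), se_rest = stats::sd(a) / sqrt(n),
      mean_stress = mean(b), se_stress = stats::sd(b) / sqrt(n),
      shapiro_p = sw, p_value = p, test = "paired t", degenerate = degenerate
    )
  }
  out <- do.call(rbind, lapply(biomarkers, one))
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  structure(out[, c("biomarker", "n", "mean_rest", "se_rest", "mean_stress",
                    "se_stress", "shapiro_p", "p_value", "p_holm", "test",
                    "degenerate")],
            class = c("paired_comparison", "data.frame"))
}

#' Unpaired two-group comparison (optional mode)
#'
#' Mann-Whitney U (Wilcoxon rank-sum) comparison of a biomarker between two
#' independent groups, e.g. recordings from two sites.
#'
#' @param a,b Numeric vectors.
#' @return p-value.
#' @export
compare_groups_unpaired <- function(a, b) {
  stats::wilcox.test(a, b)$p.value
}
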