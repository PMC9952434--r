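#' Load the Wilson-tetrahedron transform coefficients
#'
#' The linear map from lead differences to the unnormalized dipole
#' projection, and the constants of the per-sample gain K, are stored in a
#' human-readable coefficient file rather than hard-coded, so a corrected
#' transcription is a data change. The packaged file carries the updated
#' coefficient set for the four-electrode Wilson system.
#'
#' @param path Coefficient CSV; `NULL` uses the packaged file.
#' @return List with `matrix` (3x3, rows x/y/z, columns the lead differences
#'   VL-VR, VF-VR, VB-VR), `matrix_scale`, `k_scale`, `k_e2_coeff`,
#'   `k_vb_coeff`, `e2_cross_coeff`.
#' @export
vcg_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "wilson_vcg_coefficients.csv", package = "cardiovag")
  }
  if (!nzchar(path) || !file.exists(path)) {
    abort_typed("cardiovag_missing_file", paste0("coefficient file not found: ", path))
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  val <- stats::setNames(tab$value, tab$name)
  m <- matrix(val[c("m11", "m12", "m13", "m21", "m22", "m23", "m31", "m32", "m33")],
              nrow = 3, byrow = TRUE,
              dimnames = list(c("x", "y", "z"), c("d_lr", "d_fr", "d_br")))
  list(matrix = m,
       matrix_scale = unname(val["matrix_scale"]),
       k_scale = unname(val["k_scale"]),
       k_e2_coeff = unname(val["k_e2_coeff"]),
       k_vb_coeff = unname(val["k_vb_coeff"]),
       e2_cross_coeff = unname(val["e2_cross_coeff"]))
}

#' Lead differences of a Wilson recording
#'
#' Returns the three differences (VL-VR, VF-VR, VB-VR) that drive the
#' vectorcardiographic transform. Exactly invariant under any common
#' per-sample offset of all channels (so the reference site is immaterial).
#'
#' @param ecg A [multilead_ecg()].
#' @return 3 x n numeric matrix with rows `d_lr`, `d_fr`, `d_br`.
#' @export
lead_differences <- function(ecg) {
  stopifnot(inherits(ecg, "multilead_ecg"))
  rbind(d_lr = ecg$v_l - ecg$v_r,
        d_fr = ecg$v_f - ecg$v_r,
        d_br = ecg$v_b - ecg$v_r)
}

#' Direction cosines of the cardiac dipole
#'
#' Applies the linear transform to the lead differences and normalizes to
#' unit Euclidean norm per sample. Samples where all three differences are
#' zero have no defined direction; they are marked `undefined` (not silently
#' NaN-propagated).
#'
#' @param diffs 3 x n matrix from [lead_differences()].
#' @param coeffs Coefficient list from [vcg_coefficients()].
#' @return List with `p` (3 x n unit direction cosines, rows x/y/z), `vp`
#'   (unnormalized projection), `undefined` (logical per sample).
#' @export
direction_cosines <- function(diffs, coeffs = vcg_coefficients()) {
  vp <- coeffs$matrix_scale * (coeffs$matrix %*% diffs)
  nrm <- sqrt(colSums(vp^2))
  undefined <- !is.finite(nrm) | nrm == 0
  p <- vp
  safe <- ifelse(undefined, 1, nrm)
  p <- sweep(vp, 2, safe, "/")
  p[, undefined] <- NA_real_
  rownames(p) <- c("x", "y", "z")
  list(p = p, vp = vp, undefined = undefined)
}

#' Construct a vectorcardiogram container
#'
#' @param v_x,v_y,v_z Orthogonal components (uV): X right-to-left, Y
#'   head-to-foot, Z front-to-back.
#' @param fs Sampling rate (Hz).
#' @param undefined Logical per sample: samples whose dipole direction was
#'   undefined and bridged by interpolation.
#' @return Object of class `vcg_signal`.
#' @export
vcg_signal <- function(v_x, v_y, v_z, fs, undefined = NULL) {
  n <- length(v_x)
  stopifnot(length(v_y) == n, length(v_z) == n, fs > 0)
  if (is.null(undefined)) undefined <- rep(FALSE, n)
  structure(list(v_x = as.numeric(v_x), v_y = as.numeric(v_y),
                 v_z = as.numeric(v_z), fs = fs, undefined = undefined),
            class = "vcg_signal")
}

#' @export
print.vcg_signal <- function(x, ...) {
  cat(sprintf("<vcg_signal> %d samples, fs = %g Hz, %d undefined\n",
              length(x$v_x), x$fs, sum(x$undefined)))
  invisible(x)
}

vcg_matrix <- function(vcg) rbind(x = vcg$v_x, y = vcg$v_y, z = vcg$v_z)

vcg_magnitude <- function(vcg) sqrt(vcg$v_x^2 + vcg$v_y^2 + vcg$v_z^2)

#' Wilson tetrahedron to spatial vectorcardiogram
#'
#' Per sample, the orthogonal components are `3 * K * (px, py, pz)`, where
#' the direction cosines come from the linear transform of the lead
#' differences and the gain K is built from the planar magnitude E^2 and the
#' back-electrode potential (see [vcg_coefficients()]). Samples with an
#' undefined direction (all-zero differences) are bridged by linear
#' interpolation and flagged.
#'
#' @param ecg Preprocessed [multilead_ecg()].
#' @param coeffs Coefficient list from [vcg_coefficients()].
#' @return A [vcg_signal()] with attribute `projection`: list with `p`,
#'   `k_gain`, `e_sq`, `diffs`.
#' @export
wilson_to_vcg <- function(ecg, coeffs = vcg_coefficients()) {
  d <- lead_differences(ecg)
  dc <- direction_cosines(d, coeffs)
  e_sq <- d["d_lr", ]^2 + coeffs$e2_cross_coeff * (d["d_fr", ] + (ecg$v_f - ecg$v_l))^2
  k <- coeffs$k_scale * sqrt(coeffs$k_e2_coeff * e_sq + coeffs$k_vb_coeff * ecg$v_b^2)
  v <- sweep(dc$p, 2, 3 * k, "*")
  n <- ncol(v)
  frac_undef <- mean(dc$undefined)
  if (frac_undef > 0.5) {
    abort_typed("cardiovag_degenerate_signal",
                sprintf("%.0f%% of samples have undefined dipole direction", 100 * frac_undef))
  }
  if (frac_undef > 0.05) {
    warn_typed("cardiovag_quality",
               sprintf("%.1f%% of samples have undefined dipole direction", 100 * frac_undef))
  }
  if (any(dc$undefined)) {
    idx <- seq_len(n)
    ok <- !dc$undefined
    for (r in 1:3) {
      if (sum(ok) >= 2) {
        v[r, !ok] <- stats::approx(idx[ok], v[r, ok], xout = idx[!ok], rule = 2)$y
      } else {
        v[r, !ok] <- 0
      }
    }
  }
  out <- vcg_signal(v[1, ], v[2, ], v[3, ], fs = ecg$fs, undefined = dc$undefined)
  attr(out, "projection") <- list(p = dc$p, k_gain = k, e_sq = e_sq, diffs = d)
  out
}
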