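#' Construct a multi-lead ECG recording
#'
#' Container for the four Wilson-tetrahedron surface potentials: right arm
#' (`v_r`), left arm (`v_l`), left leg (`v_f`) and back (`v_b`), in
#' microvolts on a common time base.
#'
#' @param v_r,v_l,v_f,v_b Numeric voltage series (uV), equal length.
#' @param fs Sampling rate (Hz).
#' @param t0 Time of the first sample (s).
#' @param quality Optional list of per-channel quality flags.
#' @return Object of class `multilead_ecg`.
#' @export
multilead_ecg <- function(v_r, v_l, v_f, v_b, fs, t0 = 0, quality = list()) {
  n <- length(v_r)
  if (length(v_l) != n || length(v_f) != n || length(v_b) != n) {
    abort_typed("cardiovag_bad_input", "all four channels must have equal length")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort_typed("cardiovag_bad_input", "fs must be a positive scalar")
  }
  structure(
    list(v_r = as.numeric(v_r), v_l = as.numeric(v_l),
         v_f = as.numeric(v_f), v_b = as.numeric(v_b),
         fs = fs, t0 = t0, quality = quality),
    class = "multilead_ecg"
  )
}

#' @export
print.multilead_ecg <- function(x, ...) {
  cat(sprintf("<multilead_ecg> %d samples x 4 channels, fs = %g Hz (%.1f s)\n",
              length(x$v_r), x$fs, length(x$v_r) / x$fs))
  invisible(x)
}

ecg_channels <- c("v_r", "v_l", "v_f", "v_b")

#' Write a multi-lead recording to CSV
#'
#' Dialect: header `t,v_r,v_l,v_f,v_b`, comma-separated, `.` decimal, time in
#' seconds, voltages in microvolts. Values are written at full precision so a
#' write/read cycle round-trips bit-exactly.
#'
#' @param ecg A [multilead_ecg()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(ecg, path) {
  stopifnot(inherits(ecg, "multilead_ecg"))
  n <- length(ecg$v_r)
  fmt <- function(x) sprintf("%.17g", x)  # shortest exact decimal round-trip
  dt <- data.table::data.table(
    t = fmt(ecg$t0 + (seq_len(n) - 1) / ecg$fs),
    v_r = fmt(ecg$v_r), v_l = fmt(ecg$v_l), v_f = fmt(ecg$v_f), v_b = fmt(ecg$v_b)
  )
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' Read a multi-lead ECG recording from CSV
#'
#' @param path CSV file with named electrode columns.
#' @param fs Sampling rate in Hz; if `NULL`, inferred from the time column.
#' @param columns Named character vector mapping internal names
#'   (`t`, `v_r`, `v_l`, `v_f`, `v_b`) to file column names.
#' @param min_duration_s Minimum accepted record length (s); shorter files
#'   are rejected because the downstream spectral and averaging stages need
#'   adequate span.
#' @return A [multilead_ecg()]; rows with non-finite voltages are flagged in
#'   `$quality$nonfinite_rows` (the values are kept as `NA`-free via linear
#'   interpolation and counted, not silently dropped).
#' @export
read_recording <- function(path, fs = NULL,
                           columns = default_config()$signal$columns,
                           min_duration_s = 10) {
  if (!file.exists(path)) {
    abort_typed("cardiovag_missing_file", paste0("recording not found: ", path))
  }
  dt <- data.table::fread(path)
  for (nm in ecg_channels) {
    if (!columns[[nm]] %in% names(dt)) {
      abort_typed("cardiovag_missing_channel",
                  paste0("missing channel column '", columns[[nm]], "' (", nm, ") in ", path))
    }
  }
  if (is.null(fs)) {
    tcol <- columns[["t"]]
    if (!tcol %in% names(dt)) {
      abort_typed("cardiovag_bad_input", "fs not given and no time column to infer it from")
    }
    dts <- diff(dt[[tcol]])
    fs <- 1 / stats::median(dts)
  }
  if (!is.finite(fs) || fs <= 0) abort_typed("cardiovag_bad_input", "fs must be positive")
  n <- nrow(dt)
  if (n < min_duration_s * fs) {
    abort_typed("cardiovag_too_short",
                sprintf("recording is %.2f s; at least %g s required", n / fs, min_duration_s))
  }
  ch <- lapply(ecg_channels, function(nm) as.numeric(dt[[columns[[nm]]]]))
  names(ch) <- ecg_channels
  bad <- Reduce(`|`, lapply(ch, function(x) !is.finite(x)))
  if (any(bad)) {
    idx <- seq_len(n)
    ch <- lapply(ch, function(x) {
      x[!is.finite(x)] <- NA_real_
      stats::approx(idx[!is.na(x)], x[!is.na(x)], xout = idx, rule = 2)$y
    })
  }
  multilead_ecg(ch$v_r, ch$v_l, ch$v_f, ch$v_b, fs = fs,
                quality = list(nonfinite_rows = which(bad)))
}

# Forward-backward IIR filtering with reflect padding so edge transients do
# not leak into the analysis epoch. Pad length = 3x the nominal impulse span
# of the low cutoff.
filtfilt_padded <- function(b, a, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  head_ref <- 2 * x[1] - x[seq(pad + 1, 2)]
  tail_ref <- 2 * x[n] - x[seq(n - 1, n - pad)]
  y <- signal::filtfilt(signal::Arma(b = b, a = a), c(head_ref, x, tail_ref))
  y[seq(pad + 1, pad + n)]
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass (defaults 2--26 Hz, order 4) applied
#' forward-backward, so the net phase shift is zero and fiducial points are
#' not displaced; the DC component lies in the stopband and is removed.
#'
#' @param ecg A [multilead_ecg()].
#' @param low_cut,high_cut Band edges (Hz).
#' @param order Butterworth order of the one-pass prototype (effective order
#'   doubles in the forward-backward application).
#' @return Filtered [multilead_ecg()].
#' @export
zero_phase_bandpass <- function(ecg, low_cut = 2, high_cut = 26, order = 4) {
  stopifnot(inherits(ecg, "multilead_ecg"))
  fs <- ecg$fs
  if (!(low_cut > 0 && low_cut < high_cut && high_cut < fs / 2)) {
    abort_typed("cardiovag_bad_input", "need 0 < low_cut < high_cut < fs/2")
  }
  span <- ceiling(3 * fs / low_cut)
  if (length(ecg$v_r) <= span) {
    abort_typed("cardiovag_too_short", "signal shorter than 3x the filter impulse span")
  }
  bt <- signal::butter(order, c(low_cut, high_cut) / (fs / 2), type = "pass")
  out <- ecg
  for (nm in ecg_channels) out[[nm]] <- filtfilt_padded(bt$b, bt$a, ecg[[nm]], span)
  out
}

#' Remove residual isoline offset
#'
#' Subtracts the per-channel median of the recording, a robust estimate of
#' the isoelectric baseline that is insensitive to QRS outliers.
#'
#' @param ecg A [multilead_ecg()].
#' @return List-free: a [multilead_ecg()] with offsets removed; the estimated
#'   offsets are stored in `$quality$isoline_offset_uv`.
#' @export
remove_isoline_offset <- function(ecg) {
  stopifnot(inherits(ecg, "multilead_ecg"))
  off <- vapply(ecg_channels, function(nm) stats::median(ecg[[nm]]), numeric(1))
  out <- ecg
  for (nm in ecg_channels) out[[nm]] <- ecg[[nm]] - off[[nm]]
  out$quality$isoline_offset_uv <- off
  out
}

#' Re-reference to the common average
#'
#' Subtracts the per-sample mean of the four channels from each channel.
#' Lead differences (e.g. VL - VR) are exactly invariant under this step, so
#' the vectorcardiographic transform is unaffected by the reference choice.
#'
#' @param ecg A [multilead_ecg()].
#' @return Re-referenced [multilead_ecg()].
#' @export
common_average_rereference <- function(ecg) {
  stopifnot(inherits(ecg, "multilead_ecg"))
  avg <- (ecg$v_r + ecg$v_l + ecg$v_f + ecg$v_b) / 4
  out <- ecg
  for (nm in ecg_channels) out[[nm]] <- ecg[[nm]] - avg
  out
}

#' Full preprocessing chain
#'
#' Band-pass (zero phase) -> isoline-offset removal -> common-average
#' re-reference, with per-channel quality metrics (RMS, non-finite count)
#' recorded in `$quality`.
#'
#' @param ecg A [multilead_ecg()].
#' @param config Configuration list, see [default_config()].
#' @return Preprocessed [multilead_ecg()].
#' @export
preprocess_ecg <- function(ecg, config = default_config()) {
  f <- config$filter
  out <- zero_phase_bandpass(ecg, f$low_cut, f$high_cut, f$order)
  out <- remove_isoline_offset(out)
  out <- common_average_rereference(out)
  out$quality$rms_uv <- vapply(ecg_channels, function(nm) sqrt(mean(out[[nm]]^2)), numeric(1))
  out
}
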