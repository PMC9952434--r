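#' Default analysis configuration
#'
#' Every numeric constant used by the pipeline stages is reachable from this
#' single nested list, so a full analysis is reproducible from one object.
#' Values mirror the method definitions: band-pass 2--26 Hz, 20 % ectopic
#' rule, deceleration-capacity half-window `L = 12`, periodic-repolarization
#' half-window `L = 20` with anchor-averaging span `M = 9`, an 11-tap median
#' filter for the T-angle series, LF band 0.04--0.15 Hz, HF band
#' 0.15--0.4 Hz, and the T-wave window rule (onset 90 ms after the QRS mark,
#' end at `min(360 ms, 2/3 RR)`).
#'
#' @return Nested named list of configuration blocks: `signal`, `filter`,
#'   `vcg`, `delineation`, `hrv`, `dc`, `prd`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$dc$L
default_config <- function() {
  list(
    signal = list(
      fs = 250,
      columns = c(t = "t", v_r = "v_r", v_l = "v_l", v_f = "v_f", v_b = "v_b"),
      gain = 1
    ),
    filter = list(low_cut = 2, high_cut = 26, order = 4),
    vcg = list(coeff_file = NULL),  # NULL -> packaged coefficient file
    delineation = list(
      refractory_s = 0.25,
      threshold_frac = 0.4,
      smooth_ms = 15,
      search_s = 2,
      qrs_halfwidth_ms = 40,
      ectopic_threshold = 0.20,
      twave_on_ms = 90,
      twave_max_ms = 360,
      twave_rr_frac = 2 / 3,
      twave_rr_cut_ms = 720,
      rr_mode = "preceding",   # which RR the T-window rule uses for beat i
      qrs_mark = "r_peak"      # anchor of the T-window rule
    ),
    hrv = list(
      resample_fs = 4,
      lf_band = c(0.04, 0.15),
      hf_band = c(0.15, 0.40)
    ),
    dc = list(L = 12, exclude_prolongation_frac = NULL),
    prd = list(L = 20, M = 9, median_order = 10, tvec_floor_uv = 2)
  )
}

#' Read a configuration file
#'
#' Loads a YAML configuration and merges it over [default_config()], so a
#' file only needs to state the values it changes.
#'
#' @param path Path to a YAML file (may be `NULL` for pure defaults).
#' @return Configuration list as from [default_config()].
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) abort_typed("cardiovag_missing_file", paste0("config file not found: ", path))
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort_typed("cardiovag_missing_dep", "reading config files requires the 'yaml' package")
  }
  user <- yaml::read_yaml(path)
  utils::modifyList(cfg, user)
}
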