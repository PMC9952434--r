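Package: cardiovag
Title: ECG Biomarkers of Sympatho-Vagal Balance from Four-Electrode
    Vectorcardiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for quantifying cardiac autonomic
    (sympatho-vagal) balance from short multi-lead ECG epochs recorded with
    a four-electrode Wilson tetrahedron. Transforms surface potentials into
    spatial vectorcardiographic components, delineates beats, and computes
    heart-rate-variability indices (mean RR, heart rate, LF and HF spectral
    power, LF/HF), deceleration capacity of heart rate via phase-rectified
    signal averaging, and periodic repolarization dynamics from
    beat-to-beat T-wave-vector angles. Includes a synthetic multi-lead ECG
    generator with controllable RR modulation, ectopic beats and
    low-frequency T-vector oscillation, so rest-versus-stress contrasts can
    be exercised against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
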