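test_that("zero-modulation spec yields a constant tachogram with the expected beat count", {
  spec <- tachogram_spec(mean_rr = 800, lf_amp = 0, hf_amp = 0, jitter_sd = 0,
                         ectopic_rate = 0, duration = 120, seed = 1)
  tach <- generate_tachogram(spec)
  expect_equal(nrow(tach), 150)
  expect_true(all(tach$rr_ms == 800))
  expect_false(any(tach$ectopic))
})

test_that("sampled LF sinusoid carries the closed-form variance a^2/2", {
  spec <- tachogram_spec(mean_rr = 800, lf_amp = 50, lf_freq = 0.10, lf_phase = 0,
                         hf_amp = 0, jitter_sd = 0, ectopic_rate = 0,
                         duration = 120, seed = 2)
  tach <- generate_tachogram(spec)
  expect_lt(abs(var(tach$rr_ms) - 50^2 / 2) / (50^2 / 2), 0.10)
  # direct-summation oracle: the series must be exactly the stated sinusoid
  t_prev <- c(0, tach$t_s[-nrow(tach)])
  expect_equal(tach$rr_ms, 800 + 50 * sin(2 * pi * 0.10 * t_prev), tolerance = 1e-12)
})

test_that("ectopic insertion is seed-deterministic and recoverable by the 20 % rule", {
  spec <- tachogram_spec(ectopic_rate = 0.05, seed = 7, duration = 120)
  tach <- generate_tachogram(spec)
  expect_gt(attr(tach, "n_ectopic_events"), 0)
  expect_identical(generate_tachogram(spec), tach)
  flagged <- flag_ectopic(tachogram(tach$rr_ms))
  truth <- which(tach$ectopic)
  recovered <- mean(truth %in% which(flagged$ectopic))
  expect_gte(recovered, 0.90)
})

test_that("invalid tachogram specs are rejected with typed errors", {
  expect_error(tachogram_spec(mean_rr = -1), class = "cardiovag_bad_spec")
  expect_error(tachogram_spec(lf_freq = 0.3, hf_freq = 0.2), class = "cardiovag_bad_spec")
  expect_error(tachogram_spec(ectopic_rate = 1), class = "cardiovag_bad_spec")
  expect_error(generate_tachogram(tachogram_spec(mean_rr = 300, lf_amp = 400,
                                                 jitter_sd = 0, seed = 1)),
               class = "cardiovag_bad_spec")
})

test_that("generated VCG is deterministic and carries usable ground truth", {
  rec <- fixture("clean")
  rec2 <- generate_recording(tachogram_spec(duration = 60, seed = 11, ectopic_rate = 0),
                             morphology_spec(noise_sd = 0))
  expect_identical(rec$vcg$v_x, rec2$vcg$v_x)
  expect_identical(rec$ecg$v_b, rec2$ecg$v_b)
  gt <- rec$ground_truth
  expect_equal(length(gt$r_samples), nrow(rec$tachogram))
  expect_equal(length(gt$dtheta_deg), length(gt$r_samples) - 1)
  # rigid rotation: analytic inter-beat angle matches the direction vectors
  ang <- acos(pmin(1, colSums(gt$t_dirs[, -1] * gt$t_dirs[, -ncol(gt$t_dirs)]))) * 180 / pi
  expect_equal(ang, gt$dtheta_deg, tolerance = 1e-9)
})

test_that("zero rotation amplitude gives identical T directions", {
  tach <- generate_tachogram(tachogram_spec(duration = 30, seed = 3, ectopic_rate = 0))
  vcg <- generate_vcg(tach, morphology_spec(twave_osc_amp = 0, noise_sd = 0))
  gt <- attr(vcg, "ground_truth")
  expect_true(all(gt$dtheta_deg < 1e-12))
})

test_that("templates wider than the typical RR are rejected", {
  tach <- generate_tachogram(tachogram_spec(mean_rr = 420, lf_amp = 0, hf_amp = 0,
                                            jitter_sd = 0, ectopic_rate = 0,
                                            duration = 30, seed = 1))
  expect_error(generate_vcg(tach, morphology_spec()), class = "cardiovag_bad_spec")
})

test_that("LF-only modulation places >= 90 % of tachogram power in the LF band", {
  for (case in list(list(lf = 40, hf = 0), list(lf = 0, hf = 40))) {
    spec <- tachogram_spec(lf_amp = case$lf, hf_amp = case$hf, jitter_sd = 0,
                           ectopic_rate = 0, duration = 120, seed = 5)
    sp <- suppressWarnings(rr_psd(generate_tachogram(spec)))
    total <- band_power(sp, c(0.003, 2))
    in_band <- if (case$lf > 0) sp$lf_power else sp$hf_power
    expect_gte(in_band / total, 0.90)
  }
})

test_that("cohort generation is reproducible and writes a readable cohort", {
  spec <- cohort_spec(
    n_subjects = 2,
    rest = list(tach = tachogram_spec(duration = 30),
                morph = morphology_spec()),
    stress = list(tach = tachogram_spec(duration = 30),
                  morph = morphology_spec()),
    master_seed = 9
  )
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co1$subjects[[2]]$stress$ecg$v_f, co2$subjects[[2]]$stress$ecg$v_f)
  # rest and stress seeds differ per subject
  expect_false(identical(co1$subjects[[1]]$rest$ecg$v_r, co1$subjects[[1]]$stress$ecg$v_r))

  dir <- withr::local_tempdir()
  generate_cohort(spec, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_recording(file.path(dir, "S01_rest.csv"))
  expect_equal(back$v_l, co1$subjects[[1]]$rest$ecg$v_l)
  expect_equal(back$fs, 250, tolerance = 1e-6)
})
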