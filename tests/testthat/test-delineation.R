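test_that("noise-free synthetic beats are all found within two samples", {
  rec <- fixture("clean")
  vcg <- suppressWarnings(wilson_to_vcg(preprocess_ecg(rec$ecg)))
  r <- detect_r_peaks(vcg)
  gt <- rec$ground_truth$r_samples
  expect_equal(length(r), length(gt))
  expect_lte(max(abs(r - gt)), 2)
})

test_that("detection tolerates 20 dB white noise", {
  tach <- generate_tachogram(tachogram_spec(duration = 60, seed = 21, ectopic_rate = 0))
  morph0 <- morphology_spec(noise_sd = 0)
  vcg_true <- generate_vcg(tach, morph0)
  # noise at -20 dB of the per-channel RMS of the clean surface leads
  set.seed(21)
  clean <- project_to_wilson(vcg_true, morph0)
  rms <- sqrt(mean(clean$v_l^2))
  noisy_morph <- morphology_spec(noise_sd = rms / 10)
  set.seed(22)
  noisy <- project_to_wilson(vcg_true, noisy_morph)
  r <- detect_r_peaks(wilson_to_vcg(preprocess_ecg(noisy)))
  gt <- attr(vcg_true, "ground_truth")$r_samples
  hits <- vapply(gt, function(g) any(abs(r - g) <= 4), logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("flat or too-short signals raise typed errors", {
  z <- vcg_signal(rep(0, 3000), rep(0, 3000), rep(0, 3000), fs = 250)
  expect_error(detect_r_peaks(z), class = "cardiovag_no_beats")
  s <- vcg_signal(rnorm(100), rnorm(100), rnorm(100), fs = 250)
  expect_error(detect_r_peaks(s), class = "cardiovag_too_short")
})

test_that("tachogram arithmetic follows rr = diff(r) / fs", {
  tach <- build_tachogram(c(1, 201, 401), fs = 250)
  expect_equal(tach$rr_ms, c(800, 800))
  expect_equal(tach$t_s, c(0.8, 1.6))
  expect_equal(nrow(build_tachogram(c(10, 260), 250)), 1)
  expect_error(build_tachogram(5, 250), class = "cardiovag_bad_input")
})

test_that("noise-free round trip recovers the generated RR series", {
  rec <- fixture("clean")
  vcg <- suppressWarnings(wilson_to_vcg(preprocess_ecg(rec$ecg)))
  tach <- build_tachogram(detect_r_peaks(vcg), vcg$fs)
  true_rr <- rec$tachogram$rr_ms[-1]  # first interval is consumed as onset offset
  expect_equal(length(tach$rr_ms), length(true_rr))
  expect_lt(max(abs(tach$rr_ms - true_rr)), 1000 / vcg$fs + 1e-9)
})

test_that("the 20 % rule flags by strict inequality against the last valid interval", {
  t1 <- suppressWarnings(flag_ectopic(tachogram(c(800, 800, 1000, 800))))
  expect_identical(t1$ectopic, c(FALSE, FALSE, TRUE, FALSE))
  # exact 20 % deviation is kept (strict inequality)
  t2 <- flag_ectopic(tachogram(c(800, 960)))
  expect_identical(t2$ectopic, c(FALSE, FALSE))
  t3 <- flag_ectopic(tachogram(rep(732, 40)))
  expect_false(any(t3$ectopic))
  # flagged intervals do not update the reference
  t4 <- suppressWarnings(flag_ectopic(tachogram(c(800, 810, 1100, 1080, 820))))
  expect_identical(t4$ectopic, c(FALSE, FALSE, TRUE, TRUE, FALSE))
  # idempotent
  expect_identical(suppressWarnings(flag_ectopic(t4))$ectopic, t4$ectopic)
})

test_that("T-wave windows follow the min(360, 2/3 RR) fallback rule", {
  fs <- 250
  cfg <- default_config()$delineation
  r <- c(1000L, 1000L + ms_to_samples(450, fs), 3000L, 6000L)
  # beat 2 preceded by RR 450 -> Tend at +300 ms; later beats: long RR -> +360 ms
  tach <- build_tachogram(r, fs)
  ann <- assign_twave_windows(r, tach, fs, n_samples = 10000L, config = cfg)
  expect_equal(ann$t_on, r + ms_to_samples(90, fs))
  expect_equal(ann$t_end[2] - ann$r_sample[2], ms_to_samples(300, fs))
  expect_equal(ann$t_end[3] - ann$r_sample[3], ms_to_samples(360, fs))
  expect_false(ann$valid[1])  # no preceding RR
  expect_true(ann$valid[2])

  # RR = 540 ms: 2/3 * 540 = 360, the boundary where both arms agree
  r2 <- c(1000L, 1000L + ms_to_samples(540, fs), 4000L)
  ann2 <- assign_twave_windows(r2, build_tachogram(r2, fs), fs, 10000L, cfg)
  expect_equal(ann2$t_end[2] - ann2$r_sample[2], ms_to_samples(360, fs))
  # RR = 900 ms >= 720 -> 360 ms
  r3 <- c(1000L, 1000L + ms_to_samples(900, fs), 4000L)
  ann3 <- assign_twave_windows(r3, build_tachogram(r3, fs), fs, 10000L, cfg)
  expect_equal(ann3$t_end[2] - ann3$r_sample[2], ms_to_samples(360, fs))
})

test_that("valid windows are ordered and non-overlapping on synthetic data", {
  rec <- fixture("default")
  dl <- delineate(suppressWarnings(wilson_to_vcg(preprocess_ecg(rec$ecg))))
  ann <- dl$annotations[dl$annotations$valid, ]
  expect_true(all(ann$qrs_on < ann$r_sample))
  expect_true(all(ann$r_sample < ann$qrs_off))
  expect_true(all(ann$qrs_off < ann$t_on))
  expect_true(all(ann$t_on < ann$t_end))
  nxt <- match(ann$beat + 1, dl$annotations$beat)
  has_next <- !is.na(nxt)
  expect_true(all(ann$t_end[has_next] <= dl$annotations$r_sample[nxt[has_next]]))
})
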