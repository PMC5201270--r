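test_that("pharmacokinetic superposition is causal, linear and peaks near hour 13", {
  m <- pk_model()
  expect_identical(simulate_pk(m, 0), 0)
  expect_true(all(simulate_pk(m, c(0, 1, 5, 9, 13, 24)) >= 0))

  m2 <- m
  m2$dose_amounts <- 2 * m$dose_amounts
  t <- seq(0, 24, by = 0.5)
  expect_equal(simulate_pk(m2, t), 2 * simulate_pk(m, t), tolerance = 1e-12)

  grid <- seq(0, 24, by = 0.05)
  conc <- simulate_pk(m, grid)
  expect_gt(grid[which.max(conc)], 12)
  expect_lt(grid[which.max(conc)], 14)

  expect_error(pk_model(ka_per_h = 0.1, ke_per_h = 0.1), "flip-flop")
  expect_error(simulate_pk(m, c(2, 1)), "sorted")

  cal <- pk_calibrate_cmax(m, 1.83)
  expect_equal(max(simulate_pk(cal, grid)), 1.83, tolerance = 1e-6)
})

test_that("drug effects are additive in concentration and zero at zero dose", {
  b <- test_baseline()
  eff <- test_models()$effects

  same <- apply_drug_effect(b, eff, c(dofetilide = 0))
  expect_equal(same$j_to_tpeak_ms, b$j_to_tpeak_ms)
  expect_equal(same$qt_ms, b$qt_ms, tolerance = 1e-6)

  expect_error(apply_drug_effect(b, eff, c(dofetilide = -1)), "nonnegative")
  expect_error(apply_drug_effect(b, eff, c(unknown = 1)), "no effect slopes")

  # additivity: effect of the combination equals the sum of the parts on
  # the beat-parameter scale
  p_d <- apply_drug_effect(b, eff, c(dofetilide = 1.83))
  p_m <- apply_drug_effect(b, eff, c(mexiletine = 1426))
  p_dm <- apply_drug_effect(b, eff, c(dofetilide = 1.83, mexiletine = 1426))
  expect_equal(p_dm$j_to_tpeak_ms - b$j_to_tpeak_ms,
               (p_d$j_to_tpeak_ms - b$j_to_tpeak_ms) +
                 (p_m$j_to_tpeak_ms - b$j_to_tpeak_ms), tolerance = 1e-9)
  expect_equal(p_dm$t_amplitude_uv - b$t_amplitude_uv,
               (p_d$t_amplitude_uv - b$t_amplitude_uv) +
                 (p_m$t_amplitude_uv - b$t_amplitude_uv), tolerance = 1e-9)

  # gross overdose drives durations inadmissible
  expect_error(apply_drug_effect(b, eff, c(mexiletine = 1e6)),
               "admissible")
})

test_that("calibration closes on the population change targets", {
  b <- test_baseline()
  eff <- test_models()$effects
  tb <- truth_biomarkers(b)
  al <- repolsig:::correction_alphas()
  corrected_changes <- function(conc) {
    t2 <- truth_biomarkers(apply_drug_effect(b, eff, conc))
    c(
      dqtc = (t2$qt_ms - tb$qt_ms) / b$rr_s^al[["qt"]],
      djtpeakc = (t2$jtpeak_ms - tb$jtpeak_ms) / b$rr_s^al[["jtpeak"]],
      damplitude = (t2$amplitude_uv - tb$amplitude_uv) / b$rr_s^al[["amplitude"]]
    )
  }
  dof <- corrected_changes(c(dofetilide = 1.83))
  expect_equal(dof[["dqtc"]], 45.2, tolerance = 0.5 / 45.2)
  expect_equal(dof[["djtpeakc"]], 29.1, tolerance = 0.5 / 29.1)
  expect_equal(dof[["damplitude"]], -87.9, tolerance = 0.5 / 87.9)

  mex <- corrected_changes(c(dofetilide = 1.83, mexiletine = 1426))
  expect_equal(mex[["dqtc"]], 17.3, tolerance = 0.5 / 17.3)
  expect_equal(mex[["djtpeakc"]], 1.1, tolerance = 0.5)

  lid <- corrected_changes(c(dofetilide = 1.83, lidocaine = 2261))
  expect_equal(lid[["dqtc"]], 17.9, tolerance = 0.5 / 17.9)
  expect_equal(lid[["djtpeakc"]], 4.1, tolerance = 0.5 / 4.1)
})

test_that("the calibrated baseline beat reproduces the cohort baseline table", {
  tb <- truth_biomarkers(test_baseline())
  b <- test_baseline()
  expect_equal(fridericia(tb$qt_ms, b$rr_s), 397.1, tolerance = 1e-6)
  expect_equal(tb$jtpeak_ms / b$rr_s^0.58, 228.2, tolerance = 1e-6)
  expect_equal(tb$tpeaktend_ms, 82.2, tolerance = 1e-6)
  expect_equal(tb$erd_ms, 50.1, tolerance = 1e-6)
  expect_equal(tb$lrd_ms, 31.1, tolerance = 1e-6)
  expect_equal(tb$amplitude_uv, 569)
  # ascending limb wider than descending at baseline (normal T asymmetry)
  expect_gt(b$sigma_asc_ms, b$sigma_desc_ms)
})

test_that("synthesized beats match their ground truth", {
  b <- test_baseline()
  sb <- synthesize_beat(b, fs_hz = 1000)
  vm <- sqrt(rowSums(sb$samples^2))
  # waveform maximum in the T region coincides with the truth T peak
  t_ms <- (seq_along(vm) - 1)
  t_region <- t_ms > sb$truth$qrs_offset_ms + 40
  expect_lt(abs(t_ms[t_region][which.max(vm[t_region])] - sb$truth$t_peak_ms), 1.5)
  # truth QT lands in the cohort QTc band after Fridericia
  qt <- sb$truth$t_end_ms - sb$truth$qrs_onset_ms
  expect_lt(abs(fridericia(qt, b$rr_s) - 397.1), 14)
  # amplitude scaling doubles the waveform outside the QRS, truth unchanged
  b2 <- baseline_at_rr(b$rr_s)
  b2$t_amplitude_uv <- 2 * b$t_amplitude_uv
  sb2 <- synthesize_beat(b2, fs_hz = 1000)
  after_qrs <- t_ms > sb$truth$qrs_offset_ms + 1
  expect_equal(sb2$samples[after_qrs, 1], 2 * sb$samples[after_qrs, 1],
               tolerance = 1e-9)
  expect_equal(sb2$truth$t_peak_ms, sb$truth$t_peak_ms)
  expect_error(synthesize_beat(b, fs_hz = 100), "250")
})

test_that("recordings are reproducible, periodic without jitter, and well annotated", {
  b <- test_baseline()
  r1 <- synthesize_recording(b, seed = 7)
  r2 <- synthesize_recording(b, seed = 7)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$truth, r2$truth)

  r0 <- synthesize_recording(baseline_at_rr(1.0), noise_uv_rms = 0,
                             rr_variability = 0, seed = 1)
  expect_gte(nrow(r0$truth), 9)
  expect_equal(stats::sd(diff(r0$truth$r_s)), 0, tolerance = 1e-9)
  # strict periodicity: consecutive beat windows are identical
  fs <- r0$fs_hz
  i1 <- round(r0$truth$qrs_onset_s[2] * fs)
  i2 <- round(r0$truth$qrs_onset_s[3] * fs)
  expect_equal(r0$samples[i1 + 1:200, ], r0$samples[i2 + 1:200, ])
  # quantization at the acquisition resolution
  expect_true(all(abs(r1$samples / 2.5 - round(r1$samples / 2.5)) < 1e-9))
  expect_error(synthesize_recording(b, noise_uv_rms = -1), "nonnegative")
  expect_error(synthesize_recording(b, duration_s = 1), "two beats")
})

test_that("the simulated trial honours the crossover design", {
  d <- trial_design(n_subjects = 6, n_female = 3,
                    timepoint_hours = c(0, 13),
                    replicates_per_timepoint = 1, seed = 42)
  tr <- simulate_trial(d)
  expect_equal(nrow(tr), 6 * 5 * 2 * 1)
  # every subject appears in every arm, in a Latin-square-style sequence
  tab <- table(tr$subject, tr$arm)
  expect_true(all(tab == 2))
  per <- dplyr::distinct(tr, subject, period, arm)
  by_subj <- split(per$arm[order(per$period)], per$subject[order(per$period)])
  expect_true(all(vapply(by_subj, function(a) length(unique(a)) == 5, logical(1))))
  # placebo rows carry zero concentration everywhere
  plac <- tr[tr$arm == "placebo", grep("^conc_", names(tr))]
  expect_true(all(as.matrix(plac) == 0))
  # reproducibility: the trial is a pure function of (design, models, seed)
  tr2 <- simulate_trial(d)
  expect_equal(as.data.frame(tr), as.data.frame(tr2))
})

test_that("zero-dose (all slopes zero) makes every arm distributionally identical", {
  d <- trial_design(n_subjects = 4, n_female = 2, timepoint_hours = c(0, 13),
                    replicates_per_timepoint = 1, seed = 9)
  models <- test_models()
  models$effects <- drug_effect_model(
    dplyr::mutate(models$effects$slopes, d_jtpeak = 0, d_tpeaktend = 0,
                  d_amplitude = 0, d_tail_weight = 0)
  )
  tr <- simulate_trial(d, models, measurement_noise = 0)
  # same subject, same time-point: biomarkers equal across arms up to the
  # (seeded) per-recording RR jitter; compare the rate-independent ones
  w <- tidyr::pivot_wider(
    tr[tr$timepoint_h == 13, c("subject", "arm", "tpeaktend_ms", "erd_ms")],
    names_from = arm, values_from = c(tpeaktend_ms, erd_ms)
  )
  tp <- as.matrix(w[, grep("^tpeaktend", names(w))])
  expect_lt(max(apply(tp, 1, stats::sd)), 1e-9)
  erd <- as.matrix(w[, grep("^erd", names(w))])
  expect_lt(max(apply(erd, 1, stats::sd)), 1e-9)
})
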