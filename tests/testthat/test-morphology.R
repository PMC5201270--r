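test_that("flatness matches the Gaussian closed form and its invariances", {
  t <- seq(-250, 250, by = 0.5)
  g <- make_segment(t, 500 * exp(-t^2 / (2 * 45^2)))
  expect_equal(t_flatness(g), 1 - 3^(-1 / 2), tolerance = 5e-4)

  # amplitude-scale invariance and time-reversal invariance
  g2 <- make_segment(t, 7 * g$y_uv)
  expect_equal(t_flatness(g2), t_flatness(g), tolerance = 1e-12)
  g3 <- make_segment(t, rev(g$y_uv))
  expect_equal(t_flatness(g3), t_flatness(g), tolerance = 1e-12)

  # a heavy shoulder raises kurtosis-flatness above the pure bell, and
  # flatness grows with the shoulder width (mixture kurtosis is not
  # globally monotone in the weight itself: it peaks at light weights and
  # returns to the Gaussian value as the shoulder takes over)
  ts <- seq(-320, 320, by = 0.5)
  fl_w <- sapply(seq(0.05, 0.5, by = 0.05), function(w) {
    y <- (1 - w) * exp(-ts^2 / (2 * 15^2)) + w * exp(-ts^2 / (2 * 60^2))
    t_flatness(make_segment(ts, 500 * y))
  })
  expect_true(all(fl_w > 1 - 3^(-1 / 2) + 0.01))
  fl_r <- sapply(c(1.5, 2, 2.5, 3), function(r) {
    y <- 0.9 * exp(-ts^2 / (2 * 15^2)) + 0.1 * exp(-ts^2 / (2 * (15 * r)^2))
    t_flatness(make_segment(ts, 500 * y))
  })
  expect_true(all(diff(fl_r) > 0))

  expect_error(t_flatness(make_segment(t, rep(0, length(t)))), "zero-area")
})

test_that("asymmetry is zero for mirror-symmetric waves and symmetric in the limbs", {
  t <- seq(-100, 100, by = 1)
  tri <- make_segment(t, pmax(0, 100 - abs(t)))
  expect_equal(t_asymmetry(tri), 0, tolerance = 1e-12)

  # two-half-bell wave with sigma_asc = 2 sigma_desc vs direct summation
  y <- ifelse(t <= 0, exp(-t^2 / (2 * 40^2)), exp(-t^2 / (2 * 20^2)))
  seg <- make_segment(t, 300 * y)
  p <- seg$peak_index
  w <- abs(seg$y_uv) / abs(seg$y_uv[p])
  m <- min(p - 1, length(w) - p)
  direct <- sum(abs(w[p + 1:m] - w[p - 1:m])) / sum(w[p + 1:m] + w[p - 1:m])
  expect_equal(t_asymmetry(seg), direct, tolerance = 1e-12)
  expect_gt(t_asymmetry(seg), 0)

  # time reversal swaps the limbs but not the value
  segr <- make_segment(t, rev(seg$y_uv))
  expect_equal(t_asymmetry(segr), t_asymmetry(seg), tolerance = 1e-12)

  bound <- make_segment(t, c(100, rep(1, length(t) - 1)))
  expect_error(t_asymmetry(bound), "boundary")
})

test_that("level-crossing ERD/LRD agrees with the bell closed form", {
  sigma <- 32.2
  t <- seq(-200, 200, by = 1)  # 1000 Hz sampling
  y <- 400 * exp(-t^2 / (2 * sigma^2))
  seg <- make_segment(t, y)
  el <- erd_lrd(seg, level = 0.30)
  closed <- sigma * sqrt(2 * log(1 / 0.3))
  expect_lt(abs(el$erd_ms - closed), 1)
  expect_lt(abs(closed - 50), 0.2)  # the bell width was chosen near 50 ms
  # symmetric wave: equal limbs; level 1 collapses both to zero
  expect_equal(el$erd_ms, el$lrd_ms, tolerance = 1e-9)
  el1 <- erd_lrd(seg, level = 1)
  expect_equal(c(el1$erd_ms, el1$lrd_ms), c(0, 0))
  # no crossing inside the segment
  seg2 <- make_segment(seq(-10, 10, 1), 400 * exp(-seq(-10, 10, 1)^2 / (2 * sigma^2)))
  expect_error(erd_lrd(seg2, level = 0.30), "no level crossing")
})

test_that("T amplitude is the vector-magnitude peak and is 1-homogeneous", {
  b <- test_baseline()
  rec <- synthesize_recording(b, noise_uv_rms = 0, rr_variability = 0, seed = 3)
  rec <- resample_recording(rec, 1000)
  mb <- build_median_beat(rec, detect_r_peaks(rec))
  fid <- delineate_beat(mb)
  seg <- t_wave_segment(mb, fid)
  expect_lt(abs(t_amplitude(seg) - 569), 2.6)  # within a quantization step

  mb2 <- mb
  mb2$beat <- mb$beat * 2
  seg2 <- t_wave_segment(mb2, fid)
  expect_equal(t_amplitude(seg2), 2 * t_amplitude(seg), tolerance = 1e-9)
})

test_that("ventricular gradient integrates per lead and scales linearly", {
  fs <- 1000
  n <- 500
  # two-lead toy with rectangular deflections: lead1 100 uV for 100 ms,
  # lead2 -50 uV for 200 ms -> integrals (0.01, -0.01) uV*s, norm 0.01*sqrt(2)
  m <- matrix(0, n, 2)
  m[101:200, 1] <- 100
  m[101:300, 2] <- -50
  beat <- structure(list(beat = m, fs_hz = fs, n_contributing_beats = 5,
                         mean_rr_s = 1, r_offset_ms = 150),
                    class = "median_beat")
  fid <- tibble::tibble(qrs_onset_ms = 0, qrs_offset_ms = 90, t_peak_ms = 250,
                        t_end_ms = 499, rr_s = 1, r_offset_ms = 150)
  vg <- ventricular_gradient(beat, fid)
  expect_equal(vg, sqrt(2) * 10, tolerance = 0.02)

  beat2 <- beat
  beat2$beat <- 2 * m
  expect_equal(ventricular_gradient(beat2, fid), 2 * vg, tolerance = 1e-9)

  # zero-mean beat integrates to nothing
  m3 <- matrix(c(rep(100, 250), rep(-100, 250)), n, 2)
  beat3 <- beat
  beat3$beat <- m3
  expect_lt(ventricular_gradient(beat3, fid), 0.3)  # boundary-sample slack

  beat1 <- beat
  beat1$beat <- m[, 1, drop = TRUE]
  expect_error(ventricular_gradient(beat1, fid), "multi-lead")
})

test_that("generator sweeps drive the morphology biomarkers monotonically", {
  b <- test_baseline()
  # ERD grows with the ascending width; amplitude with the amplitude knob
  erds <- sapply(c(30, 45, 60, 75), function(s) {
    repolsig:::asc_level_cross_ms(s, 0.70)
  })
  expect_true(all(diff(erds) > 0))
  amps <- sapply(c(300, 500, 700), function(a) {
    p <- baseline_at_rr(b$rr_s)
    p$t_amplitude_uv <- a
    truth_biomarkers(p)$amplitude_uv
  })
  expect_true(all(diff(amps) > 0))
})
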