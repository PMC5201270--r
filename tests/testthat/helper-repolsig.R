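# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; nothing is read from disk.

# Cached calibrated study models (deterministic; calibration is ~1 s).
test_models <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- study_models()
    m
  }
})

test_baseline <- function() test_models()$baseline

# Noise RMS giving ~20 dB SNR against the clean baseline recording.
noise_20db <- local({
  v <- NULL
  function() {
    if (is.null(v)) {
      rec <- synthesize_recording(test_baseline(), noise_uv_rms = 0,
                                  rr_variability = 0, seed = 1)
      vm <- sqrt(rowSums(rec$samples^2))
      v <<- sqrt(mean(vm^2)) / 10
    }
    v
  }
})

# Synthesize -> delineate one recording; return fiducial errors (ms,
# relative to the R peak) against the generator truth.
fiducial_errors <- function(params, noise_uv_rms, seed,
                            rr_variability = 0.02) {
  rec <- synthesize_recording(params, noise_uv_rms = noise_uv_rms,
                              rr_variability = rr_variability, seed = seed)
  rec2 <- resample_recording(rec, 1000)
  mb <- build_median_beat(rec2, detect_r_peaks(rec2))
  fid <- delineate_beat(mb)
  tru <- rec$truth[2, ]
  c(
    onset = (fid$qrs_onset_ms - fid$r_offset_ms) -
      (tru$qrs_onset_s - tru$r_s) * 1000,
    j = (fid$qrs_offset_ms - fid$r_offset_ms) -
      (tru$qrs_offset_s - tru$r_s) * 1000,
    tpeak = (fid$t_peak_ms - fid$r_offset_ms) -
      (tru$t_peak_s - tru$r_s) * 1000,
    tend = (fid$t_end_ms - fid$r_offset_ms) -
      (tru$t_end_s - tru$r_s) * 1000
  )
}

# Baseline beat at a different RR (other shape parameters unchanged).
baseline_at_rr <- function(rr) {
  b <- test_baseline()
  beat_params(
    qrs_duration_ms = b$qrs_duration_ms, j_to_tpeak_ms = b$j_to_tpeak_ms,
    sigma_asc_ms = b$sigma_asc_ms, sigma_desc_ms = b$sigma_desc_ms,
    t_amplitude_uv = b$t_amplitude_uv, t_tail_weight = b$t_tail_weight,
    rr_s = rr, shoulder_ratio = b$shoulder_ratio
  )
}

# Independent brute-force AUC oracle: explicit enumeration of all
# positive/negative pairs, ties counted one half.
brute_auc <- function(scores, labels, positive = "multichannel") {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(sp) * length(sn))
}

# Vectorized paired sign-swap permutation oracle for the DeLong test:
# swaps the two models' scores per subject and returns the two-sided
# permutation p-value of the AUC difference.
perm_delong_p <- function(scores_a, scores_b, labels, n_perm = 20000,
                          positive = "multichannel", seed = 1) {
  y <- labels == positive
  ap <- scores_a[y]; an <- scores_a[!y]
  bp <- scores_b[y]; bn <- scores_b[!y]
  m <- length(ap); n <- length(an)
  cmp <- function(x, z) outer(x, z, function(u, v) (u > v) + 0.5 * (u == v))
  Daa <- cmp(ap, an); Dab <- cmp(ap, bn)
  Dba <- cmp(bp, an); Dbb <- cmp(bp, bn)
  withr::with_seed(seed, {
    Sp <- matrix(stats::rbinom(n_perm * m, 1, 0.5), n_perm)
    Sn <- matrix(stats::rbinom(n_perm * n, 1, 0.5), n_perm)
  })
  Sp0 <- 1 - Sp; Sn0 <- 1 - Sn
  quad <- function(D, U, V) rowSums((U %*% D) * V)
  auc_a <- (quad(Daa, Sp0, Sn0) + quad(Dab, Sp0, Sn) +
              quad(Dba, Sp, Sn0) + quad(Dbb, Sp, Sn)) / (m * n)
  auc_b <- (quad(Dbb, Sp0, Sn0) + quad(Dba, Sp0, Sn) +
              quad(Dab, Sp, Sn0) + quad(Daa, Sp, Sn)) / (m * n)
  d_perm <- auc_a - auc_b
  d_obs <- mean(Daa) - mean(Dbb)
  mean(abs(d_perm) >= abs(d_obs) - 1e-12)
}

# Construct a t_segment directly from a sampled wave (for morphology unit
# tests that do not need the delineation pipeline).
make_segment <- function(t_ms, y_uv, fs_hz = 1000) {
  structure(list(t_ms = t_ms, y_uv = y_uv, peak_index = which.max(abs(y_uv)),
                 fs_hz = fs_hz),
            class = "t_segment")
}

# Long-format change table for a perfectly balanced noiseless crossover:
# `effect` is added to the active arm at the stated time-point.
balanced_changes <- function(n_subjects = 6, arms = c("placebo", "drug"),
                             timepoints = c(5, 13), effect = 45.2,
                             effect_arm = "drug", effect_time = 13,
                             biomarker = "qtc_ms") {
  g <- expand.grid(subject = sprintf("S%02d", seq_len(n_subjects)),
                   arm = arms, timepoint_h = timepoints,
                   stringsAsFactors = FALSE)
  g$period <- match(g$arm, arms)
  g$sequence <- "seq1"
  g$biomarker <- biomarker
  g$change <- ifelse(g$arm == effect_arm & g$timepoint_h == effect_time,
                     effect, 0)
  tibble::as_tibble(g)
}

# Reduced-size calibrated trial (one replicate, baseline + Tmax) plus its
# classification features — the workhorse for the ordering/coverage checks.
reduced_trial_features <- function(seed, n_subjects = 21) {
  d <- trial_design(n_subjects = n_subjects,
                    n_female = min(8, n_subjects),
                    timepoint_hours = c(0, 13),
                    replicates_per_timepoint = 1, seed = seed)
  tr <- simulate_trial(d)
  ch <- changes_from_baseline(correct_biomarkers(tr))
  list(changes = ch, features = classification_features(subject_delta_delta(ch)))
}
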