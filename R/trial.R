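#' Crossover trial design
#'
#' Defaults emulate the study conditions: 21 healthy subjects (8 female) in
#' a five-period randomized crossover, three doses per treatment day,
#' triplicate 10-s ECGs per time-point, with a pre-dose baseline and two
#' post-dose time-points (the second near the population Tmax).
#'
#' @param n_subjects,n_female Cohort size and number of females.
#' @param arms Arm identifiers; `"placebo"` must be present for the
#'   placebo-corrected analyses.
#' @param timepoint_hours ECG extraction times, hours after the first dose
#'   of the day; hour 0 is the pre-dose baseline.
#' @param replicates_per_timepoint Number of 10-s ECGs per time-point.
#' @param doses_per_day Number of doses per treatment day.
#' @param seed Integer root seed for the whole simulated trial.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n_subjects = 21, n_female = 8,
                         arms = c("placebo", "dofetilide", "moxifloxacin",
                                  "mexiletine+dofetilide",
                                  "lidocaine+dofetilide"),
                         timepoint_hours = c(0, 5, 13),
                         replicates_per_timepoint = 3,
                         doses_per_day = 3,
                         seed = 20160101) {
  stopifnot(n_subjects >= 2, n_female <= n_subjects,
            replicates_per_timepoint >= 1, length(arms) >= 1,
            !anyDuplicated(arms))
  structure(
    list(n_subjects = n_subjects, n_female = n_female, arms = arms,
         periods = length(arms), doses_per_day = doses_per_day,
         timepoint_hours = sort(timepoint_hours),
         replicates_per_timepoint = replicates_per_timepoint, seed = seed),
    class = "trial_design"
  )
}

# Drugs administered in each arm.
arm_drugs <- function(arm) {
  if (arm == "placebo") character(0) else strsplit(arm, "+", fixed = TRUE)[[1]]
}

# Williams-style sequence assignment: cyclic rotations of the arm list,
# subjects assigned to sequences round-robin.
arm_sequences <- function(arms, n_subjects) {
  k <- length(arms)
  seqs <- lapply(seq_len(k) - 1, function(s) arms[(seq_len(k) + s - 1) %% k + 1])
  lapply(seq_len(n_subjects), function(i) seqs[[(i - 1) %% k + 1]])
}

# Per-biomarker single-measurement noise SDs (one 10-s ECG), chosen so that
# per-subject placebo-corrected changes have spreads of the order of the
# study's reported confidence-interval widths.
measurement_noise_sd <- function() {
  c(qt_ms = 4, jtpeak_ms = 6, tpeaktend_ms = 8, flatness = 0.045,
    asymmetry = 0.08, erd_ms = 8, lrd_ms = 6, amplitude_uv = 40)
}

#' Bundle of calibrated models defining the synthetic study
#'
#' Baseline beat, drug-effect slopes, and per-drug pharmacokinetics with
#' the arm peak concentrations. Calibration is deterministic; the result
#' is cached for the session.
#'
#' @param erd_level ERD/LRD crossing level used in calibration and
#'   downstream measurement.
#' @return A list with `baseline` ([beat_params()]), `effects`
#'   ([drug_effect_model()]), `pk` (named list of [pk_model()]), `targets`.
#' @export
study_models <- function(erd_level = 0.70) {
  key <- paste0("m", erd_level)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  baseline <- calibrate_baseline_beat(erd_level = erd_level)
  effects <- calibrate_drug_effects(baseline)
  targets <- study_effect_targets()
  pk <- lapply(seq_len(nrow(targets)), function(i) {
    pk_calibrate_cmax(pk_model(), targets$cmax[i])
  })
  names(pk) <- targets$drug
  out <- list(baseline = baseline, effects = effects, pk = pk,
              targets = targets, erd_level = erd_level)
  .study_cache[[key]] <- out
  out
}
.study_cache <- new.env(parent = emptyenv())

#' Draw the subject cohort
#'
#' Subject-level baselines vary around the population targets (heart rate,
#' QTc, J-Tpeakc, T-wave widths, amplitude per the baseline table); each
#' subject carries lognormal sensitivity multipliers on the drug slopes
#' and lognormal pharmacokinetic multipliers on concentration.
#'
#' @param design A [trial_design()].
#' @param models A [study_models()] bundle.
#' @param slope_sdlog Lognormal SD of the per-subject, per-drug
#'   sensitivity multipliers.
#' @param pk_sdlog Lognormal SD of the per-subject concentration
#'   multipliers.
#' @return A tibble, one row per subject.
#' @export
make_subjects <- function(design, models = study_models(),
                          slope_sdlog = 0.35, pk_sdlog = 0.25) {
  base <- models$baseline
  n <- design$n_subjects
  drugs <- models$targets$drug
  seqs <- arm_sequences(design$arms, n)
  rr <- pmin(pmax(stats::rnorm(n, base$rr_s, 0.10), 0.75), 1.30)
  qtc <- stats::rnorm(n, 397.1, 14.0)
  qrs <- pmin(pmax(stats::rnorm(n, base$qrs_duration_ms, 8), 55), 130)
  sigma_d <- base$sigma_desc_ms * exp(stats::rnorm(n, 0, 0.07))
  w <- pmin(base$t_tail_weight * exp(stats::rnorm(n, 0, 0.10)), 0.9)
  sigma_a <- base$sigma_asc_ms * exp(stats::rnorm(n, 0, 0.14))
  amp <- pmax(stats::rnorm(n, 569, 149), 150)
  tpte <- vapply(seq_len(n), function(i) {
    tangent_tend_ms(sigma_d[i], w[i], base$shoulder_ratio)
  }, numeric(1))
  al <- correction_alphas()
  # J-Tpeakc is derived so each subject's QTc, QRS and Tpeak-Tend stay
  # mutually consistent; its spread matches the cohort table's ~18 ms SD
  jtpc <- (qtc * rr^al[["qt"]] - qrs - tpte) / rr^al[["jtpeak"]]
  sens <- matrix(stats::rlnorm(n * length(drugs),
                               meanlog = -slope_sdlog^2 / 2,
                               sdlog = slope_sdlog), n)
  pkm <- matrix(stats::rlnorm(n * length(drugs),
                              meanlog = -pk_sdlog^2 / 2,
                              sdlog = pk_sdlog), n)
  colnames(sens) <- paste0("sens_", drugs)
  colnames(pkm) <- paste0("pkmult_", drugs)
  tibble::tibble(
    subject = sprintf("S%02d", seq_len(n)),
    sex = c(rep("F", design$n_female), rep("M", n - design$n_female)),
    sequence = vapply(seqs, paste, collapse = "|", character(1)),
    baseline_rr_s = rr, qtc_i = qtc, jtpeakc_i = jtpc,
    sigma_desc_i = sigma_d, tail_weight_i = w, sigma_asc_i = sigma_a,
    amplitude_i = amp, qrs_i = qrs
  ) |>
    dplyr::bind_cols(tibble::as_tibble(sens), tibble::as_tibble(pkm))
}

# Beat parameters for one subject at instantaneous RR and drug
# concentrations (already multiplied by the subject's sensitivities).
subject_beat_params <- function(subj, models, rr_t, conc) {
  base <- models$baseline
  al <- correction_alphas()
  p0 <- beat_params(
    qrs_duration_ms = subj$qrs_i,
    j_to_tpeak_ms = subj$jtpeakc_i * rr_t^al[["jtpeak"]],
    sigma_asc_ms = subj$sigma_asc_i,
    sigma_desc_ms = subj$sigma_desc_i,
    t_amplitude_uv = (subj$amplitude_i / subj$baseline_rr_s^al[["amplitude"]]) *
      rr_t^al[["amplitude"]],
    t_tail_weight = subj$tail_weight_i,
    rr_s = rr_t,
    shoulder_ratio = base$shoulder_ratio
  )
  if (length(conc) == 0 || all(conc == 0)) return(p0)
  apply_drug_effect(p0, models$effects, conc)
}

#' Simulate the full synthetic crossover trial
#'
#' Every subject passes through every arm (Williams-style sequences); per
#' period there is a pre-dose baseline and post-dose time-points, each
#' with replicate 10-s recordings. Drug concentrations follow the
#' calibrated pharmacokinetics with per-subject multipliers; beat
#' parameters respond linearly to concentration through the calibrated
#' effect model; the placebo arm carries zero drug effect.
#'
#' With `waveforms = FALSE` (the default) the measurement step is
#' emulated: each recording contributes the ground-truth biomarkers of its
#' beat parameters plus independent measurement noise. With
#' `waveforms = TRUE`, 10-s multi-lead recordings are synthesized for
#' delineation by the measurement pipeline.
#'
#' @param design A [trial_design()].
#' @param models A [study_models()] bundle.
#' @param waveforms Emit waveform recordings instead of biomarker rows.
#' @param noise_uv_rms,rr_variability Waveform-path noise settings, see
#'   [synthesize_recording()].
#' @param measurement_noise Named vector of biomarker measurement noise
#'   SDs for the fast path (see `measurement_noise_sd()`); use 0 to
#'   disable.
#' @return With `waveforms = FALSE`: a tibble of biomarker measurements
#'   (one row per subject x arm x time-point x replicate) with metadata
#'   and per-drug concentration columns. With `waveforms = TRUE`: a list
#'   with `recordings` (list of [ecg_recording()]) and `meta` (tibble).
#'   The subject table is attached as attribute `subjects`.
#' @export
simulate_trial <- function(design = trial_design(), models = study_models(),
                           waveforms = FALSE, noise_uv_rms = 12,
                           rr_variability = 0.02,
                           measurement_noise = measurement_noise_sd()) {
  stopifnot(inherits(design, "trial_design"))
  if (design$n_subjects < 2) stop("at least 2 subjects required")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(design$seed)
  subjects <- make_subjects(design, models)
  drugs <- models$targets$drug
  grid <- tidyr::expand_grid(
    si = seq_len(design$n_subjects),
    period = seq_len(design$periods),
    timepoint_h = design$timepoint_hours,
    replicate = seq_len(design$replicates_per_timepoint)
  )
  seqs <- arm_sequences(design$arms, design$n_subjects)
  grid$arm <- vapply(seq_len(nrow(grid)),
                     function(i) seqs[[grid$si[i]]][grid$period[i]],
                     character(1))
  noise <- measurement_noise
  if (length(noise) == 1 && noise == 0) {
    noise <- measurement_noise_sd() * 0
  }
  rows <- vector("list", nrow(grid))
  recordings <- if (waveforms) vector("list", nrow(grid)) else NULL
  rec_seeds <- sample.int(.Machine$integer.max, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    subj <- subjects[g$si, ]
    rr_t <- subj$baseline_rr_s * exp(stats::rnorm(1, 0, 0.015))
    active <- arm_drugs(g$arm)
    conc_all <- vapply(drugs, function(d) {
      if (d %in% active) {
        simulate_pk(models$pk[[d]], g$timepoint_h) *
          subj[[paste0("pkmult_", d)]]
      } else 0
    }, numeric(1))
    eff_conc <- vapply(drugs, function(d) {
      conc_all[[d]] * subj[[paste0("sens_", d)]]
    }, numeric(1))
    params <- subject_beat_params(subj, models, rr_t, eff_conc[eff_conc > 0])
    meta <- tibble::tibble(
      subject = subj$subject, sex = subj$sex, arm = g$arm,
      period = g$period, sequence = subj$sequence,
      timepoint_h = g$timepoint_h, replicate = g$replicate
    )
    conc_tbl <- tibble::as_tibble(as.list(stats::setNames(
      conc_all, paste0("conc_", drugs))))
    if (waveforms) {
      recordings[[i]] <- synthesize_recording(
        params, noise_uv_rms = noise_uv_rms,
        rr_variability = rr_variability,
        metadata = c(as.list(meta), as.list(conc_tbl)),
        seed = rec_seeds[i]
      )
      rows[[i]] <- dplyr::bind_cols(meta, conc_tbl)
    } else {
      tb <- truth_biomarkers(params, erd_level = models$erd_level)
      tb$rr_s <- rr_t
      for (nm in names(noise)) {
        tb[[nm]] <- tb[[nm]] + stats::rnorm(1, 0, noise[[nm]])
      }
      rows[[i]] <- dplyr::bind_cols(meta, conc_tbl, tb)
    }
  }
  meta_tbl <- dplyr::bind_rows(rows)
  if (waveforms) {
    out <- list(recordings = recordings, meta = meta_tbl)
  } else {
    out <- meta_tbl
  }
  attr(out, "subjects") <- subjects
  attr(out, "design") <- design
  out
}

#' Delineate every recording of a waveform-path trial
#'
#' @param trial The list returned by `simulate_trial(waveforms = TRUE)`.
#' @param ... Passed to [delineate_recording()].
#' @return A biomarker tibble in the same layout as the fast path.
#' @export
delineate_trial <- function(trial, ...) {
  stopifnot(is.list(trial), !is.null(trial$recordings))
  purrr::map_dfr(trial$recordings, function(rec) {
    delineate_recording(rec, ...)
  })
}
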