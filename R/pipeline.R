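#' Pipeline configuration
#'
#' Every tunable of the end-to-end run with its default and unit.
#'
#' @param out_dir Output directory for stage tables and the manifest.
#' @param seed Integer root seed governing every stochastic stage.
#' @param n_subjects,n_female,timepoint_hours,replicates_per_timepoint
#'   Trial-design settings (see [trial_design()]).
#' @param arms Arm identifiers.
#' @param waveforms Run the waveform path (synthesize and delineate 10-s
#'   ECGs) instead of the fast biomarker path.
#' @param analysis_fs_hz Delineation analysis rate, Hz.
#' @param noise_uv_rms Waveform noise RMS, microvolts.
#' @param erd_level ERD/LRD crossing level (fraction of peak).
#' @param seg_level T-onset surrogate level (fraction of peak).
#' @param jtpeak_alpha J-Tpeak correction exponent.
#' @param n_boot Bootstrap replicates for AUC/accuracy CIs.
#' @param cv_folds Cross-validation folds for the tree learner.
#' @param jtpeakc_threshold_ms,qtc_threshold_ms Fixed decision-rule
#'   thresholds, ms.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("repolsig-run-"),
                            seed = 20160101,
                            n_subjects = 21, n_female = 8,
                            arms = c("placebo", "dofetilide", "moxifloxacin",
                                     "mexiletine+dofetilide",
                                     "lidocaine+dofetilide"),
                            timepoint_hours = c(0, 5, 13),
                            replicates_per_timepoint = 3,
                            waveforms = FALSE,
                            analysis_fs_hz = 1000,
                            noise_uv_rms = 12,
                            erd_level = 0.70, seg_level = 0.05,
                            jtpeak_alpha = 0.58,
                            n_boot = 2000, cv_folds = 10,
                            jtpeakc_threshold_ms = 9,
                            qtc_threshold_ms = 29) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

# Class label implied by an arm: combinations with a late sodium blocker
# are multichannel, single-drug hERG blockers are hERG, placebo has none.
arm_class_label <- function(arm) {
  dplyr::case_when(
    arm %in% c("dofetilide", "moxifloxacin") ~ "hERG",
    arm %in% c("mexiletine+dofetilide", "lidocaine+dofetilide") ~ "multichannel",
    TRUE ~ NA_character_
  )
}

#' Classification feature table from per-subject placebo-corrected changes
#'
#' One row per subject, arm and time-point, with the placebo-corrected
#' changes spread into columns (`dd_` prefix) and the class label derived
#' from the arm; unlabeled (placebo-like) arms are dropped.
#'
#' @param sdd Output of [subject_delta_delta()].
#' @return A wide tibble with a `label` column.
#' @export
classification_features <- function(sdd) {
  wide <- sdd |>
    dplyr::select(subject, arm, timepoint_h, biomarker, dd) |>
    tidyr::pivot_wider(names_from = biomarker, values_from = dd,
                       names_prefix = "dd_")
  wide$label <- arm_class_label(wide$arm)
  dplyr::filter(wide, !is.na(.data$label))
}

#' Run the full analysis pipeline
#'
#' Simulate (or accept) a trial, measure biomarkers, correct for heart
#' rate, compute placebo-corrected changes, fit the mixed-model
#' estimates, run the ROC comparison and the fixed decision rule, and
#' persist every intermediate table plus a run manifest to
#' `config$out_dir`. A fixed seed gives byte-identical outputs across
#' runs.
#'
#' @param config A [pipeline_config()].
#' @param biomarkers Optional pre-measured biomarker table (skips
#'   simulation/delineation).
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), biomarkers = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(stage, n) {
    message(sprintf("[%s] %d rows", stage, n))
  }
  counts <- list()
  design <- trial_design(
    n_subjects = config$n_subjects, n_female = config$n_female,
    arms = config$arms, timepoint_hours = config$timepoint_hours,
    replicates_per_timepoint = config$replicates_per_timepoint,
    seed = config$seed
  )
  models <- study_models(erd_level = config$erd_level)
  if (is.null(biomarkers)) {
    if (config$waveforms) {
      trial <- simulate_trial(design, models, waveforms = TRUE,
                              noise_uv_rms = config$noise_uv_rms)
      biomarkers <- delineate_trial(trial,
                                    analysis_fs_hz = config$analysis_fs_hz,
                                    erd_level = config$erd_level,
                                    seg_level = config$seg_level)
    } else {
      biomarkers <- simulate_trial(design, models, waveforms = FALSE)
    }
  }
  counts$recordings <- nrow(biomarkers)
  log_stage("simulate/measure", nrow(biomarkers))
  write_table(biomarkers, file.path(config$out_dir, "biomarkers.csv"))

  spec <- correction_spec(alphas = c(jtpeak = config$jtpeak_alpha))
  corrected <- correct_biomarkers(biomarkers, spec)
  write_table(corrected, file.path(config$out_dir, "biomarkers_corrected.csv"))

  changes <- changes_from_baseline(corrected)
  counts$changes <- nrow(changes)
  log_stage("changes", nrow(changes))
  write_table(changes, file.path(config$out_dir, "changes.csv"))

  dd <- delta_delta(changes)
  write_table(dd, file.path(config$out_dir, "delta_delta.csv"))
  log_stage("delta-delta", nrow(dd))

  sdd <- subject_delta_delta(changes)
  features <- classification_features(sdd)
  counts$feature_rows <- nrow(features)
  if (nrow(features) == 0 || length(unique(features$label)) < 2) {
    stop("classifier stage refused: fewer than two classes among the arms ",
         "(labels present: ",
         paste(unique(features$label), collapse = ", "), ")")
  }
  write_table(features, file.path(config$out_dir, "features.csv"))

  fsets <- list(
    jtpeakc = "dd_jtpeakc_ms",
    qtc = "dd_qtc_ms",
    flatness = "dd_flatness_c",
    `qtc+jtpeakc` = c("dd_qtc_ms", "dd_jtpeakc_ms")
  )
  fsets <- purrr::keep(fsets, function(fs) all(fs %in% names(features)))
  roc <- roc_analysis(features, fsets, n_boot = config$n_boot,
                      seed = config$seed)
  write_table(roc, file.path(config$out_dir, "roc.csv"))
  log_stage("roc", nrow(roc))

  rule <- tree_rule(config$jtpeakc_threshold_ms, config$qtc_threshold_ms)
  calls <- features
  calls$call <- tree_classify(features$dd_jtpeakc_ms, features$dd_qtc_ms, rule)
  tree_eval <- evaluate_classifier(calls$call, calls$label,
                                   n_boot = config$n_boot,
                                   seed = config$seed)
  write_table(calls, file.path(config$out_dir, "tree_calls.csv"))
  log_stage("tree", nrow(calls))

  manifest <- list(
    config_hash = rlang::hash(unclass(config)[setdiff(names(config), "out_dir")]),
    seed = config$seed,
    version = as.character(tryCatch(utils::packageVersion("repolsig"),
                                    error = function(e) "dev")),
    counts = counts,
    tree_accuracy = tree_eval$accuracy
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    config = config, biomarkers = biomarkers, corrected = corrected,
    changes = changes, delta_delta = dd, features = features, roc = roc,
    tree_calls = calls, tree_eval = tree_eval, manifest = manifest
  ))
}

# --- delimited-text I/O ---------------------------------------------------

#' Write/read a stage table (comma-separated, header row, UTF-8)
#'
#' @param tbl A data frame.
#' @param path Output path.
#' @return `write_table` returns the path invisibly; `read_table` the
#'   tibble.
#' @export
write_table <- function(tbl, path) {
  utils::write.csv(as.data.frame(tbl), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, fileEncoding = "UTF-8",
                                    check.names = FALSE))
}

#' Write/read a waveform recording as delimited text
#'
#' The waveform file has a `time_s` column plus one column per lead
#' (microvolts); a JSON sidecar (`<stem>_meta.json`) carries the sampling
#' rate, lead names, metadata and any truth annotations.
#'
#' @param rec An [ecg_recording()].
#' @param stem Path stem (without extension).
#' @return `write_waveform` returns the stem invisibly; `read_waveform`
#'   the reconstructed [ecg_recording()].
#' @export
write_waveform <- function(rec, stem) {
  stopifnot(inherits(rec, "ecg_recording"))
  df <- data.frame(time_s = (seq_len(nrow(rec$samples)) - 1) / rec$fs_hz)
  for (k in seq_along(rec$lead_names)) df[[rec$lead_names[k]]] <- rec$samples[, k]
  utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE,
                   fileEncoding = "UTF-8")
  meta <- list(fs_hz = rec$fs_hz, lead_names = rec$lead_names,
               units = "uV", metadata = rec$metadata,
               truth = rec$truth)
  jsonlite::write_json(meta, paste0(stem, "_meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(stem)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(stem) {
  csv <- if (grepl("\\.csv$", stem)) stem else paste0(stem, ".csv")
  stem <- sub("\\.csv$", "", csv)
  df <- utils::read.csv(csv, fileEncoding = "UTF-8", check.names = FALSE)
  if (!"time_s" %in% names(df)) {
    stop("waveform file is missing the required `time_s` column")
  }
  meta_path <- paste0(stem, "_meta.json")
  if (!file.exists(meta_path)) {
    stop("waveform sidecar not found (required field: fs_hz): ", meta_path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$fs_hz)) stop("waveform sidecar is missing the field `fs_hz`")
  leads <- setdiff(names(df), "time_s")
  truth <- if (!is.null(meta$truth) && length(meta$truth)) {
    tibble::as_tibble(meta$truth)
  } else {
    NULL
  }
  ecg_recording(as.matrix(df[leads]), meta$fs_hz, lead_names = leads,
                metadata = as.list(meta$metadata), truth = truth)
}
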