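utils::globalVariables(c(
  "arm", "timepoint_h", "replicate", "subject", "period", "sequence",
  "biomarker", "value", "change", "baseline", "estimate"
))

# Biomarker value columns of a corrected table.
biomarker_columns <- function(tbl) {
  known <- c("qtc_ms", "jtpeakc_ms", "tpeaktend_ms", "flatness_c",
             "asymmetry", "erd_ms", "lrd_ms", "amplitude_c_uv", "vg_c_uvs",
             "qt_ms", "jtpeak_ms", "flatness", "amplitude_uv", "vg_uvs")
  intersect(known, names(tbl))
}

#' Changes from baseline per subject, arm and time-point
#'
#' Replicate recordings within a time-point are aggregated by their
#' median; the change is relative to the period-specific pre-dose
#' baseline (`timepoint_h == baseline_timepoint`).
#'
#' @param tbl Corrected biomarker tibble (see [correct_biomarkers()]).
#' @param baseline_timepoint Hour identifying the pre-dose baseline rows.
#' @param value_cols Biomarker columns; default: every recognized
#'   biomarker column present.
#' @return A long tibble with columns `subject`, `sex`, `arm`, `period`,
#'   `sequence`, `timepoint_h`, `biomarker`, `change` plus per-drug mean
#'   concentration columns, covering post-baseline time-points only.
#' @export
changes_from_baseline <- function(tbl, baseline_timepoint = 0,
                                  value_cols = biomarker_columns(tbl)) {
  stopifnot(length(value_cols) > 0)
  conc_cols <- grep("^conc_", names(tbl), value = TRUE)
  agg <- tbl |>
    dplyr::group_by(subject, arm, period, sequence, timepoint_h,
                    .add = FALSE) |>
    dplyr::summarise(
      dplyr::across(dplyr::any_of(c("sex")), dplyr::first),
      dplyr::across(dplyr::all_of(c(value_cols, conc_cols)),
                    stats::median),
      .groups = "drop"
    )
  base <- agg |>
    dplyr::filter(timepoint_h == baseline_timepoint) |>
    dplyr::select(subject, arm, period,
                  dplyr::all_of(value_cols)) |>
    tidyr::pivot_longer(dplyr::all_of(value_cols),
                        names_to = "biomarker", values_to = "baseline")
  post <- agg |>
    dplyr::filter(timepoint_h != baseline_timepoint) |>
    tidyr::pivot_longer(dplyr::all_of(value_cols),
                        names_to = "biomarker", values_to = "value")
  out <- dplyr::inner_join(post, base,
                           by = c("subject", "arm", "period", "biomarker"))
  if (nrow(out) < nrow(post)) {
    stop("missing pre-dose baseline rows for some subject/period")
  }
  out |>
    dplyr::mutate(change = value - baseline) |>
    dplyr::select(-value, -baseline)
}

#' Placebo-corrected change from baseline (mixed-model estimate)
#'
#' Per biomarker, fits the crossover model
#' `change ~ sequence + period + time + treatment + treatment:time` with a
#' subject random intercept, and reports the treatment-minus-placebo
#' adjusted mean with a 95% confidence interval per active arm and
#' time-point. Under a balanced noiseless design the estimate equals the
#' cell-means contrast. If the mixed model cannot be fitted (degenerate
#' variance), subject is absorbed as a fixed intercept, which leaves the
#' contrast unchanged under balance.
#'
#' @param changes Long change table from [changes_from_baseline()].
#' @param ref_arm Reference (placebo) arm.
#' @return A tibble with `biomarker`, `arm`, `timepoint_h`, `estimate`,
#'   `ci_low`, `ci_high`, `se`, `p_value`.
#' @export
delta_delta <- function(changes, ref_arm = "placebo") {
  if (!ref_arm %in% changes$arm) stop("placebo arm rows are required")
  if (length(setdiff(unique(changes$arm), ref_arm)) == 0) {
    return(tibble::tibble(
      biomarker = character(), arm = character(), timepoint_h = numeric(),
      estimate = numeric(), ci_low = numeric(), ci_high = numeric(),
      se = numeric(), p_value = numeric()
    ))
  }
  purrr::map_dfr(split(changes, changes$biomarker), function(d) {
    d$arm <- stats::relevel(factor(d$arm), ref = ref_arm)
    d$timepoint <- factor(d$timepoint_h)
    d$period <- factor(d$period)
    d$sequence <- factor(d$sequence)
    d$subject <- factor(d$subject)
    single_tp <- nlevels(d$timepoint) == 1
    # drop design factors that are constant in this dataset (e.g. a single
    # sequence in a toy balanced design)
    terms <- c(
      if (nlevels(d$sequence) > 1) "sequence",
      if (nlevels(d$period) > 1) "period",
      if (!single_tp) "timepoint",
      "arm",
      if (!single_tp) "arm:timepoint"
    )
    form_fix <- stats::reformulate(terms, response = "change")
    fit <- tryCatch(
      suppressMessages(suppressWarnings(lmerTest::lmer(
        stats::update(form_fix, . ~ . + (1 | subject)), data = d,
        control = lme4::lmerControl(check.conv.singular = "ignore")
      ))),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      fit <- stats::lm(stats::update(form_fix, . ~ . + subject), data = d)
    }
    em <- suppressMessages(emmeans::emmeans(
      fit, if (single_tp) ~arm else ~ arm | timepoint,
      lmer.df = "satterthwaite"
    ))
    ct <- summary(stats::confint(emmeans::contrast(
      em, method = "trt.vs.ctrl", ref = 1
    ), level = 0.95), infer = c(TRUE, TRUE))
    tibble::tibble(
      biomarker = d$biomarker[1],
      arm = sub(" - .*$", "", ct$contrast),
      timepoint_h = if (single_tp) unique(d$timepoint_h) else
        as.numeric(as.character(ct$timepoint)),
      estimate = ct$estimate,
      ci_low = ct$lower.CL,
      ci_high = ct$upper.CL,
      se = ct$SE,
      p_value = ct$p.value
    )
  })
}

#' Per-subject placebo-corrected changes
#'
#' Time-matched subtraction of each subject's placebo change from the
#' active-arm change — the individual-level placebo correction used for
#' the classification features, the mitigation test and the effect sizes.
#'
#' @param changes Long change table from [changes_from_baseline()].
#' @param ref_arm Reference (placebo) arm.
#' @return A tibble with `subject`, `arm`, `timepoint_h`, `biomarker`,
#'   `dd` plus the active arm's concentration columns.
#' @export
subject_delta_delta <- function(changes, ref_arm = "placebo") {
  conc_cols <- grep("^conc_", names(changes), value = TRUE)
  plac <- changes |>
    dplyr::filter(arm == ref_arm) |>
    dplyr::select(subject, timepoint_h, biomarker, placebo_change = change)
  changes |>
    dplyr::filter(arm != ref_arm) |>
    dplyr::inner_join(plac, by = c("subject", "timepoint_h", "biomarker")) |>
    dplyr::mutate(dd = change - .data$placebo_change) |>
    dplyr::select(subject, arm, timepoint_h, biomarker, dd,
                  dplyr::all_of(conc_cols))
}

#' Concentration-response mixed model
#'
#' Linear model of biomarker change on plasma concentration with a random
#' intercept and slope per subject (restricted maximum likelihood). When
#' the mixed fit is degenerate, falls back to the two-stage estimator
#' (mean of per-subject least-squares slopes), which agrees with the
#' mixed-model population slope under balance.
#'
#' @param rows A data frame with columns `subject`, `conc` and `change`.
#' @return An object of class `conc_response`: population `intercept` and
#'   `slope`, their standard errors, random-effect variances, `n_subjects`
#'   and the fitting `method`.
#' @export
conc_response_fit <- function(rows) {
  stopifnot(all(c("subject", "conc", "change") %in% names(rows)))
  if (length(unique(rows$conc)) < 2) {
    stop("all concentrations identical: no concentration-response slope")
  }
  if (length(unique(rows$subject)) < 5) {
    stop("at least 5 subjects with concentration data required")
  }
  d <- data.frame(subject = factor(rows$subject), conc = rows$conc,
                  change = rows$change)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(lme4::lmer(
      change ~ conc + (conc | subject), data = d, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE)
    ))),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    fe <- lme4::fixef(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    re_var <- c(
      intercept = vc$vcov[vc$var1 %in% "(Intercept)" & is.na(vc$var2)][1],
      slope = vc$vcov[vc$var1 %in% "conc" & is.na(vc$var2)][1]
    )
    cov_is <- vc$vcov[!is.na(vc$var2)][1]
    out <- list(
      intercept = unname(fe[1]), slope = unname(fe[2]),
      se_intercept = se[1], se_slope = se[2],
      vcov_fixed = as.matrix(stats::vcov(fit)),
      re_variances = re_var, re_covariance = cov_is,
      sigma = stats::sigma(fit),
      n_subjects = length(unique(d$subject)), method = "reml"
    )
  } else {
    per <- lapply(split(d, d$subject), function(s) {
      stats::coef(stats::lm(change ~ conc, data = s))
    })
    m <- do.call(rbind, per)
    out <- list(
      intercept = mean(m[, 1]), slope = mean(m[, 2]),
      se_intercept = stats::sd(m[, 1]) / sqrt(nrow(m)),
      se_slope = stats::sd(m[, 2]) / sqrt(nrow(m)),
      vcov_fixed = diag(c(stats::var(m[, 1]) / nrow(m),
                          stats::var(m[, 2]) / nrow(m))),
      re_variances = c(intercept = stats::var(m[, 1]),
                       slope = stats::var(m[, 2])),
      re_covariance = stats::cov(m[, 1], m[, 2]),
      sigma = NA_real_,
      n_subjects = nrow(m), method = "two-stage"
    )
  }
  class(out) <- "conc_response"
  out
}

#' @export
print.conc_response <- function(x, ...) {
  cat(sprintf(
    "<conc_response> slope %.4g (SE %.3g) per ng/mL, intercept %.4g (SE %.3g), %d subjects [%s]\n",
    x$slope, x$se_slope, x$intercept, x$se_intercept, x$n_subjects, x$method))
  invisible(x)
}

#' Predict the ECG signature at fractions of Cmax
#'
#' Population predictions of the QTc model and a companion biomarker
#' model at fractions of the population Cmax, with delta-method 95%
#' confidence intervals; the signature is the biomarker-vs-QTc curve.
#'
#' @param model_qtc,model_biomarker [conc_response_fit()] objects from the
#'   same arm.
#' @param cmax Population Cmax (ng/mL, `> 0`).
#' @param fractions Fractions of Cmax at which to predict.
#' @return A tibble of class `signature_points` with predictions and CIs
#'   for both models at each fraction.
#' @export
predict_signature <- function(model_qtc, model_biomarker, cmax,
                              fractions = c(0.25, 0.5, 0.75, 1)) {
  if (cmax <= 0) stop("cmax must be positive")
  fractions <- sort(fractions)
  pred_one <- function(m, conc) {
    est <- m$intercept + m$slope * conc
    x <- c(1, conc)
    se <- sqrt(drop(t(x) %*% m$vcov_fixed %*% x))
    c(est = est, lo = est - 1.96 * se, hi = est + 1.96 * se)
  }
  out <- purrr::map_dfr(fractions, function(f) {
    q <- pred_one(model_qtc, f * cmax)
    b <- pred_one(model_biomarker, f * cmax)
    tibble::tibble(
      cmax_fraction = f,
      dqtc = q[["est"]], dqtc_lo = q[["lo"]], dqtc_hi = q[["hi"]],
      dbio = b[["est"]], dbio_lo = b[["lo"]], dbio_hi = b[["hi"]]
    )
  })
  class(out) <- c("signature_points", class(out))
  out
}

#' Mitigation test for a combination arm
#'
#' Per subject, the predicted selective-hERG change at the subject's
#' measured dofetilide concentration (from the dofetilide-alone
#' concentration-response model) is compared with the observed
#' combination change by a paired t-test: a negative mean difference
#' means the late sodium blocker mitigated the hERG effect.
#'
#' @param observed A data frame with `subject` and `dd` (observed
#'   combination placebo-corrected changes at the peak time-point).
#' @param model A [conc_response_fit()] for the hERG blocker alone.
#' @param conc A data frame with `subject` and `conc` (the subject's
#'   measured hERG-blocker concentration in the combination arm).
#' @return A list: `mean_difference`, `p_value`, `t`, `df`, `n`,
#'   `effect_size` (paired Cohen's d of observed vs predicted).
#' @export
mitigation_test <- function(observed, model, conc) {
  d <- dplyr::inner_join(observed, conc, by = "subject")
  if (nrow(d) < 3) stop("at least 3 paired subjects required")
  if (nrow(d) != nrow(observed) || nrow(d) != nrow(conc)) {
    stop("observed and concentration tables must cover the same subjects")
  }
  predicted <- model$intercept + model$slope * d$conc
  dif <- d$dd - predicted
  if (stats::sd(dif) == 0) {
    # degenerate pairs: identical differences leave no paired variance
    p <- if (mean(dif) == 0) 1 else 0
    return(list(mean_difference = mean(dif), p_value = p,
                t = if (mean(dif) == 0) 0 else sign(mean(dif)) * Inf,
                df = nrow(d) - 1, n = nrow(d),
                effect_size = if (mean(dif) == 0) {
                  list(cohens_d = 0, label = "negligible")
                } else {
                  NULL
                }))
  }
  tt <- stats::t.test(d$dd, predicted, paired = TRUE)
  es <- cohens_d(d$dd, predicted, paired = TRUE)
  list(
    mean_difference = unname(tt$estimate), p_value = tt$p.value,
    t = unname(tt$statistic), df = unname(tt$parameter), n = nrow(d),
    effect_size = es
  )
}

#' Cohen's d effect size with qualitative label
#'
#' `d = mean difference / SD`, where the SD is the paired-difference SD
#' (paired) or the pooled SD (unpaired). Labels: negligible (`|d| < 0.2`),
#' small (`< 0.5`), medium (`< 0.8`), large (`>= 0.8`) — left-closed at
#' each printed bound.
#'
#' @param x,y Numeric samples (`n >= 2` each; equal length if paired).
#' @param paired Paired samples?
#' @return A list with `cohens_d` and `label`.
#' @export
cohens_d <- function(x, y, paired = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (paired) {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    dif <- x - y
    s <- stats::sd(dif)
    if (s == 0) {
      if (mean(dif) == 0) {
        return(list(cohens_d = 0, label = "negligible"))
      }
      stop("zero variance with nonzero mean difference")
    }
    d <- mean(dif) / s
  } else {
    sp <- sqrt(((length(x) - 1) * stats::var(x) +
                  (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
    if (sp == 0) {
      if (mean(x) == mean(y)) {
        return(list(cohens_d = 0, label = "negligible"))
      }
      stop("zero pooled variance with different means")
    }
    d <- (mean(x) - mean(y)) / sp
  }
  a <- abs(d)
  label <- if (a < 0.2) "negligible" else if (a < 0.5) "small" else
    if (a < 0.8) "medium" else "large"
  list(cohens_d = d, label = label)
}
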