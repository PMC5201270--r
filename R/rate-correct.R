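#' Fridericia heart-rate correction
#'
#' `QTc = QT / RR^(1/3)`; RR = 1 s is a fixed point.
#'
#' @param qt_ms QT interval, ms (`> 0`).
#' @param rr_s RR interval, seconds (`> 0`).
#' @return Corrected QT, ms.
#' @export
fridericia <- function(qt_ms, rr_s) {
  if (any(qt_ms <= 0) || any(rr_s <= 0)) stop("qt_ms and rr_s must be positive")
  qt_ms / rr_s^(1 / 3)
}

#' Exponential heart-rate correction
#'
#' `biomarker_c = biomarker / RR^alpha`; RR = 1 s is a fixed point for any
#' alpha, and alpha = 0 is the identity.
#'
#' @param value Biomarker value (finite).
#' @param rr_s RR interval, seconds (`> 0`).
#' @param alpha Correction exponent (dimensionless).
#' @return Corrected value.
#' @export
apply_exponential <- function(value, rr_s, alpha) {
  if (any(!is.finite(value))) stop("value must be finite")
  if (any(rr_s <= 0)) stop("rr_s must be positive")
  value / rr_s^alpha
}

#' Heart-rate correction specification
#'
#' Which correction applies to each biomarker column: Fridericia for QT,
#' exponential for the rate-dependent morphology biomarkers, none for the
#' rest. Default exponents are 0.58 for J-Tpeak, 0.50 for flatness, 0.96
#' for T-vector amplitude and 1.17 for the ventricular gradient.
#'
#' @param alphas Named numeric overrides of the default exponents
#'   (names among `qt`, `jtpeak`, `flatness`, `amplitude`, `vg`).
#' @param provenance Provenance tag for the exponents.
#' @return A tibble with columns `biomarker`, `column`, `kind`, `alpha`,
#'   `corrected_column`, `provenance`.
#' @export
correction_spec <- function(alphas = NULL, provenance = "literature") {
  al <- correction_alphas()
  if (!is.null(alphas)) al[names(alphas)] <- alphas
  tibble::tibble(
    biomarker = c("qt", "jtpeak", "flatness", "amplitude", "vg",
                  "tpeaktend", "asymmetry", "erd", "lrd"),
    column = c("qt_ms", "jtpeak_ms", "flatness", "amplitude_uv", "vg_uvs",
               "tpeaktend_ms", "asymmetry", "erd_ms", "lrd_ms"),
    kind = c("fridericia", "exponential", "exponential", "exponential",
             "exponential", "none", "none", "none", "none"),
    alpha = c(1 / 3, al[["jtpeak"]], al[["flatness"]], al[["amplitude"]],
              al[["vg"]], 0, 0, 0, 0),
    corrected_column = c("qtc_ms", "jtpeakc_ms", "flatness_c",
                         "amplitude_c_uv", "vg_c_uvs",
                         "tpeaktend_ms", "asymmetry", "erd_ms", "lrd_ms"),
    provenance = provenance
  )
}

#' Apply heart-rate corrections to a biomarker table
#'
#' QT receives Fridericia; J-Tpeak, flatness, amplitude (and the
#' ventricular gradient, if present) receive the exponential correction
#' with the spec's exponents; Tpeak-Tend, asymmetry and ERD/LRD are
#' reported uncorrected. Corrected columns are renamed with the
#' c-suffix convention.
#'
#' @param tbl Biomarker tibble with an `rr_s` column.
#' @param spec A [correction_spec()].
#' @return The corrected tibble.
#' @export
correct_biomarkers <- function(tbl, spec = correction_spec()) {
  if (!"rr_s" %in% names(tbl)) stop("biomarker table must carry an rr_s column")
  for (i in seq_len(nrow(spec))) {
    col <- spec$column[i]
    if (!col %in% names(tbl)) next
    out_col <- spec$corrected_column[i]
    kind <- spec$kind[i]
    if (kind == "fridericia") {
      tbl[[out_col]] <- fridericia(tbl[[col]], tbl$rr_s)
    } else if (kind == "exponential") {
      tbl[[out_col]] <- apply_exponential(tbl[[col]], tbl$rr_s, spec$alpha[i])
    } else {
      next
    }
    if (out_col != col) tbl[[col]] <- NULL
  }
  tbl
}

#' Estimate a population heart-rate-correction exponent from baseline data
#'
#' Fits `log(value) = subject intercept + alpha * log(rr)` with subject as
#' an absorbed fixed intercept, and tests a sex difference in the exponent
#' through a `sex : log(rr)` interaction. If the interaction is
#' significant at `sex_alpha_level`, sex-specific exponents are reported.
#'
#' @param baseline A data frame of pre-dose rows with columns `subject`,
#'   `sex`, `value` (`> 0`) and `rr_s` (`> 0`).
#' @param sex_alpha_level Significance level for the sex-difference test.
#' @return An object of class `alpha_fit` with `alpha_estimate`,
#'   `standard_error`, `sex_difference_p`, `sex_specific` (logical),
#'   `alpha_by_sex`, `subject_intercepts`, `n`.
#' @export
fit_alpha <- function(baseline, sex_alpha_level = 0.05) {
  need <- c("subject", "value", "rr_s")
  stopifnot(all(need %in% names(baseline)))
  if (any(baseline$value <= 0) || any(baseline$rr_s <= 0)) {
    stop("values and rr_s must be positive for the log-log fit")
  }
  if (length(unique(baseline$subject)) < 2) stop("at least 2 subjects required")
  lrr <- log(baseline$rr_s)
  if (stats::var(lrr) < 1e-12) {
    stop("degenerate RR spread: log(rr) variance below tolerance")
  }
  d <- data.frame(
    y = log(baseline$value),
    lrr = lrr,
    subject = factor(baseline$subject)
  )
  fit <- stats::lm(y ~ 0 + subject + lrr, data = d)
  co <- suppressWarnings(summary(fit))$coefficients
  alpha <- co["lrr", "Estimate"]
  se <- co["lrr", "Std. Error"]
  sex_p <- NA_real_
  alpha_by_sex <- NULL
  if ("sex" %in% names(baseline) && length(unique(baseline$sex)) == 2) {
    d$sex <- factor(baseline$sex)
    fit2 <- stats::lm(y ~ 0 + subject + lrr + sex:lrr, data = d)
    co2 <- suppressWarnings(summary(fit2))$coefficients
    int_row <- grep("^lrr:sex|^sex.*:lrr", rownames(co2), value = TRUE)
    if (length(int_row) == 1) {
      sex_p <- co2[int_row, "Pr(>|t|)"]
      if (is.finite(sex_p) && sex_p < sex_alpha_level) {
        base_lvl <- levels(d$sex)[1]
        a1 <- co2["lrr", "Estimate"]
        a2 <- a1 + co2[int_row, "Estimate"]
        alpha_by_sex <- stats::setNames(c(a1, a2), levels(d$sex))
      }
    }
  }
  structure(
    list(
      alpha_estimate = alpha, standard_error = se,
      sex_difference_p = sex_p,
      sex_specific = !is.null(alpha_by_sex),
      alpha_by_sex = alpha_by_sex,
      subject_intercepts = stats::coef(fit)[grep("^subject", names(stats::coef(fit)))],
      n = nrow(d)
    ),
    class = "alpha_fit"
  )
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat(sprintf("<alpha_fit> alpha = %.4f (SE %.4f), n = %d\n",
              x$alpha_estimate, x$standard_error, x$n))
  if (is.finite(x$sex_difference_p)) {
    cat(sprintf("  sex-difference p = %.3f%s\n", x$sex_difference_p,
                if (x$sex_specific) " (sex-specific exponents reported)" else ""))
  }
  invisible(x)
}
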