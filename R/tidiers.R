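#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn fit_alpha Tidy the exponent estimate (one row per exponent:
#'   a single population row, or one per sex when the sex test is
#'   significant).
#' @param x An `alpha_fit` object.
#' @param ... Unused.
#' @method tidy alpha_fit
#' @export
tidy.alpha_fit <- function(x, ...) {
  if (x$sex_specific) {
    tibble::tibble(
      term = paste0("alpha[", names(x$alpha_by_sex), "]"),
      estimate = unname(x$alpha_by_sex),
      std.error = NA_real_
    )
  } else {
    tibble::tibble(term = "alpha", estimate = x$alpha_estimate,
                   std.error = x$standard_error)
  }
}

#' @describeIn fit_alpha One-row model summary.
#' @method glance alpha_fit
#' @export
glance.alpha_fit <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha_estimate, std.error = x$standard_error,
    sex_difference_p = x$sex_difference_p, sex_specific = x$sex_specific,
    nobs = x$n
  )
}

#' @describeIn conc_response_fit Tidy the fixed effects.
#' @param x A `conc_response` object.
#' @param ... Unused.
#' @method tidy conc_response
#' @export
tidy.conc_response <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "conc"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$se_intercept, x$se_slope)
  )
}

#' @describeIn conc_response_fit One-row model summary with the
#'   random-effect variances.
#' @method glance conc_response
#' @export
glance.conc_response <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, se_slope = x$se_slope,
    intercept = x$intercept, se_intercept = x$se_intercept,
    var_intercept = unname(x$re_variances["intercept"]),
    var_slope = unname(x$re_variances["slope"]),
    cov_intercept_slope = x$re_covariance,
    sigma = x$sigma, n_subjects = x$n_subjects, method = x$method
  )
}

#' @describeIn learn_tree Cross-validation metrics as a one-row tibble.
#' @param x A `gain_tree` object.
#' @param ... Unused.
#' @method glance gain_tree
#' @export
glance.gain_tree <- function(x, ...) {
  tibble::tibble(
    cv_accuracy = x$cv$accuracy, cv_sensitivity = x$cv$sensitivity,
    cv_specificity = x$cv$specificity, n = x$cv$n
  )
}

#' @describeIn roc_auc The ROC curve as a tibble.
#' @param x A `roc_result` object.
#' @param ... Unused.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) {
  x$curve
}

#' @describeIn roc_auc One-row AUC summary.
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, sensitivity = x$sensitivity,
                 specificity = x$specificity, n_pos = x$n_pos,
                 n_neg = x$n_neg)
}
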