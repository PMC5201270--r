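#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbar
#'   geom_errorbarh geom_line geom_abline labs theme_minimal
#' @export
ggplot2::autoplot

#' @describeIn predict_signature Plot the ECG signature: predicted
#'   biomarker change against predicted QTc change with 95% CI bars at
#'   each Cmax fraction.
#' @param object A `signature_points` tibble.
#' @param biomarker_label Axis label for the companion biomarker.
#' @param ... Unused.
#' @method autoplot signature_points
#' @export
autoplot.signature_points <- function(object,
                                      biomarker_label = "biomarker change",
                                      ...) {
  ggplot(object, aes(x = .data$dqtc, y = .data$dbio)) +
    geom_errorbar(aes(ymin = .data$dbio_lo, ymax = .data$dbio_hi),
                  width = 0) +
    geom_errorbarh(aes(xmin = .data$dqtc_lo, xmax = .data$dqtc_hi),
                   height = 0) +
    geom_line() +
    geom_point(size = 2) +
    labs(x = expression(Delta * "QTc (ms)"), y = biomarker_label) +
    theme_minimal()
}

#' @describeIn roc_auc Plot the empirical ROC curve.
#' @param object A `roc_result`.
#' @param ... Unused.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot(object$curve,
         aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    geom_line() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    labs(x = "1 - specificity", y = "sensitivity",
         title = sprintf("AUC = %.3f", object$auc)) +
    theme_minimal()
}

#' @describeIn roc_analysis Dot-and-interval plot of model AUCs.
#' @param object A `roc_table`.
#' @param ... Unused.
#' @method autoplot roc_table
#' @export
autoplot.roc_table <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$model <- stats::reorder(d$model, d$auc)
  ggplot(d, aes(x = .data$auc, y = .data$model)) +
    geom_errorbarh(aes(xmin = .data$auc_lo, xmax = .data$auc_hi),
                   height = 0.15) +
    geom_point(size = 2) +
    labs(x = "ROC AUC (multichannel vs hERG)", y = NULL) +
    theme_minimal()
}
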