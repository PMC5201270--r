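#' Logistic model scores for a one- or two-biomarker classifier
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via `stats::glm`) of the positive class on the chosen feature
#' columns. Complete separation is reported as a warning (capped
#' iterations), not an error.
#'
#' @param data A data frame with a `label` column and feature columns.
#' @param features Character vector of 1 or 2 feature column names (more
#'   allowed with `allow_many = TRUE`).
#' @param positive Positive-class label.
#' @param allow_many Allow more than two features.
#' @return A list of class `logistic_scores`: `scores` (predicted positive
#'   probability per row), `labels`, `model`, `features`.
#' @export
logistic_fit <- function(data, features, positive = "multichannel",
                         allow_many = FALSE) {
  stopifnot(all(features %in% names(data)), "label" %in% names(data))
  if (length(features) > 2 && !allow_many) {
    stop("at most two features (set allow_many = TRUE to override)")
  }
  y <- as.integer(data$label == positive)
  if (length(unique(y)) < 2) stop("both classes must be present")
  d <- data.frame(y = y, data[features])
  form <- stats::as.formula(paste("y ~", paste(features, collapse = " + ")))
  fit <- withCallingHandlers(
    stats::glm(form, data = d, family = stats::binomial(),
               control = stats::glm.control(maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        warning("complete or quasi-complete separation; coefficients capped by iteration limit",
                call. = FALSE)
        invokeRestart("muffleWarning")
      }
    }
  )
  structure(
    list(scores = unname(stats::fitted(fit)), labels = data$label,
         model = fit, features = features, positive = positive),
    class = "logistic_scores"
  )
}

#' ROC area under the curve with best operating point
#'
#' AUC by the Mann-Whitney pair statistic (ties count one half); the best
#' operating point maximizes sensitivity + specificity over the empirical
#' ROC curve.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Class labels.
#' @param positive Positive-class label.
#' @return A list of class `roc_result`: `auc`, `sensitivity`,
#'   `specificity`, `threshold`, `n_pos`, `n_neg`, `curve` (tibble of the
#'   full ROC curve).
#' @export
roc_auc <- function(scores, labels, positive = "multichannel") {
  stopifnot(length(scores) == length(labels))
  y <- labels == positive
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # empirical curve over unique thresholds (predict positive if score >= t)
  th <- sort(unique(scores))
  sens <- vapply(th, function(t) sum(scores[y] >= t) / n_pos, numeric(1))
  spec <- vapply(th, function(t) sum(scores[!y] < t) / n_neg, numeric(1))
  i <- which.max(sens + spec)
  structure(
    list(auc = auc, sensitivity = sens[i], specificity = spec[i],
         threshold = th[i], n_pos = n_pos, n_neg = n_neg,
         curve = tibble::tibble(threshold = th, sensitivity = sens,
                                specificity = spec)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (sens %.2f, spec %.2f at best point); %d pos / %d neg\n",
              x$auc, x$sensitivity, x$specificity, x$n_pos, x$n_neg))
  invisible(x)
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Resamples within each class (stratified), recomputes the AUC and takes
#' the percentile 2.5/97.5 interval. Seeded and deterministic.
#'
#' @inheritParams roc_auc
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return Numeric `c(low, high)`.
#' @export
auc_bootstrap_ci <- function(scores, labels, n_boot = 2000, seed = 1,
                             positive = "multichannel") {
  y <- labels == positive
  if (sum(y) < 2 || sum(!y) < 2) stop("both classes need at least 2 members")
  if (n_boot < 100) warning("fewer than 100 bootstrap replicates")
  ip <- which(y)
  im <- which(!y)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  aucs <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(ip, replace = TRUE), sample(im, replace = TRUE))
    s <- scores[idx]
    yy <- y[idx]
    r <- rank(s, ties.method = "average")
    np <- sum(yy)
    (sum(r[yy]) - np * (np + 1) / 2) / (np * sum(!yy))
  }, numeric(1))
  unname(stats::quantile(aucs, c(0.025, 0.975)))
}

# DeLong placement values: for each positive, the fraction of negatives it
# beats (ties half), and vice versa.
delong_placements <- function(scores, y) {
  sp <- scores[y]
  sn <- scores[!y]
  v10 <- vapply(sp, function(s) mean((s > sn) + 0.5 * (s == sn)), numeric(1))
  v01 <- vapply(sn, function(s) mean((sp > s) + 0.5 * (sp == s)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors computed on the same rows using
#' the DeLong placement-value covariance; two-sided p from the normal
#' reference. Monotone transforms of the scores leave the test invariant.
#'
#' @param scores_a,scores_b Paired score vectors (same rows, same labels).
#' @param labels Class labels.
#' @param positive Positive-class label.
#' @return A list: `auc_a`, `auc_b`, `difference`, `se`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels, positive = "multichannel") {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("scores_a, scores_b and labels must be paired (equal length)")
  }
  y <- labels == positive
  m <- sum(y)
  n <- sum(!y)
  if (m == 0 || n == 0) stop("both classes must be present")
  pa <- delong_placements(scores_a, y)
  pb <- delong_placements(scores_b, y)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  svar <- s10 / m + s01 / n
  L <- c(1, -1)
  v <- drop(t(L) %*% svar %*% L)
  diff <- pa$auc - pb$auc
  if (v <= .Machine$double.eps) {
    z <- 0
    p <- if (abs(diff) < 1e-12) 1 else 0
  } else {
    z <- diff / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, difference = diff,
       se = sqrt(max(v, 0)), z = z, p_value = p)
}

#' ROC comparison table for a set of biomarker models
#'
#' Fits one logistic model per feature set, computes the AUC with a
#' stratified bootstrap CI and the best sensitivity/specificity point —
#' one row per model, sorted by AUC.
#'
#' @param data Feature table with a `label` column.
#' @param feature_sets Named list of character vectors of feature columns.
#' @param n_boot Bootstrap replicates for the CI.
#' @param seed Integer seed for the bootstrap.
#' @param positive Positive-class label.
#' @return A tibble of class `roc_table`; attribute `scores` carries the
#'   per-model score vectors for later DeLong comparisons.
#' @export
roc_analysis <- function(data, feature_sets, n_boot = 2000, seed = 1,
                         positive = "multichannel") {
  stopifnot(length(feature_sets) > 0)
  if (is.null(names(feature_sets))) {
    names(feature_sets) <- vapply(feature_sets, paste, collapse = "+",
                                  character(1))
  }
  scores <- list()
  rows <- purrr::imap(feature_sets, function(fs, nm) {
    lf <- logistic_fit(data, fs, positive = positive)
    rr <- roc_auc(lf$scores, lf$labels, positive = positive)
    ci <- auc_bootstrap_ci(lf$scores, lf$labels, n_boot = n_boot,
                           seed = seed, positive = positive)
    scores[[nm]] <<- lf$scores
    tibble::tibble(
      model = nm, auc = rr$auc, auc_lo = ci[1], auc_hi = ci[2],
      sensitivity = rr$sensitivity, specificity = rr$specificity
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(auc))
  attr(out, "scores") <- scores
  attr(out, "labels") <- data$label
  attr(out, "positive") <- positive
  class(out) <- c("roc_table", class(out))
  out
}
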