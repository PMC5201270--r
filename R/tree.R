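#' The fixed J-Tpeakc/QTc decision rule
#'
#' The published two-threshold rule: a placebo-corrected J-Tpeakc change
#' above `jtpeakc_threshold_ms` indicates predominant or selective hERG
#' potassium channel block; at or below it, a QTc change at or below
#' `qtc_threshold_ms` indicates multichannel (hERG plus inward current)
#' block; otherwise the call is inconclusive.
#'
#' @param jtpeakc_threshold_ms J-Tpeakc threshold, ms.
#' @param qtc_threshold_ms QTc threshold, ms.
#' @return A list of class `tree_rule`.
#' @export
tree_rule <- function(jtpeakc_threshold_ms = 9, qtc_threshold_ms = 29) {
  stopifnot(is.finite(jtpeakc_threshold_ms), is.finite(qtc_threshold_ms))
  structure(
    list(jtpeakc_threshold_ms = jtpeakc_threshold_ms,
         qtc_threshold_ms = qtc_threshold_ms),
    class = "tree_rule"
  )
}

#' Classify placebo-corrected changes with the fixed decision rule
#'
#' The three regions partition the plane exhaustively and disjointly;
#' boundaries are inclusive toward the lower branch
#' (`<=` at both thresholds).
#'
#' @param ddjtpeakc_ms Placebo-corrected J-Tpeakc change(s), ms.
#' @param ddqtc_ms Placebo-corrected QTc change(s), ms.
#' @param rule A [tree_rule()].
#' @return Character vector in `{"hERG", "multichannel", "inconclusive"}`.
#' @export
tree_classify <- function(ddjtpeakc_ms, ddqtc_ms, rule = tree_rule()) {
  stopifnot(length(ddjtpeakc_ms) == length(ddqtc_ms),
            all(is.finite(ddjtpeakc_ms)), all(is.finite(ddqtc_ms)))
  out <- rep("inconclusive", length(ddjtpeakc_ms))
  herg <- ddjtpeakc_ms > rule$jtpeakc_threshold_ms
  multi <- !herg & ddqtc_ms <= rule$qtc_threshold_ms
  out[herg] <- "hERG"
  out[multi] <- "multichannel"
  out
}

# Shannon entropy of a label vector (base 2).
label_entropy <- function(labels) {
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Gain ratio of a binary split at `threshold` on `x`.
gain_ratio <- function(x, labels, threshold) {
  left <- x <= threshold
  n <- length(x)
  nl <- sum(left)
  if (nl == 0 || nl == n) return(0)
  gain <- label_entropy(labels) -
    (nl / n) * label_entropy(labels[left]) -
    ((n - nl) / n) * label_entropy(labels[!left])
  split_info <- -((nl / n) * log2(nl / n) + ((n - nl) / n) * log2((n - nl) / n))
  if (split_info == 0) return(0)
  gain / split_info
}

# Best gain-ratio split over candidate thresholds (midpoints of adjacent
# observed values) for one feature.
best_split_feature <- function(x, labels) {
  xs <- sort(unique(x))
  if (length(xs) < 2) return(NULL)
  mids <- (xs[-1] + xs[-length(xs)]) / 2
  gr <- vapply(mids, function(t) gain_ratio(x, labels, t), numeric(1))
  i <- which.max(gr)
  list(threshold = mids[i], gain_ratio = gr[i])
}

# Leaf label: majority class, demoted to "inconclusive" when purity falls
# below the configured minimum.
leaf_label <- function(labels, min_purity) {
  tab <- table(labels)
  maj <- names(tab)[which.max(tab)]
  if (max(tab) / length(labels) < min_purity) "inconclusive" else maj
}

grow_tree <- function(data, features, label_col, depth, max_depth,
                      min_purity, min_split = 4) {
  labels <- data[[label_col]]
  if (depth >= max_depth || length(unique(labels)) == 1 ||
      nrow(data) < min_split) {
    return(list(kind = "leaf", label = leaf_label(labels, min_purity),
                n = nrow(data)))
  }
  cand <- purrr::compact(stats::setNames(
    lapply(features, function(f) best_split_feature(data[[f]], labels)),
    features
  ))
  if (length(cand) == 0 || max(vapply(cand, `[[`, numeric(1), "gain_ratio")) <= 0) {
    return(list(kind = "leaf", label = leaf_label(labels, min_purity),
                n = nrow(data)))
  }
  f <- names(cand)[which.max(vapply(cand, `[[`, numeric(1), "gain_ratio"))]
  thr <- cand[[f]]$threshold
  left <- data[[f]] <= thr
  list(
    kind = "split", feature = f, threshold = thr,
    gain_ratio = cand[[f]]$gain_ratio, n = nrow(data),
    left = grow_tree(data[left, ], features, label_col, depth + 1,
                     max_depth, min_purity, min_split),
    right = grow_tree(data[!left, ], features, label_col, depth + 1,
                      max_depth, min_purity, min_split)
  )
}

predict_tree_node <- function(node, row) {
  while (node$kind == "split") {
    node <- if (row[[node$feature]] <= node$threshold) node$left else node$right
  }
  node$label
}

#' Learn a two-feature, depth-limited gain-ratio decision tree
#'
#' Greedy binary splits on candidate thresholds at observed-value
#' midpoints maximizing the gain ratio; leaves take the majority label,
#' demoted to "inconclusive" when leaf purity falls below `min_purity`.
#' Performance is estimated with seeded stratified k-fold
#' cross-validation.
#'
#' @param data Feature table with a label column.
#' @param features Feature column names (typically the two change
#'   biomarkers).
#' @param label_col Label column name.
#' @param max_depth Maximum tree depth.
#' @param folds Cross-validation folds.
#' @param seed Integer seed for the fold assignment.
#' @param min_purity Minimum leaf purity for a class call.
#' @param positive Positive-class label for sensitivity/specificity.
#' @return An object of class `gain_tree`: the tree, the equivalent
#'   [tree_rule()] when the learned shape matches the canonical
#'   two-threshold form (else `NULL`), and `cv` metrics.
#' @export
learn_tree <- function(data, features, label_col = "label", max_depth = 2,
                       folds = 10, seed = 1, min_purity = 0.75,
                       positive = "multichannel") {
  labels <- data[[label_col]]
  classes <- unique(labels)
  if (length(classes) < 2) stop("both classes must be present")
  if (min(table(labels)) < folds) {
    stop("each class needs at least `folds` rows for cross-validation")
  }
  tree <- grow_tree(data, features, label_col, 0, max_depth, min_purity)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  fold_id <- integer(nrow(data))
  for (cl in classes) {
    idx <- which(labels == cl)
    fold_id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  preds <- character(nrow(data))
  for (k in seq_len(folds)) {
    hold <- fold_id == k
    tr <- grow_tree(data[!hold, ], features, label_col, 0, max_depth,
                    min_purity)
    preds[hold] <- vapply(which(hold), function(i) {
      predict_tree_node(tr, data[i, ])
    }, character(1))
  }
  cv <- evaluate_classifier(preds, labels, positive = positive, n_boot = 0)
  rule <- NULL
  if (tree$kind == "split" && length(features) == 2) {
    other <- setdiff(features, tree$feature)
    sub <- if (tree$left$kind == "split") tree$left else
      if (tree$right$kind == "split") tree$right else NULL
    if (!is.null(sub) && sub$feature == other) {
      thr <- stats::setNames(c(tree$threshold, sub$threshold),
                             c(tree$feature, sub$feature))
      rule <- thr
    }
  }
  structure(list(tree = tree, thresholds = rule, cv = cv,
                 features = features, positive = positive),
            class = "gain_tree")
}

#' @export
predict.gain_tree <- function(object, newdata, ...) {
  vapply(seq_len(nrow(newdata)), function(i) {
    predict_tree_node(object$tree, newdata[i, ])
  }, character(1))
}

#' @export
print.gain_tree <- function(x, ...) {
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$kind == "leaf") {
      cat(sprintf("%s-> %s (n=%d)\n", pad, node$label, node$n))
    } else {
      cat(sprintf("%s%s <= %.3g ? (n=%d)\n", pad, node$feature,
                  node$threshold, node$n))
      show(node$left, indent + 1)
      show(node$right, indent + 1)
    }
  }
  cat("<gain_tree>\n")
  show(x$tree, 1)
  cat(sprintf("  CV accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              x$cv$accuracy, x$cv$sensitivity, x$cv$specificity))
  invisible(x)
}

#' Confusion-matrix metrics with a stratified bootstrap CI
#'
#' Accuracy, sensitivity and specificity of class calls against reference
#' labels. "inconclusive" calls count as errors by default
#' (`inconclusive = "error"`); with `inconclusive = "exclude"` the
#' metrics are recomputed on conclusive rows only.
#'
#' @param predictions Character class calls (may include "inconclusive").
#' @param labels Reference labels.
#' @param positive Positive-class label.
#' @param inconclusive Handling of inconclusive calls.
#' @param n_boot Bootstrap replicates for the accuracy CI (0 to skip).
#' @param seed Integer seed.
#' @return A list: `accuracy`, `sensitivity`, `specificity`, `n`,
#'   `accuracy_ci` (when bootstrapped).
#' @export
evaluate_classifier <- function(predictions, labels,
                                positive = "multichannel",
                                inconclusive = c("error", "exclude"),
                                n_boot = 2000, seed = 1) {
  stopifnot(length(predictions) == length(labels))
  inconclusive <- match.arg(inconclusive)
  if (inconclusive == "exclude") {
    keep <- predictions != "inconclusive"
    predictions <- predictions[keep]
    labels <- labels[keep]
    if (length(labels) == 0) stop("no conclusive predictions left")
  }
  metrics <- function(pred, lab) {
    pos <- lab == positive
    c(accuracy = mean(pred == lab),
      sensitivity = if (any(pos)) mean(pred[pos] == positive) else NA_real_,
      specificity = if (any(!pos)) mean(pred[!pos] == lab[!pos]) else NA_real_)
  }
  m <- metrics(predictions, labels)
  out <- list(accuracy = m[["accuracy"]], sensitivity = m[["sensitivity"]],
              specificity = m[["specificity"]], n = length(labels))
  if (n_boot > 0) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    ip <- which(labels == positive)
    im <- which(labels != positive)
    accs <- vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(ip, replace = TRUE), sample(im, replace = TRUE))
      mean(predictions[idx] == labels[idx])
    }, numeric(1))
    out$accuracy_ci <- unname(stats::quantile(accs, c(0.025, 0.975)))
  }
  out
}
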