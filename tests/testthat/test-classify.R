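test_that("logistic scores separate, stay null, and match a likelihood grid search", {
  toy <- data.frame(
    x = c(-3, -2.5, -2, -1.5, -1, 1, 1.5, 2, 2.5, 3),
    label = rep(c("hERG", "multichannel"), each = 5)
  )
  suppressWarnings({
    lf <- logistic_fit(toy, "x")
  })
  expect_true(all((lf$scores > 0.5) == (toy$label == "multichannel")))

  withr::with_seed(8, {
    null <- data.frame(x = stats::rnorm(400),
                       label = rep(c("hERG", "multichannel"), 200))
    lf0 <- logistic_fit(null, "x")
    expect_lt(abs(stats::coef(lf0$model)[["x"]]), 0.25)
    expect_lt(max(abs(lf0$scores - 0.5)), 0.15)
  })

  # brute-force likelihood grid search agrees with the IRLS fit
  small <- data.frame(x = c(-1.2, -0.4, 0.1, 0.7, -0.6, 0.3, 1.1, 1.6),
                      label = c("hERG", "hERG", "hERG", "hERG",
                                "multichannel", "multichannel",
                                "multichannel", "multichannel"))
  lf2 <- logistic_fit(small, "x")
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * small$x
    y <- as.integer(small$label == "multichannel")
    sum(y * eta - log1p(exp(eta)))
  }
  ctr <- c(0, 0)
  span <- 10
  for (step in 1:8) {
    b0s <- seq(ctr[1] - span, ctr[1] + span, length.out = 21)
    b1s <- seq(ctr[2] - span, ctr[2] + span, length.out = 21)
    ll <- outer(b0s, b1s, Vectorize(loglik))
    i <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    ctr <- c(b0s[i[1]], b1s[i[2]])
    span <- span / 5
  }
  expect_lt(max(abs(ctr - stats::coef(lf2$model))), 1e-3)

  expect_error(logistic_fit(toy, c("x", "x", "x")), "two features")
  expect_error(logistic_fit(dplyr::mutate(toy, label = "hERG"), "x"),
               "both classes")
})

test_that("the AUC equals brute-force pair enumeration, with tie handling", {
  scores <- c(0.1, 0.4, 0.4, 0.8, 0.9, 0.2)
  labels <- c("hERG", "hERG", "multichannel", "multichannel",
              "multichannel", "hERG")
  r <- roc_auc(scores, labels)
  expect_equal(r$auc, brute_auc(scores, labels), tolerance = 1e-12)

  # perfect separation and label-flip antisymmetry
  sep <- roc_auc(c(1, 2, 3, 7, 8, 9), rep(c("hERG", "multichannel"), each = 3))
  expect_equal(sep$auc, 1)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  flip <- roc_auc(scores, ifelse(labels == "hERG", "multichannel", "hERG"))
  expect_equal(flip$auc, 1 - r$auc, tolerance = 1e-12)

  # random instances against the oracle
  withr::with_seed(99, {
    for (i in 1:200) {
      n <- sample(6:50, 1)
      s <- round(stats::rnorm(n), sample(0:2, 1))
      l <- sample(c("hERG", "multichannel"), n, replace = TRUE)
      if (length(unique(l)) < 2) next
      expect_equal(roc_auc(s, l)$auc, brute_auc(s, l), tolerance = 1e-12)
    }
  })

  # invariance under strictly increasing transforms
  expect_equal(roc_auc(exp(scores), labels)$auc, r$auc, tolerance = 1e-12)
  expect_error(roc_auc(scores, rep("hERG", 6)), "both classes")
})

test_that("the stratified bootstrap CI is seeded and degenerate-safe", {
  labels <- rep(c("hERG", "multichannel"), each = 10)
  ci1 <- auc_bootstrap_ci(rep(1, 20), labels, n_boot = 200, seed = 4)
  expect_equal(ci1, c(0.5, 0.5))
  withr::with_seed(1, s <- stats::rnorm(20) + (labels == "multichannel"))
  ci2 <- auc_bootstrap_ci(s, labels, n_boot = 500, seed = 9)
  ci3 <- auc_bootstrap_ci(s, labels, n_boot = 500, seed = 9)
  expect_identical(ci2, ci3)
  expect_true(ci2[1] <= roc_auc(s, labels)$auc, ci2[2] >= roc_auc(s, labels)$auc)
  expect_warning(auc_bootstrap_ci(s, labels, n_boot = 50, seed = 1), "100")
})

test_that("the DeLong test is null on identical or rank-equivalent scores", {
  labels <- rep(c("hERG", "multichannel"), each = 15)
  withr::with_seed(2, s <- stats::rnorm(30) + (labels == "multichannel"))
  same <- delong_test(s, s, labels)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)
  mono <- delong_test(s, 1 / (1 + exp(-3 * s)) + 2, labels)
  expect_equal(mono$difference, 0)
  expect_equal(mono$p_value, 1)
  expect_error(delong_test(s[1:10], s, labels), "paired")
  # cross-check against the reference implementation
  if (requireNamespace("pROC", quietly = TRUE)) {
    withr::with_seed(5, s2 <- s + stats::rnorm(30, 0, 0.8))
    ours <- delong_test(s, s2, labels)
    ref <- pROC::roc.test(
      pROC::roc(labels, s, levels = c("hERG", "multichannel"),
                direction = "<", quiet = TRUE),
      pROC::roc(labels, s2, levels = c("hERG", "multichannel"),
                direction = "<", quiet = TRUE),
      method = "delong"
    )
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
    expect_equal(ours$auc_a, as.numeric(pROC::auc(pROC::roc(
      labels, s, levels = c("hERG", "multichannel"), direction = "<",
      quiet = TRUE))), tolerance = 1e-12)
  }
})

test_that("the fixed decision rule reproduces the published calls and partitions the plane", {
  expect_equal(tree_classify(29.1, 45.2), "hERG")
  expect_equal(tree_classify(1.1, 17.3), "multichannel")
  expect_equal(tree_classify(4.1, 17.9), "multichannel")
  # boundary convention: <= goes to the lower branch
  expect_equal(tree_classify(9.0, 29.0), "multichannel")
  expect_equal(tree_classify(5.0, 35.0), "inconclusive")
  expect_equal(tree_classify(9.000001, -100), "hERG")

  withr::with_seed(3, {
    x <- stats::rnorm(500, 5, 20)
    y <- stats::rnorm(500, 20, 30)
    calls <- tree_classify(x, y)
    expect_true(all(calls %in% c("hERG", "multichannel", "inconclusive")))
    # the three regions are disjoint and exhaustive
    expect_equal(sum(calls == "hERG"), sum(x > 9))
    expect_equal(sum(calls == "multichannel"), sum(x <= 9 & y <= 29))
    expect_equal(sum(calls == "inconclusive"), sum(x <= 9 & y > 29))
  })
  expect_error(tree_classify(NA, 1), "finite")
})

test_that("the gain-ratio learner recovers separations and matches hand entropy", {
  withr::with_seed(10, {
    d <- data.frame(
      x = c(stats::rnorm(30, -3), stats::rnorm(30, 3)),
      z = stats::rnorm(60),
      label = rep(c("hERG", "multichannel"), each = 30)
    )
    fit <- learn_tree(d, c("x", "z"), folds = 10, seed = 2)
    expect_equal(fit$tree$feature, "x")
    expect_gt(fit$tree$threshold, -2)
    expect_lt(fit$tree$threshold, 2)
    expect_gt(fit$cv$accuracy, 0.9)

    # labels independent of features: CV accuracy near the prevalence
    d0 <- data.frame(x = stats::rnorm(80), z = stats::rnorm(80),
                     label = sample(rep(c("hERG", "multichannel"), c(48, 32))))
    fit0 <- learn_tree(d0, c("x", "z"), folds = 10, seed = 2,
                       min_purity = 0.5)
    expect_lt(abs(fit0$cv$accuracy - 0.6), 0.2)
  })

  # 8-row toy: gain ratio at a fixed split vs hand-computed entropies
  xs <- c(1, 2, 3, 4, 5, 6, 7, 8)
  lab <- c("a", "a", "a", "b", "a", "b", "b", "b")
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  # split at 4.5: left = a a a b a? no: x <= 4.5 -> labels a a a b
  gain_hand <- h(c(0.5, 0.5)) - 0.5 * h(c(3 / 4, 1 / 4)) - 0.5 * h(c(1 / 4, 3 / 4))
  split_info <- h(c(0.5, 0.5))
  expect_equal(repolsig:::gain_ratio(xs, lab, 4.5), gain_hand / split_info,
               tolerance = 1e-12)

  expect_error(learn_tree(data.frame(x = 1:20, z = 1:20,
                                     label = rep("a", 20)),
                          c("x", "z")), "both classes")
})

test_that("classifier evaluation counts inconclusive calls per the convention", {
  labels <- rep(c("multichannel", "hERG"), each = 20)
  expect_equal(evaluate_classifier(labels, labels, n_boot = 0)$accuracy, 1)
  allinc <- rep("inconclusive", 40)
  expect_equal(evaluate_classifier(allinc, labels, n_boot = 0)$accuracy, 0)

  # 2x2 toy: 15/5 and 5/15
  pred <- c(rep("multichannel", 15), rep("hERG", 5),
            rep("multichannel", 5), rep("hERG", 15))
  ev <- evaluate_classifier(pred, labels, n_boot = 0)
  expect_equal(ev$accuracy, 0.75)
  expect_equal(ev$sensitivity, 0.75)
  expect_equal(ev$specificity, 0.75)

  # excluding inconclusive rows recomputes on the conclusive subset
  pred2 <- pred
  pred2[1:10] <- "inconclusive"
  ev2 <- evaluate_classifier(pred2, labels, inconclusive = "exclude",
                             n_boot = 0)
  expect_equal(ev2$n, 30)
  ci <- evaluate_classifier(pred, labels, n_boot = 300, seed = 3)$accuracy_ci
  expect_true(ci[1] <= 0.75 && ci[2] >= 0.75)
})
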