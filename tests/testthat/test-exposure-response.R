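test_that("changes from baseline use the period-specific pre-dose value", {
  tbl <- tidyr::expand_grid(
    subject = c("S01", "S02"), arm = c("placebo", "drug"),
    timepoint_h = c(0, 13), replicate = 1:3
  )
  tbl$period <- match(tbl$arm, c("placebo", "drug"))
  tbl$sequence <- "q"
  tbl$rr_s <- 1
  # replicate-level values: median over replicates is the middle one
  tbl$qtc_ms <- 400 + ifelse(tbl$timepoint_h == 13 & tbl$arm == "drug",
                             c(44, 45, 46), c(-1, 0, 1))
  ch <- changes_from_baseline(tbl)
  expect_equal(nrow(ch), 4)  # 2 subjects x 2 arms x 1 post time-point
  expect_equal(ch$change[ch$arm == "drug"], c(45, 45))
  expect_equal(ch$change[ch$arm == "placebo"], c(0, 0))

  # missing baseline rows are an error
  expect_error(changes_from_baseline(tbl[tbl$timepoint_h != 0, ]),
               "baseline")
})

test_that("delta_delta equals the cell-means contrast on balanced designs", {
  ch <- balanced_changes(effect = 45.2)
  dd <- delta_delta(ch)
  hit <- dd[dd$timepoint_h == 13, ]
  expect_equal(hit$estimate, 45.2, tolerance = 1e-9)
  expect_equal(dd$estimate[dd$timepoint_h == 5], 0, tolerance = 1e-9)

  # null case: active arm is placebo relabeled
  ch0 <- balanced_changes(effect = 0)
  dd0 <- delta_delta(ch0)
  expect_true(all(abs(dd0$estimate) < 1e-9))
  expect_true(all(dd0$ci_low <= 0 & dd0$ci_high >= 0))

  expect_error(delta_delta(dplyr::filter(ch, arm != "placebo")), "placebo")
})

test_that("delta_delta with noise stays near the injected effect", {
  withr::with_seed(7, {
    ch <- balanced_changes(n_subjects = 12, effect = 45.2)
    ch$change <- ch$change + stats::rnorm(nrow(ch), 0, 5)
    dd <- delta_delta(ch)
    hit <- dd[dd$timepoint_h == 13, ]
    expect_lt(abs(hit$estimate - 45.2), 3 * hit$se)
    expect_lt(hit$ci_low, hit$estimate)
    expect_gt(hit$ci_high, hit$estimate)
  })
})

test_that("concentration-response fits recover slopes and reject degenerate input", {
  conc <- rep(c(0, 0.5, 1, 1.5, 2), times = 6)
  subj <- rep(sprintf("S%02d", 1:6), each = 5)
  d <- data.frame(subject = subj, conc = conc, change = 3 + 10 * conc)
  fit <- conc_response_fit(d)
  expect_equal(fit$slope, 10, tolerance = 1e-6)
  expect_equal(fit$intercept, 3, tolerance = 1e-6)
  expect_lt(max(fit$re_variances, na.rm = TRUE), 1e-4)

  # unit rescaling of concentration inverts the slope by the same factor
  d2 <- d
  d2$conc <- d$conc * 1000
  fit2 <- conc_response_fit(d2)
  expect_equal(fit2$slope, fit$slope / 1000, tolerance = 1e-9)

  expect_error(conc_response_fit(dplyr::mutate(d, conc = 1)), "identical")
  expect_error(conc_response_fit(d[1:10, ]), "5 subjects")

  # heterogeneous slopes: population estimate within 2 SE of the mean
  withr::with_seed(21, {
    ok <- replicate(40, {
      slopes <- stats::rnorm(10, 10, 2)
      d3 <- data.frame(
        subject = rep(sprintf("S%02d", 1:10), each = 5),
        conc = rep(c(0, 0.5, 1, 1.5, 2), times = 10)
      )
      d3$change <- slopes[as.integer(factor(d3$subject))] * d3$conc +
        stats::rnorm(nrow(d3), 0, 1)
      f <- conc_response_fit(d3)
      abs(f$slope - 10) < 2.5 * sqrt(f$se_slope^2 + 4 / 10)
    })
    expect_gte(mean(ok), 0.9)
  })
})

test_that("signature predictions are linear in the Cmax fraction", {
  m <- list(intercept = 0, slope = 10, vcov_fixed = diag(c(0.5, 0.8)))
  class(m) <- "conc_response"
  mq <- list(intercept = 0, slope = 20, vcov_fixed = diag(c(0.5, 0.8)))
  class(mq) <- "conc_response"
  sig <- predict_signature(mq, m, cmax = 1)
  expect_equal(sig$dbio, c(2.5, 5, 7.5, 10))
  expect_equal(sig$dqtc, c(5, 10, 15, 20))
  expect_true(all(diff(sig$dbio_hi - sig$dbio_lo) > 0))  # CIs widen with dose

  flat <- predict_signature(mq, within_flat <- {
    z <- m
    z$slope <- 0
    z
  }, cmax = 1)
  expect_true(all(flat$dbio == m$intercept))
  expect_error(predict_signature(mq, m, cmax = 0), "positive")
})

test_that("the mitigation paired t-test matches the textbook formula", {
  model <- list(intercept = 0, slope = 1)
  class(model) <- "conc_response"
  obs <- data.frame(subject = c("a", "b", "c", "d"), dd = c(10, 12, 9, 14))
  conc <- data.frame(subject = c("a", "b", "c", "d"), conc = c(11, 11, 11, 11))
  res <- mitigation_test(obs, model, conc)
  dif <- obs$dd - 11
  t_hand <- mean(dif) / (stats::sd(dif) / sqrt(4))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 3)
  expect_equal(res$t, t_hand, tolerance = 1e-9)
  expect_equal(res$p_value, p_hand, tolerance = 1e-9)

  # observed == predicted: no difference, p = 1
  obs0 <- data.frame(subject = obs$subject, dd = 11)
  res0 <- mitigation_test(obs0, model, conc)
  expect_equal(res0$mean_difference, 0)
  expect_equal(res0$p_value, 1)

  # a -28 ms shift across 21 subjects with small noise is overwhelming
  withr::with_seed(3, {
    obs2 <- data.frame(subject = sprintf("S%02d", 1:21),
                       dd = 11 - 28 + stats::rnorm(21, 0, 6))
    conc2 <- data.frame(subject = sprintf("S%02d", 1:21), conc = 11)
    expect_lt(mitigation_test(obs2, model, conc2)$p_value, 0.001)
  })

  expect_error(mitigation_test(obs[1:2, ], model, conc[1:2, ]), "3 paired")
})

test_that("Cohen's d follows the definition and the label conventions", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3), paired = TRUE),
               list(cohens_d = 0, label = "negligible"))
  withr::with_seed(5, {
    x <- stats::rnorm(4000, 1, 1)
    y <- stats::rnorm(4000, 0, 1)
    d <- cohens_d(x, y)
    expect_lt(abs(d$cohens_d - 1), 0.08)
    expect_equal(d$label, "large")
  })
  # exact boundary values: label switches at the printed bound
  # (paired diffs with mean d and SD 1 give Cohen's d = d exactly)
  d_exact <- function(dval) {
    x <- c(0, 0, 0)
    y <- x - (dval + c(-1, 0, 1))
    cohens_d(x, y, paired = TRUE)
  }
  expect_equal(d_exact(0.5)$cohens_d, 0.5, tolerance = 1e-12)
  expect_equal(d_exact(0.5)$label, "medium")
  expect_equal(d_exact(0.9)$label, "large")
  expect_equal(d_exact(0.25)$label, "small")
  expect_equal(d_exact(0.1)$label, "negligible")
  expect_error(cohens_d(c(1, 1), c(2, 2)), "zero")
})
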