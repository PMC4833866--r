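test_that("confusion_at_cutoff applies the SENS/SPEC formulas", {
  pairs <- tibble::tibble(rate_fold = c(5, 4, 1), score = c(2, 0.5, 0.5))
  ev <- confusion_at_cutoff(pairs, cutoff = 1)
  expect_equal(ev$tp, 1L); expect_equal(ev$fn, 1L)
  expect_equal(ev$tn, 1L); expect_equal(ev$fp, 0L)
  expect_equal(ev$sens, 0.5)
  expect_equal(ev$spec, 1.0)
  expect_equal(ev$cost, 2 * 0.5 + 1 * 1.0)
  # cutoff below every score: everything called positive
  low <- confusion_at_cutoff(pairs, cutoff = 0)
  expect_equal(low$sens, 1)
  expect_equal(low$spec, 0)
  # degenerate classes warn and go NA
  expect_warning(
    one_class <- confusion_at_cutoff(
      tibble::tibble(rate_fold = c(5, 6), score = c(1, 2)), 1),
    "specificity undefined")
  expect_true(is.na(one_class$spec))
  expect_error(confusion_at_cutoff(pairs[0, ], 1), "non-empty")
  expect_error(
    confusion_at_cutoff(tibble::tibble(rate_fold = -1, score = 1), 1),
    "rate_fold")
})

test_that("confusion counts match the brute-force oracle on random tables", {
  set.seed(20)
  for (i in 1:25) {
    n <- sample(10:500, 1)
    pairs <- tibble::tibble(
      rate_fold = stats::rlnorm(n, log(2), 1),
      score = round(stats::runif(n, 0, 5) * 3) / 3
    )
    cutoff <- stats::runif(1, 0, 5)
    ev <- confusion_at_cutoff(pairs, cutoff)
    oracle <- oracle_confusion(pairs$rate_fold, pairs$score, cutoff)
    expect_identical(c(tp = ev$tp, fn = ev$fn, tn = ev$tn, fp = ev$fp), oracle)
    expect_equal(ev$tp + ev$fn + ev$tn + ev$fp, n)
  }
})

test_that("cost is bounded by w1 + w2 with equality only at perfect separation", {
  set.seed(21)
  pairs <- tibble::tibble(rate_fold = stats::rlnorm(100, log(2), 1),
                          score = stats::runif(100, 0, 5))
  for (cutoff in seq(0, 5, by = 0.5)) {
    suppressWarnings(ev <- confusion_at_cutoff(pairs, cutoff, w1 = 2, w2 = 1))
    expect_lte(ev$cost, 3 + 1e-12)
    if (isTRUE(all.equal(ev$cost, 3))) {
      expect_equal(ev$fn + ev$fp, 0L)
    }
  }
  separable <- tibble::tibble(rate_fold = c(10, 10, 1, 1),
                              score = c(3, 4, 1, 0))
  ev <- confusion_at_cutoff(separable, 2, w1 = 2, w2 = 1)
  expect_equal(ev$cost, 3)
})

test_that("optimal_cutoff separates separable data and breaks ties low", {
  separable <- tibble::tibble(
    rate_fold = c(10, 8, 6, 1, 1.5, 0.5),
    score = c(2.0, 2.5, 3.0, 1.0, 0.5, 1.0)
  )
  fit <- optimal_cutoff(separable)
  expect_gt(fit$cutoff, 1)
  expect_lt(fit$cutoff, 2)
  expect_equal(fit$evaluation$sens, 1)
  expect_equal(fit$evaluation$spec, 1)
  expect_equal(fit$auc, 1)
  # two candidates attain the same cost; the lower one is returned
  tied <- tibble::tibble(rate_fold = c(5, 5, 1, 1), score = c(1, 3, 0, 2))
  fit_tied <- optimal_cutoff(tied, w1 = 1, w2 = 1)
  grid <- tidy(fit_tied)
  best_cost <- max(grid$cost)
  expect_equal(fit_tied$cutoff, min(grid$cutoff[grid$cost == best_cost]))
  expect_error(optimal_cutoff(tibble::tibble(rate_fold = c(5, 6),
                                             score = c(1, 2))),
               "positive and one negative")
})

test_that("glance and tidy expose the cutoff fit", {
  pairs <- tibble::tibble(rate_fold = c(10, 8, 1, 1.2),
                          score = c(3.0, 2.5, 1.0, 0.8))
  fit <- optimal_cutoff(pairs)
  g <- glance(fit)
  expect_equal(g$cutoff, fit$cutoff)
  expect_true(all(c("sens", "spec", "cost", "auc", "n") %in% names(g)))
  expect_equal(nrow(tidy(fit)), length(unique(pairs$score)) + 1)
})

test_that("roc_curve has the required endpoints and monotone shape", {
  pairs <- tibble::tibble(rate_fold = c(10, 8, 6, 1, 1.5, 0.5),
                          score = c(2.0, 2.5, 3.0, 1.0, 0.5, 1.0))
  roc <- roc_curve(pairs)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
  # separable data pass through the perfect corner
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
})

test_that("AUC is ~0.5 when scores are independent of class and grows with effect", {
  set.seed(22)
  null_auc <- replicate(400, {
    pairs <- tibble::tibble(
      rate_fold = c(stats::rlnorm(20, log(6), 0.3), stats::rlnorm(20, 0, 0.3)),
      score = stats::runif(40, 0, 5)
    )
    optimal_cutoff(pairs)$auc
  })
  expect_lt(abs(mean(null_auc) - 0.5), 0.05)
  # paired simulation: stronger planted effects give larger AUC
  wins <- replicate(40, {
    base <- stats::runif(30, 0.5, 1.5)
    fold <- c(stats::rlnorm(15, log(6), 0.3), stats::rlnorm(15, 0, 0.3))
    weak <- tibble::tibble(rate_fold = fold,
                           score = base + 0.5 * (fold >= 3) +
                             stats::rnorm(30, 0, 0.4))
    strong <- tibble::tibble(rate_fold = fold,
                             score = base + 2.0 * (fold >= 3) +
                               stats::rnorm(30, 0, 0.4))
    strong$score <- pmin(pmax(strong$score, 0), 5)
    weak$score <- pmin(pmax(weak$score, 0), 5)
    optimal_cutoff(strong)$auc > optimal_cutoff(weak)$auc
  })
  expect_gt(stats::binom.test(sum(wins), length(wins),
                              alternative = "greater")$estimate, 0.5)
  expect_lt(stats::binom.test(sum(wins), length(wins), p = 0.5,
                              alternative = "greater")$p.value, 0.01)
})

test_that("ks_discrete_test handles identical, disjoint and noisy samples", {
  a <- rep(0:3, times = c(5, 10, 4, 1))
  same <- ks_discrete_test(a, a, n_mc = 499, seed = 1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  lo <- rep(1, 200); hi <- rep(4, 200)
  disjoint <- ks_discrete_test(lo, hi, n_mc = 499, seed = 2)
  expect_equal(disjoint$statistic, 1)
  expect_equal(disjoint$p.value, 1 / 500)
  expect_error(ks_discrete_test(a, a, n_mc = 0), "n_mc")
  expect_error(ks_discrete_test(numeric(0), a), "non-empty")
  shifted <- ks_discrete_test(sample(0:2, 80, TRUE), sample(2:4, 80, TRUE),
                              n_mc = 499, seed = 3)
  expect_lt(shifted$p.value, 0.01)
  td <- tidy(shifted)
  expect_equal(td$statistic, shifted$statistic)
})

test_that("ks p-values are reproducible under a fixed seed", {
  a <- sample(0:5, 50, TRUE); b <- sample(0:5, 50, TRUE)
  r1 <- ks_discrete_test(a, b, n_mc = 199, seed = 42)
  r2 <- ks_discrete_test(a, b, n_mc = 199, seed = 42)
  expect_identical(r1$p.value, r2$p.value)
})
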