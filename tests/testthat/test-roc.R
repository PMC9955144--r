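test_that("ROC curve contains the degenerate endpoints and perfect separation", {
  curve <- roc_curve(c(1, 2, 3), c(0, 0, 1))
  expect_true(any(curve$sensitivity == 0 & curve$specificity == 1))
  expect_true(any(curve$sensitivity == 1 & curve$specificity == 0))
  expect_true(any(curve$sensitivity == 1 & curve$specificity == 1))
  expect_true(all(diff(curve$sensitivity) >= 0))
})

test_that("an all-tied score collapses the curve onto the chance diagonal", {
  curve <- roc_curve(rep(2, 6), c(1, 0, 1, 0, 0, 1))
  expect_true(all(abs(curve$sensitivity - (1 - curve$specificity)) < 1e-12))
  expect_equal(auc_trapezoid(curve), 0.5)
  expect_equal(auc_rank(rep(2, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
})

test_that("single-class labels are rejected", {
  expect_error(roc_curve(1:3, c(1, 1, 1)), class = "avs_degenerate_labels")
  expect_error(auc_rank(1:3, c(0, 0, 0)), class = "avs_degenerate_labels")
})

test_that("curve points match brute-force counting in both directions", {
  set.seed(47)
  for (i in 1:30) {
    n <- sample(5:20, 1)
    scores <- round(rnorm(n), sample(0:1, 1)) # rounding induces ties
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    for (direction in c("higher_is_positive", "lower_is_positive")) {
      curve <- roc_curve(scores, labels, direction)
      for (j in which(is.finite(curve$threshold))) {
        bf <- brute_sens_spec(scores, labels, curve$threshold[j], direction)
        expect_equal(curve$sensitivity[j], unname(bf["sensitivity"]))
        expect_equal(curve$specificity[j], unname(bf["specificity"]))
      }
      # arbitrary cutoffs, including between observed scores
      for (t in c(min(scores) - 1, max(scores) + 1, sort(scores)[2] + 0.01)) {
        expect_equal(sens_spec_at(curve, t),
                     brute_sens_spec(scores, labels, t, direction))
      }
    }
  }
})

test_that("rank AUC equals exhaustive pair enumeration and the trapezoid area", {
  expect_equal(auc_rank(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  set.seed(48)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    scores <- sample(1:5, n, replace = TRUE)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    for (direction in c("higher_is_positive", "lower_is_positive")) {
      a <- auc_rank(scores, labels, direction)
      expect_equal(a, brute_auc(scores, labels, direction))
      expect_equal(a, auc_trapezoid(roc_curve(scores, labels, direction)))
    }
  }
})

test_that("AUC flips under direction reversal and is 0.5 for independent labels", {
  set.seed(49)
  scores <- rnorm(2000); labels <- runif(2000) > 0.5
  a <- auc_rank(scores, labels)
  expect_equal(a, 0.5, tolerance = 0.05)
  expect_equal(auc_rank(scores, labels, "lower_is_positive"), 1 - a)
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(50)
  scores <- c(rnorm(40, 1), rnorm(60)); labels <- rep(c(1, 0), c(40, 60))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                        direction = "<", quiet = TRUE)))
  expect_equal(auc_rank(scores, labels), ref, tolerance = 1e-12)
})

test_that("LR-maximizing threshold follows the formula and exclusion rule", {
  curve <- fake_roc(threshold = c(3, 1, 2), sensitivity = c(0, 0.95, 0.5),
                    specificity = c(1, 0.83, 0.9))
  best <- best_threshold_by_lr(curve)
  expect_equal(best$lr_positive, 0.95 / 0.17, tolerance = 1e-9)
  expect_equal(best$threshold, 1)

  # perfect-specificity point with positive sensitivity is excluded
  curve2 <- fake_roc(threshold = c(3, 2), sensitivity = c(0.4, 0.9),
                     specificity = c(1, 0.5))
  expect_equal(best_threshold_by_lr(curve2)$threshold, 2)

  curve3 <- fake_roc(threshold = c(3), sensitivity = c(0.4), specificity = c(1))
  expect_error(best_threshold_by_lr(curve3), class = "avs_no_finite_lr")
})

test_that("LR choice equals a brute-force scan and survives monotone transforms", {
  set.seed(51)
  for (i in 1:25) {
    n <- sample(10:30, 1)
    scores <- round(rnorm(n), 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.4)
    curve <- roc_curve(scores, labels)
    best <- best_threshold_by_lr(curve)
    ok <- curve$specificity < 1 & curve$sensitivity > 0
    expect_equal(best$lr_positive, max(curve$lr_positive[ok]))

    # strictly increasing transform: same operating point, mapped threshold
    curve_t <- roc_curve(exp(scores), labels)
    best_t <- best_threshold_by_lr(curve_t)
    expect_equal(best_t$sensitivity, best$sensitivity)
    expect_equal(best_t$specificity, best$specificity)
    expect_equal(best_t$threshold, exp(best$threshold))
  }
})

test_that("binormal lognormal AUC matches Monte-Carlo rank AUC", {
  p <- lognormal_from_moments(1, 1)
  expect_equal(binormal_auc_lognormal(p, p), 0.5)
  hi <- list(mu = 50, sigma = 1)
  expect_equal(binormal_auc_lognormal(hi, p), 1, tolerance = 1e-9)
  expect_error(binormal_auc_lognormal(list(mu = 0, sigma = 0), p),
               class = "avs_invalid_parameter")

  set.seed(52)
  for (i in 1:3) {
    pp <- list(mu = runif(1, -1, 1), sigma = runif(1, 0.3, 1))
    pn <- list(mu = runif(1, -1, 1), sigma = runif(1, 0.3, 1))
    n <- 20000
    scores <- c(rlnorm(n, pp$mu, pp$sigma), rlnorm(n, pn$mu, pn$sigma))
    labels <- rep(c(TRUE, FALSE), each = n)
    emp <- auc_rank(scores, labels)
    theo <- binormal_auc_lognormal(pp, pn)
    se <- sqrt(theo * (1 - theo) * (1 / n + 1 / n)) # generous SE bound
    expect_lt(abs(emp - theo), max(3 * se, 0.01))
  }
})

test_that("rank-sum test: exact enumeration and degenerate inputs", {
  res <- rank_sum_test(1:4, 5:8)
  expect_identical(res$method_used, "exact")
  expect_equal(res$p_value, 2 / 70)
  expect_equal(unname(res$statistic), 0)

  same <- rank_sum_test(c(3), c(3))
  expect_equal(same$p_value, 1)
  expect_error(rank_sum_test(numeric(0), 1:3), class = "avs_invalid_input")
})

test_that("exact rank-sum p agrees with the reference implementation", {
  set.seed(53)
  for (i in 1:15) {
    a <- rnorm(sample(3:5, 1)); b <- rnorm(sample(3:5, 1)) # no ties
    ref <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(rank_sum_test(a, b, method = "exact")$p_value, ref,
                 tolerance = 1e-12)
  }
})

test_that("moderated normal approximation tracks the exact p-value", {
  set.seed(54)
  dmax <- 0
  for (i in 1:100) {
    na <- sample(5:7, 1)
    a <- rnorm(na); b <- rnorm(12 - na)
    pe <- rank_sum_test(a, b, method = "exact")$p_value
    pn <- rank_sum_test(a, b, method = "normal")$p_value
    dmax <- max(dmax, abs(pe - pn))
  }
  expect_lt(dmax, 0.01)
})
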