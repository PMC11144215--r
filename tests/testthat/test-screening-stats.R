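test_that("confusion metrics equal hand-counted values", {
  ## perfect predictions
  cm <- confusionMetrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(cm$sensitivity, 1); expect_equal(cm$specificity, 1)
  ## all-positive predictions on mixed truth
  cm <- confusionMetrics(rep(1, 4), c(1, 0, 1, 0))
  expect_equal(cm$sensitivity, 1); expect_equal(cm$specificity, 0)
  ## 6-sample toy, counted by hand
  cm <- confusionMetrics(c(1, 1, 0, 0, 1, 0), c(1, 0, 1, 0, 1, 0))
  expect_equal(cm$TP, 2L); expect_equal(cm$FP, 1L)
  expect_equal(cm$TN, 2L); expect_equal(cm$FN, 1L)
  expect_equal(cm$sensitivity, 2 / 3)
  expect_equal(cm$specificity, 2 / 3)
  expect_equal(cm$ppv, 2 / 3); expect_equal(cm$npv, 2 / 3)
  ## zero denominators report NA, not 0
  cm <- confusionMetrics(c(1, 1), c(1, 1))
  expect_true(is.na(cm$specificity))
})

test_that("binomial confidence intervals match closed forms", {
  ## Clopper-Pearson with k = n: lower = (alpha/2)^(1/n), upper = 1
  ci <- binomialCI(10, 10, "clopper_pearson")
  expect_equal(unname(ci["lower"]), 0.025^(1 / 10), tolerance = 1e-10)
  expect_equal(unname(ci["upper"]), 1)
  ## Wald arithmetic
  ci <- binomialCI(5, 10, "wald")
  half <- qnorm(0.975) * sqrt(0.25 / 10)
  expect_equal(unname(ci), c(0.5 - half, 0.5 + half))
  ## degenerate p-hat = 0 clips to (0, 0)
  expect_equal(unname(binomialCI(0, 10, "wald")), c(0, 0))
  expect_error(binomialCI(0, 0), "n must be")
})

test_that("AUC equals the pairwise concordance oracle", {
  concordance <- function(scores, y) {
    pos <- scores[y == 1]; neg <- scores[y == 0]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  ## separable scores
  expect_equal(rocCurveAuc(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  ## all scores tied
  expect_equal(rocCurveAuc(rep(1, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  ## 8-sample toy
  s <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2)
  y <- c(1, 0, 1, 1, 0, 0, 1, 0)
  expect_equal(rocCurveAuc(s, y)$auc, concordance(s, y))
  ## random instances with ties, n <= 50
  set.seed(19)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    s <- sample(round(runif(n), 1), n, replace = TRUE)
    y <- as.integer(runif(n) < 0.4)
    if (all(y == 0)) y[1] <- 1L
    if (all(y == 1)) y[1] <- 0L
    expect_equal(rocCurveAuc(s, y)$auc, concordance(s, y))
  }
  expect_error(rocCurveAuc(1:4, rep(1, 4)), "both classes")
  ## ROC curve is monotone
  roc <- rocCurveAuc(s, y)$roc
  expect_true(all(diff(roc$sensitivity) >= 0))
  expect_true(all(diff(roc$specificity) <= 0))
})

test_that("operating point selection matches brute force", {
  bruteOp <- function(scores, y, min_sens = NULL, min_spec = NULL) {
    thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
    best <- NULL
    for (t in thr) {
      pred <- scores >= t
      sens <- sum(pred & y == 1) / sum(y == 1)
      spec <- sum(!pred & y == 0) / sum(y == 0)
      ok <- if (!is.null(min_sens)) sens >= min_sens else spec >= min_spec
      obj <- if (!is.null(min_sens)) spec else sens
      if (ok && (is.null(best) || obj > best$obj ||
                 (obj == best$obj && t > best$t)))
        best <- list(t = t, obj = obj, sens = sens, spec = spec)
    }
    best
  }
  set.seed(5)
  for (i in 1:20) {
    n <- sample(8:30, 1)
    s <- round(runif(n), 2)
    y <- as.integer(runif(n) < 0.5)
    if (all(y == 0)) y[1] <- 1L
    if (all(y == 1)) y[1] <- 0L
    roc <- rocCurveAuc(s, y)$roc
    for (target in c(0.9, 0.8)) {
      got <- operatingPointFor(roc, min_sensitivity = target)
      bf <- bruteOp(s, y, min_sens = target)
      expect_equal(got$specificity, bf$spec)
      got <- operatingPointFor(roc, min_specificity = target)
      bf <- bruteOp(s, y, min_spec = target)
      expect_equal(got$sensitivity, bf$sens)
    }
  }
  ## separable scores: sens >= 0.9 achievable at full specificity
  roc <- rocCurveAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$roc
  op <- operatingPointFor(roc, min_sensitivity = 0.9)
  expect_equal(op$specificity, 1)
  expect_false(op$flagged)
})

test_that("expected confusion matrices follow the scenario arithmetic", {
  op <- operatingPoint(NA, 0.887, 0.318)
  ec <- expectedConfusion(op, 0.15, 1000)
  expect_equal(ec$TP, 133.05)
  expect_equal(ec$FN, 16.95)
  expect_equal(ec$TN, 270.3)
  expect_equal(ec$FP, 579.7)
  ## degenerate scenarios
  ec0 <- expectedConfusion(op, 0, 1000)
  expect_equal(ec0$TP, 0); expect_equal(ec0$FN, 0)
  ec1 <- expectedConfusion(operatingPoint(NA, 1, 1), 0.3, 500)
  expect_equal(ec1$FP, 0); expect_equal(ec1$FN, 0)
  expect_equal(ec1$TP + ec1$TN, 500)
  ## cells always sum to n
  set.seed(3)
  for (i in 1:1000) {
    opi <- operatingPoint(NA, runif(1), runif(1))
    e <- expectedConfusion(opi, runif(1), 1000)
    expect_lt(abs(e$TP + e$FP + e$TN + e$FN - 1000), 1e-9)
  }
})

test_that("test reduction follows the predicted-negative identity", {
  expect_equal(testReduction(operatingPoint(NA, 0.887, 0.318), 0.15),
               0.28725)
  expect_equal(testReduction(operatingPoint(NA, 1, 1), 0.2), 0.8)
  expect_equal(testReduction(operatingPoint(NA, 1, 0), 0.37), 0)
  ## reduction equals the expected negative fraction of the confusion
  set.seed(8)
  for (i in 1:200) {
    op <- operatingPoint(NA, runif(1), runif(1)); p <- runif(1)
    e <- expectedConfusion(op, p, 1)
    expect_lt(abs(testReduction(op, p) - (e$TN + e$FN)), 1e-12)
  }
})

test_that("tier math is Bayes-consistent and reproduces >8x enrichment", {
  ## enrichment implied by the published tier prevalences
  expect_gt(0.493 / 0.059, 8)
  ## a high-sens / high-spec pair at 15% baseline
  op_low <- operatingPoint(NA, sensitivity = 0.887, specificity = 0.318)
  op_high <- operatingPoint(NA, sensitivity = 0.5, specificity = 0.9)
  tp <- tierPrevalences(op_low, op_high, 0.15)
  expect_equal(unname(sum(tp$fractions)), 1)
  ## tier-weighted prevalences mix back to baseline
  expect_lt(abs(sum(tp$fractions * tp$prevalences) - 0.15), 1e-9)
  ## degenerate collapse: identical operating points empty the Mid tier
  tp2 <- tierPrevalences(op_low, op_low, 0.15)
  expect_equal(unname(tp2$fractions["Mid"]), 0)
  ## random consistent pairs: mixture property holds
  set.seed(12)
  for (i in 1:1000) {
    sH <- runif(1); sL <- runif(1, sH, 1)
    eL <- runif(1); eH <- runif(1, eL, 1)
    p <- runif(1, 0.01, 0.99)
    t <- tierPrevalences(operatingPoint(NA, sL, eL),
                         operatingPoint(NA, sH, eH), p)
    expect_lt(abs(sum(t$fractions) - 1), 1e-9)
    pr <- ifelse(is.na(t$prevalences), 0, t$prevalences)
    expect_lt(abs(sum(t$fractions * pr) - p), 1e-9)
  }
  expect_error(tierPrevalences(operatingPoint(NA, 0.5, 0.9),
                               operatingPoint(NA, 0.9, 0.3), 0.15),
               "high-sensitivity")
})

test_that("the cost model conserves money and matches the headline case", {
  base <- costModel(24000, 5000, 0.15)
  expect_equal(base$total_cost, 120e6)
  expect_equal(base$detected_positives, 3600)
  expect_equal(base$cost_per_detected_positive, 120e6 / 3600)
  withAI <- costModel(24000, 5000, 0.15,
                      operatingPoint(NA, 0.887, 0.318))
  expect_equal(withAI$savings_vs_no_AI, 120e6 * 0.28725)
  ## conservation: with-AI cost + savings = without-AI cost, exactly
  expect_equal(withAI$total_cost + withAI$savings_vs_no_AI,
               base$total_cost)
  set.seed(4)
  for (i in 1:200) {
    op <- operatingPoint(NA, runif(1), runif(1))
    n <- sample(1000:50000, 1); c <- runif(1, 100, 10000); p <- runif(1)
    a <- costModel(n, c, p, op); b <- costModel(n, c, p)
    expect_equal(a$total_cost + a$savings_vs_no_AI, b$total_cost)
  }
  ## zero cost per test zeroes all monetary outputs
  z <- costModel(1000, 0, 0.15, operatingPoint(NA, 0.9, 0.3))
  expect_equal(z$total_cost, 0); expect_equal(z$savings_vs_no_AI, 0)
})

test_that("exact binomial power behaves like an exact test", {
  ## size never exceeds alpha; power at p1 = p0 equals the size
  pw <- exactBinomialPower(150, 0.8, 0.8, 0.05)
  expect_lte(pw$power, 0.05)
  expect_equal(pw$power, pw$size)
  ## monotone non-decreasing in n
  pows <- vapply(c(50, 100, 150, 300), function(n)
    exactBinomialPower(n, 0.8, 0.9, 0.05)$power, numeric(1))
  expect_true(all(diff(pows) >= -1e-12))
  ## large n separates any fixed pair
  expect_gt(exactBinomialPower(2000, 0.8, 0.9)$power, 0.999)
  ## alternative conventions also control size
  for (conv in c("doubled", "minlike")) {
    p <- exactBinomialPower(60, 0.5, 0.5, 0.05, convention = conv)
    expect_lte(p$size, 0.05 + 1e-12)
  }
  ## region bounds: rejection counts are extreme outcomes
  r <- exactBinomialPower(150, 0.8, 0.9)$region
  expect_true(all(r <= 150 & r >= 0))
  expect_true(all(diff(sort(r[r < 120])) == 1))
})
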