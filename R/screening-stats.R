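## Validation statistics and deployment-impact analytics: confusion
## metrics with confidence intervals, ROC/AUC and operating points,
## expected confusion matrices, molecular-test reduction, 3-tier
## enrichment, the testing cost model and exact binomial power.

#' Operating point
#'
#' @param threshold likelihood threshold.
#' @param sensitivity,specificity in `[0, 1]`.
#' @return list of class `"OperatingPoint"`.
#' @export
operatingPoint <- function(threshold = NA_real_, sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  structure(list(threshold = threshold, sensitivity = sensitivity,
                 specificity = specificity), class = "OperatingPoint")
}

#' Confusion-matrix metrics from binary predictions
#'
#' Metrics whose denominator is zero are reported `NA` (undefined), not
#' 0.
#'
#' @param predictions,truth equal-length binary vectors (1/TRUE =
#'   positive).
#' @return list with counts `TP`, `FP`, `TN`, `FN` and `sensitivity`,
#'   `specificity`, `ppv`, `npv`.
#' @export
confusionMetrics <- function(predictions, truth) {
  stopifnot(length(predictions) == length(truth))
  p <- as.logical(predictions); y <- as.logical(truth)
  TP <- sum(p & y); FP <- sum(p & !y); TN <- sum(!p & !y); FN <- sum(!p & y)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       sensitivity = safe(TP, TP + FN), specificity = safe(TN, TN + FP),
       ppv = safe(TP, TP + FP), npv = safe(TN, TN + FN))
}

#' Binomial proportion confidence interval
#'
#' `wald`: normal approximation `p +/- z * sqrt(p(1-p)/n)`, clipped to
#' `[0, 1]` (matches the deployment-style CI digits). `clopper_pearson`:
#' exact beta-quantile interval (recommended for small n).
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, `n >= 1`.
#' @param method `"wald"` or `"clopper_pearson"`.
#' @param level confidence level (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
binomialCI <- function(k, n, method = c("wald", "clopper_pearson"),
                       level = 0.95) {
  method <- match.arg(method)
  if (n < 1) stop("n must be >= 1")
  stopifnot(k >= 0, k <= n)
  a <- 1 - level
  if (method == "wald") {
    p <- k / n
    z <- qnorm(1 - a / 2)
    half <- z * sqrt(p * (1 - p) / n)
    c(lower = max(0, p - half), upper = min(1, p + half))
  } else {
    lower <- if (k == 0) 0 else qbeta(a / 2, k, n - k + 1)
    upper <- if (k == n) 1 else qbeta(1 - a / 2, k + 1, n - k)
    c(lower = lower, upper = upper)
  }
}

#' ROC curve and AUC
#'
#' AUC equals the Mann-Whitney concordance probability (ties count 1/2);
#' the curve is computed over all score thresholds and integrated by the
#' trapezoidal rule, which coincides with the concordance value.
#'
#' @param scores numeric scores (larger = more positive).
#' @param labels binary truth (1/TRUE = positive).
#' @return list with `roc` (data.frame `threshold`, `sensitivity`,
#'   `specificity`) and `auc`.
#' @export
rocCurveAuc <- function(scores, labels) {
  y <- as.logical(labels)
  if (!any(y) || all(y))
    stop("both classes must be present to compute a ROC curve")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(sens = sum(pred & y) / sum(y), spec = sum(!pred & !y) / sum(!y))
  }, numeric(2)))
  roc <- data.frame(threshold = thr, sensitivity = pts[, "sens"],
                    specificity = pts[, "spec"])
  ## Mann-Whitney with half credit for ties
  r <- rank(scores)
  n1 <- sum(y); n0 <- sum(!y)
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(roc = roc, auc = auc)
}

#' Operating point meeting a sensitivity or specificity constraint
#'
#' Maximizes the complementary metric subject to the constraint; among
#' equally good thresholds the higher threshold wins. If the constraint
#' is unreachable the closest achievable point is returned with
#' `flagged = TRUE`.
#'
#' @param roc data.frame from [rocCurveAuc()]`$roc`.
#' @param min_sensitivity,min_specificity exactly one must be given.
#' @return an [operatingPoint()] with an extra `flagged` field.
#' @export
operatingPointFor <- function(roc, min_sensitivity = NULL,
                              min_specificity = NULL) {
  if (is.null(min_sensitivity) == is.null(min_specificity))
    stop("give exactly one of min_sensitivity or min_specificity")
  if (!is.null(min_sensitivity)) {
    ok <- roc$sensitivity >= min_sensitivity
    flagged <- !any(ok)
    cand <- if (flagged) which(roc$sensitivity == max(roc$sensitivity))
            else which(ok)
    best <- cand[order(-roc$specificity[cand], -roc$threshold[cand])][1]
  } else {
    ok <- roc$specificity >= min_specificity
    flagged <- !any(ok)
    cand <- if (flagged) which(roc$specificity == max(roc$specificity))
            else which(ok)
    best <- cand[order(-roc$sensitivity[cand], -roc$threshold[cand])][1]
  }
  op <- operatingPoint(roc$threshold[best], roc$sensitivity[best],
                       roc$specificity[best])
  op$flagged <- flagged
  op
}

#' Expected confusion matrix under a screening scenario
#'
#' Cells are expectations (real-valued): `TP = n * prev * sens`,
#' `FN = n * prev * (1 - sens)`, `TN = n * (1 - prev) * spec`,
#' `FP = n * (1 - prev) * (1 - spec)`; they sum to `n` exactly. Set
#' `round = TRUE` for display-style integer cells.
#'
#' @param op an [operatingPoint()].
#' @param prevalence biomarker prevalence in `[0, 1]`.
#' @param n_patients cohort size.
#' @param round round cells to integers (default FALSE).
#' @return list with `TP`, `FP`, `TN`, `FN`.
#' @export
expectedConfusion <- function(op, prevalence, n_patients, round = FALSE) {
  stopifnot(prevalence >= 0, prevalence <= 1, n_patients >= 0)
  TP <- n_patients * prevalence * op$sensitivity
  FN <- n_patients * prevalence * (1 - op$sensitivity)
  TN <- n_patients * (1 - prevalence) * op$specificity
  FP <- n_patients * (1 - prevalence) * (1 - op$specificity)
  out <- list(TP = TP, FP = FP, TN = TN, FN = FN)
  if (round) out <- lapply(out, base::round)
  out
}

#' Fraction of patients spared molecular testing
#'
#' The fraction predicted negative by the screening device:
#' `reduction = spec * (1 - prev) + (1 - sens) * prev`.
#'
#' @param op an [operatingPoint()].
#' @param prevalence biomarker prevalence.
#' @return reduction fraction in `[0, 1]`.
#' @examples
#' testReduction(operatingPoint(NA, 0.887, 0.318), 0.15)  # 0.28725
#' @export
testReduction <- function(op, prevalence) {
  op$specificity * (1 - prevalence) + (1 - op$sensitivity) * prevalence
}

#' 3-tier population fractions, per-tier prevalences and enrichment
#'
#' `High` = predicted positive at the high-specificity operating point;
#' `Low` = predicted negative at the high-sensitivity operating point;
#' `Mid` = the remainder. Per-tier biomarker prevalences follow from
#' Bayes' rule; enrichment ratios compare High vs Low and High vs the
#' baseline prevalence.
#'
#' @param op_low high-sensitivity operating point (its sensitivity must
#'   be at least `op_high`'s, and specificity at most).
#' @param op_high high-specificity operating point.
#' @param prevalence baseline prevalence.
#' @return list with `fractions` (Low/Mid/High population shares summing
#'   to 1), `prevalences` (per-tier biomarker prevalence),
#'   `enrichment_high_vs_low`, `enrichment_high_vs_baseline`.
#' @export
tierPrevalences <- function(op_low, op_high, prevalence) {
  sL <- op_low$sensitivity; eL <- op_low$specificity
  sH <- op_high$sensitivity; eH <- op_high$specificity
  if (sL < sH || eL > eH)
    stop("op_low must be the high-sensitivity point (sens >= op_high's)")
  p <- prevalence
  f_high <- p * sH + (1 - p) * (1 - eH)
  f_low <- p * (1 - sL) + (1 - p) * eL
  f_mid <- 1 - f_high - f_low
  if (f_mid < -1e-12) stop("inconsistent operating points: negative Mid mass")
  f_mid <- max(f_mid, 0)
  prev_high <- if (f_high > 0) p * sH / f_high else NA_real_
  prev_low <- if (f_low > 0) p * (1 - sL) / f_low else NA_real_
  prev_mid <- if (f_mid > 0) p * (sL - sH) / f_mid else NA_real_
  list(fractions = c(Low = f_low, Mid = f_mid, High = f_high),
       prevalences = c(Low = prev_low, Mid = prev_mid, High = prev_high),
       enrichment_high_vs_low = prev_high / prev_low,
       enrichment_high_vs_baseline = prev_high / p)
}

#' Molecular-testing cost model
#'
#' Without prescreening every patient is tested: `total = n * cost`,
#' `detected = n * prev`. With a screening operating point, only
#' patients predicted positive are tested:
#' `tested = n * (1 - reduction)`, `detected = n * prev * sens`,
#' `savings = n * cost * reduction`. The with-screening cost plus the
#' savings equals the no-screening cost exactly.
#'
#' @param n_patients cohort size.
#' @param cost_per_test currency per molecular test (>= 0).
#' @param prevalence biomarker prevalence.
#' @param op optional [operatingPoint()]; omit for the no-screening
#'   baseline.
#' @return list with `total_cost`, `n_tested`, `detected_positives`,
#'   `cost_per_detected_positive`, `savings_vs_no_AI`.
#' @examples
#' costModel(24000, 5000, 0.15)  # $120M, ~$33,333 per detected
#' @export
costModel <- function(n_patients, cost_per_test, prevalence, op = NULL) {
  stopifnot(cost_per_test >= 0, n_patients >= 0)
  base_total <- n_patients * cost_per_test
  if (is.null(op)) {
    detected <- n_patients * prevalence
    return(list(total_cost = base_total, n_tested = n_patients,
                detected_positives = detected,
                cost_per_detected_positive =
                  if (detected > 0) base_total / detected else NA_real_,
                savings_vs_no_AI = 0))
  }
  red <- testReduction(op, prevalence)
  tested <- n_patients * (1 - red)
  total <- tested * cost_per_test
  detected <- n_patients * prevalence * op$sensitivity
  list(total_cost = total, n_tested = tested,
       detected_positives = detected,
       cost_per_detected_positive =
         if (detected > 0) total / detected else NA_real_,
       savings_vs_no_AI = base_total - total)
}

#' Power of the two-sided exact binomial test
#'
#' Builds the two-sided rejection region of the exact binomial test of
#' `p = p0` at level `alpha` and returns the rejection probability under
#' `p1`. Conventions: `"central"` (default) takes the largest lower and
#' upper tails each with null probability at most `alpha/2`;
#' `"doubled"` rejects where the doubled one-sided exact p-value is at
#' most `alpha`; `"minlike"` orders outcomes by null likelihood and
#' rejects the least likely outcomes with total null mass at most
#' `alpha`.
#'
#' @param n trials.
#' @param p0 null proportion.
#' @param p1 alternative proportion.
#' @param alpha two-sided type I error (default 0.05).
#' @param convention `"central"`, `"doubled"` or `"minlike"`.
#' @return list with `power`, `size` (achieved null rejection
#'   probability), `region` (rejected counts), `flagged` (TRUE when the
#'   region is empty).
#' @examples
#' exactBinomialPower(150, 0.8, 0.9)$power  # ~0.93
#' @export
exactBinomialPower <- function(n, p0, p1, alpha = 0.05,
                               convention = c("central", "doubled",
                                              "minlike")) {
  convention <- match.arg(convention)
  stopifnot(n >= 1, p0 > 0, p0 < 1, p1 > 0, p1 < 1, alpha > 0, alpha < 1)
  k <- 0:n
  d0 <- stats::dbinom(k, n, p0)
  region <- switch(convention,
    central = {
      lower <- stats::pbinom(k, n, p0) <= alpha / 2
      upper <- (1 - stats::pbinom(k - 1, n, p0)) <= alpha / 2
      k[lower | upper]
    },
    doubled = {
      pl <- stats::pbinom(k, n, p0)
      pu <- 1 - stats::pbinom(k - 1, n, p0)
      k[2 * pmin(pl, pu) <= alpha]
    },
    minlike = {
      ord <- order(d0)
      cum <- cumsum(d0[ord])
      take <- ord[cum <= alpha]
      sort(k[take])
    })
  flagged <- length(region) == 0
  power <- if (flagged) 0 else sum(stats::dbinom(region, n, p1))
  size <- if (flagged) 0 else sum(d0[region + 1])
  list(power = power, size = size, region = region, flagged = flagged)
}

#' Deployment accounting over a batch of device results
#'
#' Counts received slides, generated predictions and QC failures; the
#' predicted-negative fraction among predictions; and, where molecular
#' outcomes are available, sensitivity, specificity and observed
#' prevalence (slides without a molecular result are excluded from those
#' denominators).
#'
#' @param results list of [DeviceResult-class].
#' @param molecular optional character vector aligned with `results`:
#'   `"positive"`, `"negative"` or `NA` when no molecular result exists.
#' @return list with `received`, `predicted`, `qc_failed`,
#'   `prediction_rate`, `predicted_negative_fraction`, `sensitivity`,
#'   `specificity`, `prevalence` (the last three `NA` when undefined).
#' @export
deploymentAccounting <- function(results, molecular = NULL) {
  stopifnot(length(results) >= 1)
  status <- vapply(results, function(r) r@status, character(1))
  calls <- vapply(results, function(r) r@call, character(1))
  received <- length(results)
  predicted <- sum(status == "ok")
  qc_failed <- sum(status == "error" &
    vapply(results, function(r) identical(r@errorMessage, ERR_QC_FAILURE),
           logical(1)))
  neg_frac <- if (predicted > 0)
    sum(calls == "FGFR-", na.rm = TRUE) / predicted else NA_real_
  sens <- spec <- prev <- NA_real_
  if (!is.null(molecular)) {
    ok <- status == "ok" & !is.na(molecular)
    if (any(ok)) {
      y <- molecular[ok] == "positive"
      p <- calls[ok] == "FGFR+"
      cm <- confusionMetrics(p, y)
      sens <- cm$sensitivity; spec <- cm$specificity
      prev <- mean(y)
    }
  }
  list(received = received, predicted = predicted, qc_failed = qc_failed,
       prediction_rate = predicted / received,
       predicted_negative_fraction = neg_frac,
       sensitivity = sens, specificity = spec, prevalence = prev)
}
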