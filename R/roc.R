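#' @title ROC curves, AUC and diagnostic metrics
#' @description Receiver operating characteristic machinery: midpoint-threshold
#'   ROC curves under the "positive if score >= threshold" rule, concordance
#'   AUC (ties counted half), normal-theory and bootstrap confidence
#'   intervals, a CI-based test for the difference of two AUCs, Youden-index
#'   cut-off selection and confusion-matrix metrics.
#' @name roc-validation
NULL

.check_two_class <- function(scores, outcomes) {
  if (length(scores) != length(outcomes)) {
    stop("scores and outcomes must have equal length", call. = FALSE)
  }
  if (any(is.na(scores)) || any(is.na(outcomes))) {
    stop("scores and outcomes must not contain missing values", call. = FALSE)
  }
  outcomes <- as.logical(outcomes)
  if (!any(outcomes) || all(outcomes)) {
    stop("ROC undefined: need at least one positive and one negative outcome",
         call. = FALSE)
  }
  outcomes
}

#' Empirical ROC curve
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' observed scores, plus `-Inf` and `+Inf` sentinels; a record is classified
#' positive when its score is greater than or equal to the threshold. The
#' curve therefore runs from (sensitivity, specificity) = (1, 0) at `-Inf`
#' to (0, 1) at `+Inf`.
#'
#' @param scores Numeric score values.
#' @param outcomes Logical outcomes (`TRUE` = event).
#' @return Object of class `mt_roc`: thresholds, sensitivity, specificity,
#'   `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, outcomes) {
  outcomes <- .check_two_class(scores, outcomes)
  u <- sort(unique(scores))
  mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  thresholds <- c(-Inf, mids, Inf)
  cases <- scores[outcomes]
  controls <- scores[!outcomes]
  sens <- vapply(thresholds, function(t) mean(cases >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(controls < t), numeric(1))
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, n_pos = length(cases),
                 n_neg = length(controls)),
            class = "mt_roc")
}

#' @export
print.mt_roc <- function(x, ...) {
  cat("ROC curve: ", length(x$thresholds), " thresholds, ",
      x$n_pos, " cases / ", x$n_neg, " controls, AUC = ",
      format(auc_trapezoid(x), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.mt_roc <- function(x, ...) {
  data.frame(threshold = x$thresholds, sensitivity = x$sensitivity,
             one_minus_specificity = 1 - x$specificity)
}

#' Area under the ROC curve (concordance form)
#'
#' AUC as the Mann-Whitney concordance probability: the fraction of
#' case/control pairs where the case outscores the control, ties counted
#' half. Computed from midranks, so ties are exact.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, outcomes) {
  outcomes <- .check_two_class(scores, outcomes)
  r <- rank(scores)
  n_pos <- sum(outcomes)
  n_neg <- sum(!outcomes)
  (sum(r[outcomes]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Trapezoidal area under an `mt_roc` curve
#'
#' @param curve An `mt_roc` object.
#' @return Trapezoidal area; equals [auc()] on the same data to numerical
#'   precision, including under ties.
#' @export
auc_trapezoid <- function(curve) {
  stopifnot(inherits(curve, "mt_roc"))
  x <- 1 - curve$specificity   # decreasing in threshold order
  y <- curve$sensitivity
  sum((x[-length(x)] - x[-1]) * (y[-length(y)] + y[-1]) / 2)
}

# DeLong variance of the AUC via midrank placements.
.delong_se <- function(scores, outcomes) {
  m <- sum(outcomes); n <- sum(!outcomes)
  r <- rank(scores)
  rx <- rank(scores[outcomes])
  ry <- rank(scores[!outcomes])
  v10 <- (r[outcomes] - rx) / n
  v01 <- 1 - (r[!outcomes] - ry) / m
  sqrt(stats::var(v10) / m + stats::var(v01) / n)
}

.hanley_mcneil_se <- function(a, n_pos, n_neg) {
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt((a * (1 - a) + (n_pos - 1) * (q1 - a^2) + (n_neg - 1) * (q2 - a^2)) /
         (n_pos * n_neg))
}

#' Confidence interval for the AUC
#'
#' Symmetric normal-theory interval (clipped to `[0, 1]`) with the standard
#' error from either the DeLong placement variance or the Hanley-McNeil
#' approximation, or a stratified percentile bootstrap.
#'
#' @inheritParams roc_curve
#' @param method `"delong"` (default), `"hanley_mcneil"` or `"bootstrap"`.
#' @param level Confidence level in (0, 1); default 0.95.
#' @param boot_reps Bootstrap replicates (bootstrap method only).
#' @param seed Integer seed for the bootstrap resampling.
#' @return Numeric `c(low, high)` with attributes `auc`, `se` (normal-theory
#'   methods) and `method`.
#' @export
auc_ci <- function(scores, outcomes,
                   method = c("delong", "hanley_mcneil", "bootstrap"),
                   level = 0.95, boot_reps = 2000, seed = 1L) {
  method <- match.arg(method)
  outcomes <- .check_two_class(scores, outcomes)
  stopifnot(level > 0, level < 1)
  a <- auc(scores, outcomes)
  if (method == "bootstrap") {
    pos <- scores[outcomes]; neg <- scores[!outcomes]
    if (length(pos) < 2 || length(neg) < 2) {
      stop("bootstrap CI needs at least 2 cases and 2 controls", call. = FALSE)
    }
    stats <- withr_seed(seed, {
      vapply(seq_len(boot_reps), function(i) {
        bp <- sample(pos, replace = TRUE)
        bn <- sample(neg, replace = TRUE)
        auc(c(bp, bn), c(rep(TRUE, length(bp)), rep(FALSE, length(bn))))
      }, numeric(1))
    })
    ci <- unname(stats::quantile(stats, c((1 - level) / 2, 1 - (1 - level) / 2),
                                 type = 7))
    return(structure(ci, auc = a, method = method))
  }
  se <- switch(method,
    delong = .delong_se(scores, outcomes),
    hanley_mcneil = .hanley_mcneil_se(a, sum(outcomes), sum(!outcomes)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- c(max(0, a - z * se), min(1, a + z * se))
  structure(ci, auc = a, se = se, method = method)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Compare two AUCs via their confidence intervals
#'
#' Recovers each curve's standard error from its symmetric 95% confidence
#' interval, `SE = (high - low) / (2 * 1.959964)`, forms
#' `z = (auc1 - auc2) / sqrt(SE1^2 + SE2^2)` and reports the two-sided
#' standard-normal p-value. This is the CI-derived parametric comparison of
#' two ROC areas; it treats the two curves as independent.
#'
#' @param auc1,auc2 The two AUC point estimates.
#' @param ci1,ci2 Length-2 numeric 95% confidence intervals, symmetric about
#'   their AUCs (tolerance 1e-6).
#' @return An `htest` object with the z statistic and two-sided p-value.
#' @export
compare_aucs_ci_method <- function(auc1, ci1, auc2, ci2) {
  for (pair in list(list(a = auc1, ci = ci1, i = 1),
                    list(a = auc2, ci = ci2, i = 2))) {
    asym <- abs((pair$ci[1] + pair$ci[2]) / 2 - pair$a)
    if (asym > 1e-6) {
      stop(sprintf("confidence interval %d is not symmetric about its AUC (off by %.2g); derive the standard errors directly and compare those",
                   pair$i, asym), call. = FALSE)
    }
  }
  zq <- stats::qnorm(0.975)
  se1 <- (ci1[2] - ci1[1]) / (2 * zq)
  se2 <- (ci2[2] - ci2[1]) / (2 * zq)
  if (se1 == 0 && se2 == 0) {
    z <- if (auc1 == auc2) 0 else sign(auc1 - auc2) * Inf
  } else {
    z <- (auc1 - auc2) / sqrt(se1^2 + se2^2)
  }
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(
    statistic = c(z = z),
    p.value = p,
    estimate = c(auc1 = auc1, auc2 = auc2),
    method = "CI-derived z test for the difference of two AUCs",
    data.name = sprintf("auc1 = %.4g, auc2 = %.4g", auc1, auc2)),
    class = "htest")
}

#' Youden-optimal cut-off
#'
#' Returns the finite threshold of an [roc_curve()] maximizing Youden's
#' J = sensitivity + specificity - 1; ties are broken toward the smaller
#' threshold (higher sensitivity), the conservative choice for a screening
#' rule.
#'
#' @param curve An `mt_roc` object.
#' @return The optimal finite threshold (half-point values on integer
#'   scores).
#' @export
optimal_cutoff <- function(curve) {
  stopifnot(inherits(curve, "mt_roc"))
  finite <- is.finite(curve$thresholds)
  if (!any(finite)) stop("no finite threshold available", call. = FALSE)
  j <- curve$sensitivity[finite] + curve$specificity[finite] - 1
  thr <- curve$thresholds[finite]
  thr[which.max(j)]   # thresholds ascending; which.max takes the smallest tie
}

#' Confusion-matrix metrics at a threshold
#'
#' Classifies positive where `score >= threshold` and reports sensitivity,
#' specificity, PPV and NPV together with the confusion counts. A metric
#' with a zero denominator is returned as `NA`.
#'
#' @inheritParams roc_curve
#' @param threshold Classification threshold.
#' @return Named list: `sensitivity`, `specificity`, `ppv`, `npv` (fractions
#'   in `[0, 1]` or `NA`), `tp`, `fp`, `tn`, `fn`.
#' @export
classification_metrics <- function(scores, outcomes, threshold) {
  outcomes <- .check_two_class(scores, outcomes)
  pred <- scores >= threshold
  tp <- sum(pred & outcomes)
  fp <- sum(pred & !outcomes)
  tn <- sum(!pred & !outcomes)
  fn <- sum(!pred & outcomes)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  list(sensitivity = safe_div(tp, tp + fn),
       specificity = safe_div(tn, tn + fp),
       ppv = safe_div(tp, tp + fp),
       npv = safe_div(tn, tn + fn),
       tp = tp, fp = fp, tn = tn, fn = fn)
}
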