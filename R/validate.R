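#' Validate massive-transfusion scores on a cohort
#'
#' The package's main entry point: applies the requested scores to a filtered,
#' complete-case cohort, builds each score's ROC curve against the
#' massive-transfusion outcome, estimates the AUC with a confidence interval,
#' selects a cut-off (Youden-optimal or the published fixed cut-offs) and
#' reports sensitivity, specificity, PPV and NPV with the underlying
#' confusion counts — one row per score, in the layout customary for a
#' score-comparison table.
#'
#' @param records Cohort `data.frame`, already eligibility-filtered and
#'   complete for the requested scores (see [apply_eligibility_filters()]),
#'   with both outcome classes present.
#' @param score_ids Scores to validate; default all six.
#' @param cutoff_mode `"youden"` (default) selects each score's cut-off by
#'   maximizing Youden's J on this cohort; `"fixed"` uses `fixed_cutoffs`.
#' @param fixed_cutoffs Named cut-offs used when `cutoff_mode = "fixed"`;
#'   defaults to the published half-point cut-offs ([default_cutoffs()]).
#' @param ci_method Confidence-interval method passed to [auc_ci()].
#' @param level Confidence level (default 0.95).
#' @param boot_reps,seed Bootstrap controls, used only when
#'   `ci_method = "bootstrap"`.
#' @return Object of class `mt_validation` with elements `performance`
#'   (a `data.frame`: `score`, `auc`, `ci_low`, `ci_high`, `cutoff`,
#'   `sensitivity`, `specificity`, `ppv`, `npv` in percent, and `tp`, `fp`,
#'   `tn`, `fn`), `roc` (named list of [roc_curve()] objects), `scores`
#'   (the per-patient score matrix), `n`, `n_mt`, and the settings used.
#' @examples
#' spec <- cohort_spec(n = 2000, seed = 11)
#' cohort <- generate_cohort(spec)
#' fit <- mt_validate(cohort)
#' fit
#' summary(fit)
#' @export
mt_validate <- function(records,
                        score_ids = mt_score_ids(),
                        cutoff_mode = c("youden", "fixed"),
                        fixed_cutoffs = default_cutoffs(),
                        ci_method = c("delong", "hanley_mcneil", "bootstrap"),
                        level = 0.95, boot_reps = 2000, seed = 1L) {
  cutoff_mode <- match.arg(cutoff_mode)
  ci_method <- match.arg(ci_method)
  defs <- score_definitions(score_ids)   # validates ids
  matrix_df <- score_cohort(records, score_ids)
  outcomes <- matrix_df$mt_outcome
  if (!any(outcomes) || all(outcomes)) {
    stop("validation needs both outcome classes in the cohort", call. = FALSE)
  }
  rows <- vector("list", length(score_ids))
  curves <- vector("list", length(score_ids))
  names(curves) <- score_ids
  for (i in seq_along(score_ids)) {
    id <- score_ids[i]
    s <- matrix_df[[id]]
    curve <- roc_curve(s, outcomes)
    curves[[id]] <- curve
    ci <- auc_ci(s, outcomes, method = ci_method, level = level,
                 boot_reps = boot_reps, seed = seed)
    cutoff <- if (cutoff_mode == "youden") {
      optimal_cutoff(curve)
    } else {
      if (is.null(fixed_cutoffs[[id]]) || is.na(fixed_cutoffs[[id]])) {
        stop("no fixed cutoff supplied for score '", id, "'", call. = FALSE)
      }
      fixed_cutoffs[[id]]
    }
    m <- classification_metrics(s, outcomes, cutoff)
    rows[[i]] <- data.frame(
      score = id, auc = attr(ci, "auc"), ci_low = ci[1], ci_high = ci[2],
      cutoff = cutoff,
      sensitivity = 100 * m$sensitivity, specificity = 100 * m$specificity,
      ppv = 100 * m$ppv, npv = 100 * m$npv,
      tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn,
      stringsAsFactors = FALSE)
  }
  structure(list(
    performance = do.call(rbind, rows),
    roc = curves,
    scores = matrix_df,
    n = nrow(matrix_df),
    n_mt = sum(outcomes),
    cutoff_mode = cutoff_mode,
    ci_method = ci_method,
    level = level,
    call = match.call()),
    class = "mt_validation")
}

#' @export
print.mt_validation <- function(x, digits = 3, ...) {
  cat("Massive-transfusion score validation\n")
  cat(sprintf("  n = %d patients, %d with massive transfusion (%.1f%%)\n",
              x$n, x$n_mt, 100 * x$n_mt / x$n))
  cat(sprintf("  cut-offs: %s; CI method: %s (level %.0f%%)\n\n",
              x$cutoff_mode, x$ci_method, 100 * x$level))
  perf <- x$performance
  disp <- data.frame(
    score = perf$score,
    AUC = sprintf("%.3f", perf$auc),
    `95% CI` = sprintf("%.3f, %.3f", perf$ci_low, perf$ci_high),
    `cut-off` = sprintf(">= %.1f", perf$cutoff),
    `Sens %` = sprintf("%.1f", perf$sensitivity),
    `Spec %` = sprintf("%.1f", perf$specificity),
    `PPV %` = sprintf("%.1f", perf$ppv),
    `NPV %` = sprintf("%.1f", perf$npv),
    check.names = FALSE, stringsAsFactors = FALSE)
  print(disp, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mt_validation <- function(object, ...) {
  structure(list(fit = object,
                 ranking = object$performance$score[
                   order(object$performance$auc, decreasing = TRUE)]),
            class = "summary.mt_validation")
}

#' @export
print.summary.mt_validation <- function(x, ...) {
  print(x$fit)
  cat("\nScores ranked by AUC: ", paste(x$ranking, collapse = " > "), "\n",
      sep = "")
  best <- x$ranking[1:2]
  perf <- x$fit$performance
  p1 <- perf[perf$score == best[1], ]
  p2 <- perf[perf$score == best[2], ]
  cmp <- compare_aucs_ci_method(p1$auc, c(p1$ci_low, p1$ci_high),
                                p2$auc, c(p2$ci_low, p2$ci_high))
  cat(sprintf("Top-two comparison (%s vs %s): z = %.3f, two-sided p = %.4f\n",
              best[1], best[2], cmp$statistic, cmp$p.value))
  invisible(x)
}

#' @export
as.data.frame.mt_validation <- function(x, ...) x$performance

#' Plot ROC curves of a validation
#'
#' Overlays the per-score ROC curves in base graphics (1 - specificity
#' against sensitivity), with the chance diagonal.
#'
#' @param x An `mt_validation` object.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.mt_validation <- function(x, ...) {
  ids <- names(x$roc)
  cols <- grDevices::hcl.colors(max(3, length(ids)), "Dark 2")[seq_along(ids)]
  graphics::plot(c(0, 1), c(0, 1), type = "n",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 main = "ROC curves: massive-transfusion prediction", ...)
  graphics::abline(0, 1, col = "grey70", lty = 2)
  for (i in seq_along(ids)) {
    curve <- x$roc[[ids[i]]]
    ord <- order(1 - curve$specificity)
    graphics::lines((1 - curve$specificity)[ord], curve$sensitivity[ord],
                    col = cols[i], lwd = 2)
  }
  labels <- sprintf("%s (AUC %.3f)", x$performance$score, x$performance$auc)
  graphics::legend("bottomright", legend = labels, col = cols, lwd = 2,
                   bty = "n", cex = 0.85)
  invisible(x)
}
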