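test_that("ROC thresholds are midpoints with sentinels and correct endpoints", {
  perfect <- roc_curve(c(10, 1), c(TRUE, FALSE))
  expect_equal(perfect$thresholds, c(-Inf, 5.5, Inf))
  expect_equal(perfect$sensitivity, c(1, 1, 0))
  expect_equal(perfect$specificity, c(0, 1, 1))

  tied <- roc_curve(c(3, 3, 3, 3), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(tied$thresholds, c(-Inf, Inf))
  expect_equal(auc(c(3, 3, 3, 3), c(TRUE, FALSE, TRUE, FALSE)), 0.5)

  mixed <- roc_curve(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(mixed$thresholds, c(-Inf, 2, 3.5, 4.5, Inf))
  i <- which(mixed$thresholds == 4.5)
  expect_equal(mixed$sensitivity[i], 0.5)
  expect_equal(mixed$specificity[i], 1.0)
  # monotone coordinates
  expect_true(all(diff(mixed$sensitivity) <= 0))
  expect_true(all(diff(mixed$specificity) >= 0))

  expect_error(roc_curve(c(1, 2), c(TRUE, TRUE)), "one positive and one negative")
})

test_that("concordance AUC matches pairwise enumeration and trapezoid exactly", {
  expect_equal(auc(c(10, 1), c(TRUE, FALSE)), 1.0)
  expect_equal(auc(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE)), 0.75)

  set.seed(202)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    scores <- sample(0:8, n, replace = TRUE)  # heavy ties
    outcomes <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    a <- auc(scores, outcomes)
    expect_equal(a, auc_pairwise(scores, outcomes), tolerance = 1e-12)
    expect_equal(a, auc_trapezoid(roc_curve(scores, outcomes)),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under monotone transforms and flips under negation", {
  set.seed(7)
  scores <- rnorm(80)
  outcomes <- c(TRUE, FALSE, sample(c(TRUE, FALSE), 78, replace = TRUE))
  a <- auc(scores, outcomes)
  expect_equal(auc(exp(scores), outcomes), a, tolerance = 1e-12)
  expect_equal(auc(-scores, outcomes), 1 - a, tolerance = 1e-12)
})

test_that("Hanley-McNeil interval matches its closed form", {
  # AUC 0.75 with 2 cases and 2 controls
  ci <- auc_ci(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE),
               method = "hanley_mcneil")
  a <- 0.75
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (q1 - a^2) + (q2 - a^2)) / 4)
  expect_equal(attr(ci, "se"), se, tolerance = 1e-12)
  expect_equal(se, 0.2763, tolerance = 1e-3)
  expect_equal(ci[[1]], a - qnorm(0.975) * se, tolerance = 1e-12)
  expect_equal(ci[[1]], 0.209, tolerance = 5e-3)
  expect_equal(ci[[2]], 1.0)  # clipped

  # perfect separation: upper bound clipped at 1
  ci2 <- auc_ci(c(rep(5, 40), rep(1, 60)), rep(c(TRUE, FALSE), c(40, 60)),
                method = "hanley_mcneil")
  expect_equal(ci2[[2]], 1.0)
})

test_that("DeLong SE agrees with the independent pROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  for (i in 1:5) {
    n <- 150
    outcomes <- c(TRUE, FALSE, runif(n - 2) < 0.3)
    scores <- rnorm(n) + outcomes
    ci <- auc_ci(scores, outcomes, method = "delong")
    ref <- pROC::roc(outcomes, scores, quiet = TRUE, direction = "<")
    expect_equal(attr(ci, "auc"), as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    expect_equal(attr(ci, "se")^2, as.numeric(pROC::var(ref, method = "delong")),
                 tolerance = 1e-10)
    ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
    expect_equal(ci[[1]], max(0, ref_ci[1]), tolerance = 1e-10)
    expect_equal(ci[[2]], min(1, ref_ci[3]), tolerance = 1e-10)
  }
})

test_that("DeLong and bootstrap intervals agree on a simulated cohort", {
  set.seed(55)
  n <- 500
  outcomes <- runif(n) < 0.3
  outcomes[1:2] <- c(TRUE, FALSE)
  scores <- rnorm(n) + 1.2 * outcomes
  dl <- auc_ci(scores, outcomes, method = "delong")
  bs <- auc_ci(scores, outcomes, method = "bootstrap", boot_reps = 10000,
               seed = 99)
  expect_lt(abs(dl[[1]] - bs[[1]]), 0.02)
  expect_lt(abs(dl[[2]] - bs[[2]]), 0.02)
  # seeded bootstrap is reproducible
  bs2 <- auc_ci(scores, outcomes, method = "bootstrap", boot_reps = 1000,
                seed = 7)
  bs3 <- auc_ci(scores, outcomes, method = "bootstrap", boot_reps = 1000,
                seed = 7)
  expect_identical(as.numeric(bs2), as.numeric(bs3))
  expect_error(auc_ci(c(1, 2), c(TRUE, FALSE), method = "bootstrap"),
               "at least 2")
})

test_that("CI-derived AUC comparison reproduces the closed form", {
  same <- compare_aucs_ci_method(0.8, c(0.75, 0.85), 0.8, c(0.75, 0.85))
  expect_equal(same$p.value, 1.0)

  # the two best-performing published scores
  cmp <- compare_aucs_ci_method(0.889, c(0.871, 0.907), 0.860, c(0.839, 0.881))
  expect_equal(unname(cmp$statistic), 2.055, tolerance = 1e-3)
  expect_equal(cmp$p.value, 0.040, tolerance = 1e-2)

  wide <- compare_aucs_ci_method(0.90, c(0.80, 1.00), 0.85, c(0.75, 0.95))
  expect_equal(unname(wide$statistic), 0.693, tolerance = 1e-3)
  expect_equal(wide$p.value, 0.49, tolerance = 1e-2)

  # symmetry in the arguments
  rev <- compare_aucs_ci_method(0.860, c(0.839, 0.881), 0.889, c(0.871, 0.907))
  expect_equal(rev$p.value, cmp$p.value, tolerance = 1e-12)
  expect_equal(unname(rev$statistic), -unname(cmp$statistic), tolerance = 1e-12)

  expect_error(compare_aucs_ci_method(0.9, c(0.7, 0.95), 0.8, c(0.75, 0.85)),
               "not symmetric")
})

test_that("p approaches 1 as the AUC difference vanishes", {
  p <- vapply(c(0.05, 0.02, 0.005, 0), function(d) {
    compare_aucs_ci_method(0.8 + d, c(0.75 + d, 0.85 + d),
                           0.8, c(0.75, 0.85))$p.value
  }, numeric(1))
  expect_true(all(diff(p) > 0))
  expect_equal(p[4], 1.0)
})

test_that("Youden cut-off equals brute-force argmax with low-threshold ties", {
  perfect <- roc_curve(c(10, 1), c(TRUE, FALSE))
  expect_equal(optimal_cutoff(perfect), 5.5)
  j <- perfect$sensitivity + perfect$specificity - 1
  expect_equal(max(j[is.finite(perfect$thresholds)]), 1)

  tie <- roc_curve(c(8, 9, 10, 1, 2, 9), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(optimal_cutoff(tie), 5.0)

  # integer scores separating between 8 and 9 report a half-point cut-off
  sep <- roc_curve(c(9, 10, 12, 3, 5, 8), rep(c(TRUE, FALSE), each = 3))
  expect_equal(optimal_cutoff(sep), 8.5)

  set.seed(404)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    scores <- sample(0:6, n, replace = TRUE)
    outcomes <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    curve <- roc_curve(scores, outcomes)
    # brute force over every finite threshold
    fin <- which(is.finite(curve$thresholds))
    j <- vapply(fin, function(k) {
      m <- classification_metrics(scores, outcomes, curve$thresholds[k])
      m$sensitivity + m$specificity - 1
    }, numeric(1))
    best <- curve$thresholds[fin][which.max(j)]
    expect_equal(optimal_cutoff(curve), best)
  }
})

test_that("classification metrics match hand confusion matrices", {
  perfect <- classification_metrics(c(9, 8, 2, 1), c(TRUE, TRUE, FALSE, FALSE), 5)
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))

  half <- classification_metrics(c(9, 3, 2, 8), c(TRUE, TRUE, FALSE, FALSE), 5)
  expect_equal(half$tp, 1); expect_equal(half$fn, 1)
  expect_equal(half$fp, 1); expect_equal(half$tn, 1)
  expect_equal(unlist(half[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 0.5, specificity = 0.5, ppv = 0.5, npv = 0.5))

  none <- classification_metrics(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE), 10)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)
  expect_true(is.na(none$ppv))

  # consistency identities on random thresholds
  set.seed(11)
  scores <- sample(0:10, 60, replace = TRUE)
  outcomes <- c(TRUE, FALSE, sample(c(TRUE, FALSE), 58, replace = TRUE))
  for (thr in c(-1, 0.5, 3.5, 7.5, 20)) {
    m <- classification_metrics(scores, outcomes, thr)
    expect_equal(m$tp + m$fp + m$tn + m$fn, 60)
    if (!is.na(m$sensitivity)) expect_equal(m$sensitivity * (m$tp + m$fn), m$tp)
    if (!is.na(m$specificity)) expect_equal(m$specificity * (m$tn + m$fp), m$tn)
  }
})

test_that("mt_validate reproduces hand metrics on the eight-patient fixture", {
  cohort <- make_cohort(
    make_record(hemoglobin_er = 6.5, base_excess_er = -11, sbp_er = 95,
                heart_rate_er = 125, fast_positive = TRUE, pelvis_ais = 5L,
                prbc_units_er_to_icu = 15L),
    make_record(hemoglobin_er = 8, sbp_er = 90, prbc_units_er_to_icu = 11L),
    make_record(hemoglobin_er = 9, base_excess_er = -7, prbc_units_er_to_icu = 4L),
    make_record(), make_record(), make_record(sex = "female"),
    make_record(hemoglobin_er = 12.5), make_record(heart_rate_er = 100))
  fit <- mt_validate(cohort, score_ids = "tash", cutoff_mode = "fixed",
                     fixed_cutoffs = c(tash = 5))
  scores <- tash_score(cohort)
  m <- classification_metrics(scores, derive_mt_outcome(cohort), 5)
  row <- fit$performance
  expect_equal(row$sensitivity, 100 * m$sensitivity)
  expect_equal(row$specificity, 100 * m$specificity)
  expect_equal(row$ppv, 100 * m$ppv)
  expect_equal(row$npv, 100 * m$npv)
  expect_equal(row$auc, auc(scores, derive_mt_outcome(cohort)))
  expect_equal(c(row$tp, row$fp, row$tn, row$fn), c(m$tp, m$fp, m$tn, m$fn))
  expect_error(mt_validate(cohort[4:8, ]), "both outcome classes")
})

test_that("mt_validate is deterministic and its methods run", {
  cohort <- generate_cohort(cohort_spec(n = 800, seed = 21))
  f1 <- mt_validate(cohort)
  f2 <- mt_validate(cohort)
  expect_equal(f1$performance, f2$performance)
  expect_true(all(f1$performance$ci_low <= f1$performance$auc))
  expect_true(all(f1$performance$auc <= f1$performance$ci_high))
  expect_output(print(f1), "Massive-transfusion score validation")
  expect_output(print(summary(f1)), "ranked by AUC")
  expect_s3_class(as.data.frame(f1), "data.frame")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(f1))
})
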