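#' Published performance of the six scores
#'
#' Reference values reported by the original multicenter registry validation
#' of these six scores (AUC, 95% CI, cut-off and classification metrics at
#' that cut-off, on a cohort of 5,147 severely injured patients). Shipped so
#' that derived quantities — e.g. the CI-based comparison of the two
#' best-performing scores — can be recomputed, and so synthetic-cohort
#' results can be set against the published ones.
#'
#' @return `data.frame` with columns `score`, `auc`, `ci_low`, `ci_high`,
#'   `cutoff`, `sensitivity`, `specificity`, `ppv`, `npv` (percent).
#' @export
published_performance <- function() {
  data.frame(
    score       = c("tash", "pwh", "vandromme", "larson", "schreiber", "abc"),
    auc         = c(0.889, 0.860, 0.840, 0.823, 0.800, 0.763),
    ci_low      = c(0.871, 0.839, 0.817, 0.800, 0.773, 0.732),
    ci_high     = c(0.907, 0.881, 0.863, 0.847, 0.828, 0.794),
    cutoff      = c(8.5, 2.5, 1.5, 1.5, 0.5, 0.5),
    sensitivity = c(84.4, 80.6, 78.9, 70.9, 85.8, 76.1),
    specificity = c(78.4, 77.7, 76.2, 80.4, 61.7, 70.3),
    ppv         = c(18.9, 17.7, 16.5, 17.4, 11.8, 13.2),
    npv         = c(98.8, 98.5, 98.4, 97.9, 98.7, 98.0),
    stringsAsFactors = FALSE)
}

#' Published cohort counts
#'
#' Patient counts reported by the original validation study and by the two
#' military derivation cohorts, from which prevalences and fractions can be
#' recomputed: registry patients screened and extracted, massive-transfusion
#' and blunt-trauma counts in the extract, and the MT counts of the
#' Schreiber and Larson derivation cohorts.
#'
#' @return Named list of integer counts.
#' @export
published_cohort_counts <- function() {
  list(
    screened = 56573L,
    extracted = 5147L,
    mt = 289L,
    blunt = 4889L,
    schreiber_derivation = c(mt = 247L, total = 558L),
    larson_derivation = c(mt = 420L, total = 1124L)
  )
}
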