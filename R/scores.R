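#' @title Massive-transfusion prediction scores
#' @description Six early MT risk scores implemented as declarative banded
#'   component tables evaluated by one generic engine. Within a component the
#'   bands are ordered most-severe first and the first matching band's points
#'   apply; component points are summed, except the TASH fracture block where
#'   the pelvis and femur contributions compete and only the larger counts.
#' @name mt-scores
NULL

# A band is list(op, value, points); op one of lt/le/gt/ge/flag/is.
# `flag` tests a logical input; `is` tests equality against a string level.
.band <- function(op, value, points) list(op = op, value = value, points = points)

.component <- function(name, variable, bands, group = NA_character_) {
  list(name = name, variable = variable, bands = bands, group = group)
}

.SCORE_DEFS <- list(
  tash = list(
    score_id = "tash", label = "TASH",
    max_points = 28L, default_cutoff = 8.5,
    components = list(
      .component("male_sex", "male", list(.band("flag", TRUE, 1L))),
      .component("hemoglobin", "hemoglobin_er", list(
        .band("lt", 7, 8L), .band("lt", 9, 6L), .band("lt", 10, 4L),
        .band("lt", 11, 3L), .band("lt", 12, 2L))),
      .component("base_excess", "base_excess_er", list(
        .band("lt", -10, 4L), .band("lt", -6, 3L), .band("lt", -2, 1L))),
      .component("sbp", "sbp_er", list(
        .band("lt", 100, 4L), .band("lt", 120, 1L))),
      .component("heart_rate", "heart_rate_er", list(.band("gt", 120, 2L))),
      .component("fast", "fast_positive", list(.band("flag", TRUE, 3L))),
      # unstable pelvis and severe femur fracture compete: max, not sum,
      # so the score tops out at the published 28 points
      .component("pelvis_fracture", "pelvis_ais", list(.band("ge", 5, 6L)),
                 group = "fracture"),
      .component("femur_fracture", "femur_ais", list(.band("ge", 3, 3L)),
                 group = "fracture")
    ),
    group_aggregation = c(fracture = "max")
  ),
  pwh = list(
    score_id = "pwh", label = "PWH (Rainer)",
    max_points = 19L, default_cutoff = 2.5,
    components = list(
      .component("heart_rate", "heart_rate_er", list(.band("ge", 120, 1L))),
      .component("sbp", "sbp_er", list(.band("le", 90, 3L))),
      .component("gcs", "gcs", list(.band("le", 8, 1L))),
      .component("pelvis_fracture", "pelvis_ais", list(.band("ge", 4, 1L))),
      .component("free_fluid", "free_fluid", list(.band("flag", TRUE, 2L))),
      # base deficit > 5 mmol/l, i.e. base excess below -5
      .component("base_deficit", "base_excess_er", list(.band("lt", -5, 1L))),
      # published bands "<= 7" and "7.1 to 10" leave (7.0, 7.1) unassigned;
      # the gap goes to the severe band to keep the score monotone in Hb
      .component("hemoglobin", "hemoglobin_er", list(
        .band("lt", 7.1, 10L), .band("le", 10, 1L)))
    ),
    group_aggregation = NULL
  ),
  vandromme = list(
    score_id = "vandromme", label = "Vandromme",
    max_points = 5L, default_cutoff = 1.5,
    components = list(
      .component("lactate", "lactate_er", list(.band("ge", 5, 1L))),
      .component("heart_rate", "heart_rate_er", list(.band("gt", 105, 1L))),
      .component("inr", "inr_er", list(.band("gt", 1.5, 1L))),
      .component("hemoglobin", "hemoglobin_er", list(.band("le", 11, 1L))),
      .component("sbp", "sbp_er", list(.band("lt", 110, 1L)))
    ),
    group_aggregation = NULL
  ),
  abc = list(
    score_id = "abc", label = "ABC (Nunez)",
    max_points = 4L, default_cutoff = 0.5,
    components = list(
      .component("mechanism", "penetrating", list(.band("flag", TRUE, 1L))),
      .component("sbp", "sbp_er", list(.band("le", 90, 1L))),
      .component("heart_rate", "heart_rate_er", list(.band("ge", 120, 1L))),
      .component("fast", "fast_positive", list(.band("flag", TRUE, 1L)))
    ),
    group_aggregation = NULL
  ),
  schreiber = list(
    score_id = "schreiber", label = "Schreiber",
    max_points = 3L, default_cutoff = 0.5,
    components = list(
      .component("hemoglobin", "hemoglobin_er", list(.band("le", 11, 1L))),
      .component("inr", "inr_er", list(.band("gt", 1.5, 1L))),
      .component("mechanism", "penetrating", list(.band("flag", TRUE, 1L)))
    ),
    group_aggregation = NULL
  ),
  larson = list(
    score_id = "larson", label = "Larson",
    max_points = 4L, default_cutoff = 1.5,
    components = list(
      .component("heart_rate", "heart_rate_er", list(.band("gt", 110, 1L))),
      .component("sbp", "sbp_er", list(.band("lt", 110, 1L))),
      .component("hemoglobin", "hemoglobin_er", list(.band("lt", 11, 1L))),
      .component("base_excess", "base_excess_er", list(.band("le", -6, 1L)))
    ),
    group_aggregation = NULL
  )
)

#' Identifiers of the implemented scores
#' @return `c("tash", "pwh", "vandromme", "abc", "schreiber", "larson")`
#' @export
mt_score_ids <- function() names(.SCORE_DEFS)

#' Declarative score definitions
#'
#' Returns the banded component tables driving every score, so callers (and
#' tests) can enumerate bands mechanically. Each definition carries
#' `score_id`, `label`, `max_points`, `default_cutoff` (the published
#' half-point cut-off), `components` and `group_aggregation`.
#'
#' @param score_ids Which definitions to return (default all six).
#' @return Named list of score definitions.
#' @export
score_definitions <- function(score_ids = mt_score_ids()) {
  unknown <- setdiff(score_ids, names(.SCORE_DEFS))
  if (length(unknown)) {
    stop("unknown score id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  .SCORE_DEFS[score_ids]
}

#' Published default cut-offs
#' @return Named numeric vector of the reported half-point cut-offs.
#' @export
default_cutoffs <- function() {
  vapply(.SCORE_DEFS, function(d) d$default_cutoff, numeric(1))
}

# Derived inputs shared across scores. `records` is a cohort data.frame.
.score_inputs <- function(records) {
  list(
    male           = ifelse(is.na(records$sex), NA, records$sex == "male"),
    penetrating    = ifelse(is.na(records$mechanism), NA,
                            records$mechanism == "penetrating"),
    free_fluid     = ifelse(is.na(records$ct_free_fluid) | is.na(records$fast_positive),
                            NA, records$ct_free_fluid | records$fast_positive),
    heart_rate_er  = records$heart_rate_er,
    sbp_er         = records$sbp_er,
    hemoglobin_er  = records$hemoglobin_er,
    base_excess_er = records$base_excess_er,
    lactate_er     = records$lactate_er,
    inr_er         = records$inr_er,
    gcs            = records$gcs,
    fast_positive  = records$fast_positive,
    pelvis_ais     = records$pelvis_ais,
    femur_ais      = records$femur_ais
  )
}

.band_matches <- function(band, x) {
  switch(band$op,
    lt   = x <  band$value,
    le   = x <= band$value,
    gt   = x >  band$value,
    ge   = x >= band$value,
    flag = x %in% TRUE,
    is   = x == band$value,
    stop("unknown band operator: ", band$op))
}

# Points contributed by one component for a vector of input values;
# first matching band wins.
.component_points <- function(comp, x) {
  pts <- integer(length(x))
  unassigned <- rep(TRUE, length(x))
  for (band in comp$bands) {
    hit <- unassigned & .band_matches(band, x)
    hit[is.na(hit)] <- FALSE
    pts[hit] <- band$points
    unassigned <- unassigned & !hit
  }
  pts
}

.evaluate_score <- function(def, records) {
  inputs <- .score_inputs(records)
  n <- nrow(records)
  # missing-field check over the variables this score reads
  for (comp in def$components) {
    x <- inputs[[comp$variable]]
    if (any(is.na(x))) {
      stop(sprintf("score '%s': required input '%s' missing for %d record(s)",
                   def$score_id, comp$variable, sum(is.na(x))), call. = FALSE)
    }
  }
  total <- integer(n)
  group_pts <- list()
  for (comp in def$components) {
    pts <- .component_points(comp, inputs[[comp$variable]])
    if (is.na(comp$group)) {
      total <- total + pts
    } else {
      group_pts[[comp$group]] <- c(group_pts[[comp$group]], list(pts))
    }
  }
  for (grp in names(group_pts)) {
    agg <- def$group_aggregation[[grp]]
    if (!identical(agg, "max")) stop("unsupported group aggregation: ", agg)
    total <- total + Reduce(pmax, group_pts[[grp]])
  }
  as.integer(total)
}

.coerce_records <- function(records) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- as.data.frame(records, stringsAsFactors = FALSE)
  }
  records
}

#' TASH score (0--28)
#'
#' Weighted seven-variable score: sex, haemoglobin, base excess, systolic
#' blood pressure, heart rate, sonographic free fluid, and pelvic/femur
#' fractures (the fracture block contributes the larger of its two parts).
#'
#' @param records Cohort `data.frame` (any number of rows).
#' @return Integer vector of scores in `[0, 28]`.
#' @export
tash_score <- function(records) {
  .evaluate_score(.SCORE_DEFS$tash, .coerce_records(records))
}

#' TASH probability transform
#'
#' Maps a TASH score to a massive-transfusion probability via the published
#' logistic transform `p = 1 / (1 + exp(5.4 - 0.3 * score))`; a score of 18
#' maps to exactly 0.5.
#'
#' @param score Numeric vector of TASH scores.
#' @return Probabilities in (0, 1).
#' @export
tash_probability <- function(score) {
  # algebraically 0.3 * score - 5.4; centred at 18 so the midpoint is exact
  stats::plogis(0.3 * (score - 18))
}

#' PWH/Rainer score (0--19)
#'
#' Weighted score: heart rate >= 120, systolic BP <= 90, GCS <= 8, displaced
#' pelvic fracture (AIS >= 4), CT- or FAST-positive free fluid, base deficit
#' > 5 mmol/l, and banded haemoglobin.
#'
#' @inheritParams tash_score
#' @return Integer vector of scores in `[0, 19]`.
#' @export
pwh_score <- function(records) {
  .evaluate_score(.SCORE_DEFS$pwh, .coerce_records(records))
}

#' Vandromme score (0--5)
#'
#' One point each for lactate >= 5 mmol/l, heart rate > 105, INR > 1.5,
#' haemoglobin <= 11 g/dl, systolic BP < 110 mmHg.
#'
#' @inheritParams tash_score
#' @return Integer vector of scores in `[0, 5]`.
#' @export
vandromme_score <- function(records) {
  .evaluate_score(.SCORE_DEFS$vandromme, .coerce_records(records))
}

#' ABC score (0--4)
#'
#' One point each for penetrating mechanism, systolic BP <= 90, heart rate
#' >= 120, positive FAST.
#'
#' @inheritParams tash_score
#' @return Integer vector of scores in `[0, 4]`.
#' @export
abc_score <- function(records) {
  .evaluate_score(.SCORE_DEFS$abc, .coerce_records(records))
}

#' Schreiber score (0--3)
#'
#' One point each for haemoglobin <= 11 g/dl, INR > 1.5, penetrating
#' mechanism.
#'
#' @inheritParams tash_score
#' @return Integer vector of scores in `[0, 3]`.
#' @export
schreiber_score <- function(records) {
  .evaluate_score(.SCORE_DEFS$schreiber, .coerce_records(records))
}

#' Larson score (0--4)
#'
#' One point each for heart rate > 110, systolic BP < 110, haemoglobin
#' < 11 g/dl, base excess <= -6 mmol/l.
#'
#' @inheritParams tash_score
#' @return Integer vector of scores in `[0, 4]`.
#' @export
larson_score <- function(records) {
  .evaluate_score(.SCORE_DEFS$larson, .coerce_records(records))
}

#' Score a cohort
#'
#' Applies the requested scores to every record and attaches the
#' massive-transfusion outcome. Records must already be filtered complete for
#' the requested scores ([apply_eligibility_filters()]).
#'
#' @param records Cohort `data.frame`.
#' @param score_ids Scores to compute (default all six).
#' @return `data.frame` with `patient_id`, one integer column per score,
#'   `tash_probability` when TASH is requested, and logical `mt_outcome`.
#' @export
score_cohort <- function(records, score_ids = mt_score_ids()) {
  records <- .coerce_records(records)
  defs <- score_definitions(score_ids)
  out <- data.frame(patient_id = records$patient_id %||% character(0),
                    stringsAsFactors = FALSE)
  if (nrow(records) == 0) {
    for (id in score_ids) out[[id]] <- integer(0)
    if ("tash" %in% score_ids) out$tash_probability <- numeric(0)
    out$mt_outcome <- logical(0)
    return(out[c("patient_id", score_ids,
                 if ("tash" %in% score_ids) "tash_probability", "mt_outcome")])
  }
  for (id in score_ids) out[[id]] <- .evaluate_score(defs[[id]], records)
  if ("tash" %in% score_ids) out$tash_probability <- tash_probability(out$tash)
  out$mt_outcome <- derive_mt_outcome(records)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Input variables required by a set of scores
#'
#' Union of the cohort columns each requested score reads, with derived
#' inputs mapped back to their source columns (`male` to `sex`,
#' `penetrating` to `mechanism`, `free_fluid` to both imaging flags).
#'
#' @param score_ids Scores of interest (default all six).
#' @return Character vector of cohort column names.
#' @export
score_required_fields <- function(score_ids = mt_score_ids()) {
  defs <- score_definitions(score_ids)
  vars <- unique(unlist(lapply(defs, function(d)
    vapply(d$components, function(c) c$variable, character(1)))))
  map <- list(male = "sex", penetrating = "mechanism",
              free_fluid = c("ct_free_fluid", "fast_positive"))
  unique(unlist(lapply(vars, function(v) map[[v]] %||% v)))
}
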