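# Fixture builders: a physiologically unremarkable adult with every score
# component silent (apart from TASH's male point), overridable per field.
make_record <- function(...) {
  rec <- data.frame(
    patient_id = "X1", age = 40L, sex = "male", mechanism = "blunt",
    primary_admission = TRUE, survived_to_icu = TRUE,
    heart_rate_er = 80, sbp_er = 130, hemoglobin_er = 13,
    base_excess_er = 0, lactate_er = 1.5, inr_er = 1.0, quick_er = 95,
    gcs = 15L, fast_positive = FALSE, ct_free_fluid = FALSE,
    pelvis_ais = 0L, femur_ais = 0L, prbc_units_er_to_icu = 0L,
    hemostatic_agents = FALSE, iss = 9L,
    stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) rec[[nm]] <- mods[[nm]]
  rec
}

make_cohort <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, rows)
  out$patient_id <- sprintf("X%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

# Independent band matcher (oracle-side twin of the engine's comparators).
match_band <- function(op, value, x) {
  switch(op, lt = x < value, le = x <= value, gt = x > value,
         ge = x >= value, flag = isTRUE(x))
}

# For one component, a representative input value per band (matching that
# band and none of the more severe ones) plus one value matching no band.
band_representatives <- function(comp) {
  if (comp$bands[[1]]$op == "flag") {
    return(list(values = list(TRUE, FALSE),
                points = c(comp$bands[[1]]$points, 0L)))
  }
  thresholds <- vapply(comp$bands, `[[`, numeric(1), "value")
  candidates <- sort(unique(c(thresholds - 0.05, thresholds, thresholds + 0.05,
                              thresholds - 1, thresholds + 1,
                              min(thresholds) - 10, max(thresholds) + 10)))
  values <- list(); points <- integer()
  for (k in seq_along(comp$bands)) {
    ok <- vapply(candidates, function(x) {
      earlier <- if (k > 1) {
        any(vapply(comp$bands[seq_len(k - 1)], function(b)
          match_band(b$op, b$value, x), logical(1)))
      } else FALSE
      !earlier && match_band(comp$bands[[k]]$op, comp$bands[[k]]$value, x)
    }, logical(1))
    stopifnot(any(ok))
    values <- c(values, candidates[which(ok)[1]])
    points <- c(points, comp$bands[[k]]$points)
  }
  none <- vapply(candidates, function(x)
    !any(vapply(comp$bands, function(b) match_band(b$op, b$value, x),
                logical(1))), logical(1))
  stopifnot(any(none))
  list(values = c(values, candidates[which(none)[1]]), points = c(points, 0L))
}

# Write a representative input into a record, mapping derived flags back to
# their source columns.
set_score_input <- function(rec, variable, value) {
  if (variable == "male") {
    rec$sex <- if (isTRUE(value)) "male" else "female"
  } else if (variable == "penetrating") {
    rec$mechanism <- if (isTRUE(value)) "penetrating" else "blunt"
  } else if (variable == "free_fluid") {
    rec$ct_free_fluid <- isTRUE(value); rec$fast_positive <- FALSE
  } else {
    rec[[variable]] <- value
  }
  rec
}

# Exhaustive enumeration of one representative input per band combination:
# a cohort data.frame plus the expected score of every row, computed from
# the declarative tables with the group-max aggregation applied.
enumerate_score_bands <- function(def) {
  reps <- lapply(def$components, band_representatives)
  grid <- expand.grid(lapply(reps, function(r) seq_along(r$points)))
  records <- vector("list", nrow(grid))
  expected <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    rec <- make_record()
    total <- 0L
    group_pts <- list()
    for (j in seq_along(def$components)) {
      comp <- def$components[[j]]
      choice <- grid[i, j]
      rec <- set_score_input(rec, comp$variable, reps[[j]]$values[[choice]])
      pts <- reps[[j]]$points[choice]
      if (is.na(comp$group)) total <- total + pts
      else group_pts[[comp$group]] <- c(group_pts[[comp$group]], pts)
    }
    for (grp in names(group_pts)) total <- total + max(group_pts[[grp]])
    records[[i]] <- rec
    expected[i] <- total
  }
  cohort <- do.call(rbind, records)
  cohort$patient_id <- sprintf("E%05d", seq_len(nrow(cohort)))
  list(records = cohort, expected = expected)
}

score_fun <- function(id) {
  switch(id, tash = tash_score, pwh = pwh_score, vandromme = vandromme_score,
         abc = abc_score, schreiber = schreiber_score, larson = larson_score)
}

# Brute-force AUC by pairwise comparison of every case/control pair.
auc_pairwise <- function(scores, outcomes) {
  cases <- scores[outcomes]; controls <- scores[!outcomes]
  total <- 0
  for (x in cases) total <- total + sum(x > controls) + 0.5 * sum(x == controls)
  total / (length(cases) * length(controls))
}
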