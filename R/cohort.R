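#' @title Trauma cohort data model and I/O
#' @description Column schema, CSV reader/writer, massive-transfusion outcome
#'   derivation and study eligibility filters for registry-style trauma
#'   cohorts. One row per patient; missing values are empty CSV fields.
#' @name cohort-model
NULL

# Column schema: name -> storage type. Order is the canonical CSV header.
.COHORT_COLUMNS <- c(
  patient_id           = "character",
  age                  = "integer",
  sex                  = "sex",
  mechanism            = "mechanism",
  primary_admission    = "logical",
  survived_to_icu      = "logical",
  heart_rate_er        = "numeric",
  sbp_er               = "numeric",
  hemoglobin_er        = "numeric",
  base_excess_er       = "numeric",
  lactate_er           = "numeric",
  inr_er               = "numeric",
  quick_er             = "numeric",
  gcs                  = "integer",
  fast_positive        = "logical",
  ct_free_fluid        = "logical",
  pelvis_ais           = "integer",
  femur_ais            = "integer",
  prbc_units_er_to_icu = "integer",
  hemostatic_agents    = "logical",
  iss                  = "integer"
)

# Range constraints checked (when the value is present) by strict reading.
.COHORT_RANGES <- list(
  age                  = c(0, Inf),
  heart_rate_er        = c(0, Inf),
  sbp_er               = c(0, Inf),
  hemoglobin_er        = c(0, Inf),
  base_excess_er       = c(-Inf, Inf),
  lactate_er           = c(0, Inf),
  inr_er               = c(1e-8, Inf),
  quick_er             = c(1e-8, 150),
  gcs                  = c(3, 15),
  pelvis_ais           = c(0, 6),
  femur_ais            = c(0, 6),
  prbc_units_er_to_icu = c(0, Inf),
  iss                  = c(0, 75)
)

#' Canonical cohort column names
#'
#' @return Character vector of the cohort CSV header, in order.
#' @export
cohort_columns <- function() names(.COHORT_COLUMNS)

.parse_logical <- function(x, column) {
  out <- rep(NA, length(x))
  out[!is.na(x) & x == "true"] <- TRUE
  out[!is.na(x) & x == "false"] <- FALSE
  bad <- !is.na(x) & !(x %in% c("true", "false"))
  if (any(bad)) {
    stop(sprintf("column '%s': unparsable boolean '%s' at data row %d (expected true/false)",
                 column, x[which(bad)[1]], which(bad)[1]), call. = FALSE)
  }
  out
}

.parse_enum <- function(x, column, levels) {
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    stop(sprintf("column '%s': unparsable value '%s' at data row %d (expected %s)",
                 column, x[which(bad)[1]], which(bad)[1],
                 paste(levels, collapse = "/")), call. = FALSE)
  }
  x
}

.parse_numeric <- function(x, column, integer = FALSE) {
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop(sprintf("column '%s': unparsable number '%s' at data row %d",
                 column, x[which(bad)[1]], which(bad)[1]), call. = FALSE)
  }
  if (integer) out <- as.integer(round(out))
  out
}

#' Read a trauma cohort CSV
#'
#' Reads a cohort file in the canonical schema (see [cohort_columns()]).
#' Empty fields become `NA`. With `strict = TRUE` any value outside its
#' physiological range aborts with a message naming the column and data row.
#'
#' @param path Path to a CSV file with the canonical header.
#' @param strict Logical; abort on range violations (default `FALSE`).
#' @return A `data.frame` with one row per patient, typed per the schema.
#' @export
read_cohort <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", na.strings = "",
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(raw), cohort_columns())) {
    missing <- setdiff(cohort_columns(), names(raw))
    extra <- setdiff(names(raw), cohort_columns())
    stop("cohort schema mismatch",
         if (length(missing)) paste0("; missing columns: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected columns: ", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  out <- raw
  for (col in cohort_columns()) {
    type <- .COHORT_COLUMNS[[col]]
    out[[col]] <- switch(type,
      character = raw[[col]],
      logical   = .parse_logical(raw[[col]], col),
      sex       = .parse_enum(raw[[col]], col, c("male", "female")),
      mechanism = .parse_enum(raw[[col]], col, c("blunt", "penetrating")),
      numeric   = .parse_numeric(raw[[col]], col),
      integer   = .parse_numeric(raw[[col]], col, integer = TRUE)
    )
  }
  if (strict) .check_ranges(out)
  out
}

.check_ranges <- function(records) {
  for (col in names(.COHORT_RANGES)) {
    rng <- .COHORT_RANGES[[col]]
    x <- records[[col]]
    bad <- !is.na(x) & (x < rng[1] | x > rng[2])
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("column '%s': value %s at data row %d outside allowed range [%s, %s]",
                   col, format(x[i]), i, format(rng[1]), format(rng[2])), call. = FALSE)
    }
  }
  invisible(records)
}

.format_cell <- function(x, type) {
  out <- switch(type,
    character = as.character(x),
    logical   = ifelse(x, "true", "false"),
    sex       = as.character(x),
    mechanism = as.character(x),
    numeric   = vapply(x, function(v) if (is.na(v)) NA_character_ else
                         format(v, digits = 15, trim = TRUE, scientific = FALSE),
                       character(1)),
    integer   = vapply(x, function(v) if (is.na(v)) NA_character_ else
                         format(as.integer(v)), character(1))
  )
  out[is.na(x)] <- ""
  out
}

#' Write a trauma cohort CSV
#'
#' Inverse of [read_cohort()]: writes the canonical schema with booleans as
#' `true`/`false` and missing values as empty fields, so that
#' `read_cohort(write_cohort(x))` reproduces `x` exactly, including its
#' missingness pattern.
#'
#' @param records Cohort `data.frame` (canonical columns).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(records, path) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(cohort_columns(), names(records))
  if (length(missing)) {
    stop("records lack required columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  cells <- lapply(cohort_columns(), function(col)
    .format_cell(records[[col]], .COHORT_COLUMNS[[col]]))
  lines <- c(paste(cohort_columns(), collapse = ","),
             if (nrow(records) > 0)
               do.call(paste, c(cells, sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Derive the massive-transfusion outcome
#'
#' A patient counts as massively transfused when 10 or more units of packed
#' red blood cells were given between emergency-room arrival and ICU
#' admission (boundary inclusive).
#'
#' @param records Cohort `data.frame`, or a numeric vector of pRBC unit counts.
#' @return Logical vector, `TRUE` where pRBC units are >= 10.
#' @export
derive_mt_outcome <- function(records) {
  units <- if (is.data.frame(records)) records$prbc_units_er_to_icu else records
  if (any(is.na(units))) {
    stop("massive-transfusion outcome undefined: pRBC unit count missing for ",
         sum(is.na(units)), " record(s); apply eligibility filters first",
         call. = FALSE)
  }
  units >= 10
}

# Ordered eligibility rules. Each predicate returns TRUE for records that PASS.
.FILTER_RULES <- list(
  age               = function(r, fields) !is.na(r$age) & r$age >= 18,
  primary_admission = function(r, fields) !is.na(r$primary_admission) & r$primary_admission,
  icu_survival      = function(r, fields) !is.na(r$survived_to_icu) & r$survived_to_icu,
  prbc_missing      = function(r, fields) !is.na(r$prbc_units_er_to_icu),
  hemostatic_agents = function(r, fields) !is.na(r$hemostatic_agents) & !r$hemostatic_agents,
  completeness      = function(r, fields) {
    ok <- rep(TRUE, nrow(r))
    for (f in fields) ok <- ok & !is.na(r[[f]])
    ok
  }
)

#' Apply the study eligibility filters
#'
#' Retains adult (age >= 18), primary-admitted patients who survived to ICU
#' admission, whose pRBC count is known, who received no hemostatic agents,
#' and who have complete data for every variable required by the requested
#' scores. Rules are applied in that fixed order; each removal is attributed
#' to the first rule a record fails.
#'
#' @param records Cohort `data.frame`.
#' @param score_ids Scores whose input variables define the complete-case
#'   rule; default all six. Pass a subset for per-score complete-case
#'   filtering.
#' @return A list with elements `records` (the retained rows) and `report`
#'   (a `mt_filter_report`: rule names, per-rule removal counts, input and
#'   output counts).
#' @export
apply_eligibility_filters <- function(records, score_ids = mt_score_ids()) {
  stopifnot(is.data.frame(records))
  fields <- score_required_fields(score_ids)
  input_count <- nrow(records)
  removed <- integer(length(.FILTER_RULES))
  names(removed) <- names(.FILTER_RULES)
  kept <- records
  for (rule in names(.FILTER_RULES)) {
    if (nrow(kept) == 0) break
    pass <- .FILTER_RULES[[rule]](kept, fields)
    removed[[rule]] <- sum(!pass)
    kept <- kept[pass, , drop = FALSE]
  }
  rownames(kept) <- NULL
  report <- structure(
    list(input_count = input_count,
         removed = removed,
         output_count = nrow(kept)),
    class = "mt_filter_report")
  list(records = kept, report = report)
}

#' @export
print.mt_filter_report <- function(x, ...) {
  cat("Eligibility filter report\n")
  cat("  input records: ", x$input_count, "\n", sep = "")
  for (rule in names(x$removed)) {
    cat(sprintf("  removed by %-18s %d\n", paste0(rule, ":"), x$removed[[rule]]))
  }
  cat("  retained:      ", x$output_count, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.mt_filter_report <- function(x, ...) {
  data.frame(rule = names(x$removed), removed = unname(x$removed),
             stringsAsFactors = FALSE)
}

.SUMMARY_CONTINUOUS <- c("age", "iss", "heart_rate_er", "sbp_er", "hemoglobin_er",
                         "base_excess_er", "lactate_er", "inr_er", "quick_er",
                         "prbc_units_er_to_icu")

#' Descriptive cohort summary
#'
#' Mean, SD, median and interquartile range for each continuous variable and
#' count/percent for each categorical one, in the layout customary for a
#' study's baseline-characteristics table.
#'
#' @param records Cohort `data.frame` with at least one row.
#' @return An object of class `mt_cohort_summary`: a list with data frames
#'   `continuous` and `categorical`.
#' @export
summarize_cohort <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) stop("cannot summarize an empty cohort", call. = FALSE)
  cont <- do.call(rbind, lapply(.SUMMARY_CONTINUOUS, function(col) {
    x <- records[[col]][!is.na(records[[col]])]
    if (length(x) == 0) {
      return(data.frame(variable = col, mean = NA_real_, sd = NA_real_,
                        median = NA_real_, q25 = NA_real_, q75 = NA_real_,
                        n = 0L, stringsAsFactors = FALSE))
    }
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(variable = col, mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else 0,
               median = q[2], q25 = q[1], q75 = q[3],
               n = length(x), stringsAsFactors = FALSE)
  }))
  cat_spec <- list(
    sex_male          = !is.na(records$sex) & records$sex == "male",
    mechanism_blunt   = !is.na(records$mechanism) & records$mechanism == "blunt",
    fast_positive     = !is.na(records$fast_positive) & records$fast_positive,
    ct_free_fluid     = !is.na(records$ct_free_fluid) & records$ct_free_fluid,
    hemostatic_agents = !is.na(records$hemostatic_agents) & records$hemostatic_agents,
    massive_transfusion = !is.na(records$prbc_units_er_to_icu) &
      records$prbc_units_er_to_icu >= 10
  )
  cat_valid <- list(
    sex_male = records$sex, mechanism_blunt = records$mechanism,
    fast_positive = records$fast_positive, ct_free_fluid = records$ct_free_fluid,
    hemostatic_agents = records$hemostatic_agents,
    massive_transfusion = records$prbc_units_er_to_icu
  )
  catg <- do.call(rbind, lapply(names(cat_spec), function(nm) {
    valid <- sum(!is.na(cat_valid[[nm]]))
    cnt <- sum(cat_spec[[nm]])
    data.frame(variable = nm, count = cnt,
               percent = if (valid > 0) 100 * cnt / valid else NA_real_,
               n = valid, stringsAsFactors = FALSE)
  }))
  structure(list(continuous = cont, categorical = catg, n = nrow(records)),
            class = "mt_cohort_summary")
}

#' @export
print.mt_cohort_summary <- function(x, digits = 3, ...) {
  cat("Cohort summary (n = ", x$n, ")\n\nContinuous variables:\n", sep = "")
  print(format(x$continuous, digits = digits), row.names = FALSE)
  cat("\nCategorical variables:\n")
  print(format(x$categorical, digits = digits), row.names = FALSE)
  invisible(x)
}
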