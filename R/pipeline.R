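#' @title End-to-end pipeline commands
#' @description File-level drivers composing the package's stages — generate,
#'   filter, score, validate — with a resolved-configuration record alongside
#'   every output so reruns with the same configuration are byte-identical.
#'   These functions back the `mtbench` command-line script
#'   (`system.file("cli", "mtbench.R", package = "mtbench")`).
#' @name pipeline
NULL

.write_config <- function(config, path) {
  config$mtbench_version <- as.character(utils::packageVersion("mtbench"))
  keys <- sort(names(config))
  vals <- vapply(config, function(v) paste(format(v, trim = TRUE, digits = 15,
                                                  scientific = FALSE),
                                           collapse = ","), character(1))
  writeLines(paste0(keys, "=", vals[keys]), path)
  invisible(path)
}

#' Read a flat key=value configuration file
#'
#' @param path Path to a text file with one `key=value` pair per line; blank
#'   lines and lines starting with `#` are ignored.
#' @return Named list of character values.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]], call. = FALSE)
  stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, character(1), 1))
}

.write_table <- function(df, path) {
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a cohort CSV
#'
#' Wraps [generate_cohort()]: builds a spec from the arguments, writes
#' `cohort.csv` and the resolved configuration into `out_dir`.
#'
#' @param out_dir Output directory (created if absent).
#' @param n,seed,prevalence Generator size, seed and target MT prevalence.
#' @param ... Further arguments forwarded to [cohort_spec()].
#' @return Invisibly, the path of the written cohort CSV.
#' @export
cmd_generate <- function(out_dir, n = 5000, seed = 1L, prevalence = 0.056, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- cohort_spec(n = n, seed = seed, target_prevalence = prevalence, ...)
  cohort <- generate_cohort(spec)
  path <- file.path(out_dir, "cohort.csv")
  write_cohort(cohort, path)
  .write_config(list(command = "generate", n = n, seed = seed,
                     prevalence = prevalence),
                file.path(out_dir, "config_generate.txt"))
  invisible(path)
}

#' Filter and score a cohort CSV
#'
#' Reads a cohort, applies the eligibility filters, scores the retained
#' records and writes `scores.csv` plus `filter_report.csv`.
#'
#' @param input Path to a cohort CSV.
#' @param out_dir Output directory (created if absent).
#' @param score_ids Scores to compute.
#' @return Invisibly, the path of the written score matrix.
#' @export
cmd_score <- function(input, out_dir, score_ids = mt_score_ids()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- read_cohort(input)
  filtered <- apply_eligibility_filters(cohort, score_ids)
  if (nrow(filtered$records) == 0) {
    warning("no eligible records after filtering; writing header-only score matrix",
            call. = FALSE)
  }
  scores <- score_cohort(filtered$records, score_ids)
  path <- file.path(out_dir, "scores.csv")
  .write_table(scores, path)
  .write_table(as.data.frame(filtered$report),
               file.path(out_dir, "filter_report.csv"))
  .write_config(list(command = "score", input = input,
                     scores = paste(score_ids, collapse = ",")),
                file.path(out_dir, "config_score.txt"))
  invisible(path)
}

#' Validate scores on a cohort CSV
#'
#' Reads a cohort, applies the eligibility filters, runs [mt_validate()] and
#' writes the performance table (CSV and JSON), per-score ROC coordinates and
#' the filter report.
#'
#' @param input Path to a cohort CSV.
#' @param out_dir Output directory (created if absent).
#' @param score_ids Scores to validate.
#' @param cutoff_mode `"youden"` or `"fixed"` (the published cut-offs).
#' @param ci_method CI method for the AUC (see [auc_ci()]).
#' @param seed Seed for the bootstrap CI, if selected.
#' @return Invisibly, the `mt_validation` object.
#' @export
cmd_validate <- function(input, out_dir, score_ids = mt_score_ids(),
                         cutoff_mode = "youden", ci_method = "delong",
                         seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- read_cohort(input)
  filtered <- apply_eligibility_filters(cohort, score_ids)
  fit <- mt_validate(filtered$records, score_ids = score_ids,
                     cutoff_mode = cutoff_mode, ci_method = ci_method,
                     seed = seed)
  .write_table(fit$performance, file.path(out_dir, "performance.csv"))
  jsonlite::write_json(fit$performance, file.path(out_dir, "performance.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  for (id in names(fit$roc)) {
    .write_table(as.data.frame(fit$roc[[id]]),
                 file.path(out_dir, sprintf("roc_%s.csv", id)))
  }
  .write_table(as.data.frame(filtered$report),
               file.path(out_dir, "filter_report.csv"))
  .write_config(list(command = "validate", input = input,
                     scores = paste(score_ids, collapse = ","),
                     cutoff_mode = cutoff_mode, ci_method = ci_method,
                     seed = seed),
                file.path(out_dir, "config_validate.txt"))
  invisible(fit)
}

#' Run the full pipeline
#'
#' Generate, filter, score, validate and summarize in one call, writing every
#' artifact (cohort, filter report, score matrix, baseline summary,
#' performance table, ROC coordinates, resolved configuration) into
#' `out_dir`. Reruns with the same configuration are byte-identical.
#'
#' @inheritParams cmd_generate
#' @inheritParams cmd_validate
#' @param n,seed,prevalence Generator controls.
#' @param ... Further arguments forwarded to [cohort_spec()].
#' @return Invisibly, the `mt_validation` object.
#' @export
cmd_run <- function(out_dir, n = 5000, seed = 1L, prevalence = 0.056,
                    score_ids = mt_score_ids(), cutoff_mode = "youden",
                    ci_method = "delong", ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- cohort_spec(n = n, seed = seed, target_prevalence = prevalence, ...)
  cohort <- generate_cohort(spec)
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  filtered <- apply_eligibility_filters(cohort, score_ids)
  .write_table(as.data.frame(filtered$report),
               file.path(out_dir, "filter_report.csv"))
  scores <- score_cohort(filtered$records, score_ids)
  .write_table(scores, file.path(out_dir, "scores.csv"))
  summ <- summarize_cohort(filtered$records)
  .write_table(summ$continuous, file.path(out_dir, "cohort_summary_continuous.csv"))
  .write_table(summ$categorical, file.path(out_dir, "cohort_summary_categorical.csv"))
  fit <- mt_validate(filtered$records, score_ids = score_ids,
                     cutoff_mode = cutoff_mode, ci_method = ci_method,
                     seed = seed)
  .write_table(fit$performance, file.path(out_dir, "performance.csv"))
  jsonlite::write_json(fit$performance, file.path(out_dir, "performance.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  for (id in names(fit$roc)) {
    .write_table(as.data.frame(fit$roc[[id]]),
                 file.path(out_dir, sprintf("roc_%s.csv", id)))
  }
  .write_config(list(command = "run", n = n, seed = seed,
                     prevalence = prevalence,
                     scores = paste(score_ids, collapse = ","),
                     cutoff_mode = cutoff_mode, ci_method = ci_method),
                file.path(out_dir, "config_run.txt"))
  invisible(fit)
}
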