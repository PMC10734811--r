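#' End-to-end analysis: scoring, eligibility, outcomes, accuracy
#'
#' Chains the pipeline on raw admission + daily tables: applies the
#' eligibility filters, scores the retained patients, derives the four
#' outcomes, optionally restricts to a COVID-19 subgroup, and runs the
#' accuracy suite.
#'
#' @param admission,daily Input tables (see [read_admission_csv()],
#'   [read_daily_csv()]).
#' @param subgroup `"all"` (default), `"covid"` or `"no_covid"`.
#' @param cutoffs Fixed PARI cutoffs for the 2x2 analyses.
#' @return List of class `pari_analysis`: `suite` (the accuracy suite),
#'   `scores`, `outcomes`, `exclusions` (audit log), `n_input`, `n_analyzed`,
#'   `subgroup`.
#' @export
analyze_cohort <- function(admission, daily, subgroup = c("all", "covid", "no_covid"),
                           cutoffs = c(4, 6, 8)) {
  subgroup <- match.arg(subgroup)
  elig <- apply_eligibility(admission, daily)
  adm <- elig$retained
  if (subgroup == "covid") adm <- adm[adm$covid_confirmed %in% TRUE, ]
  if (subgroup == "no_covid") adm <- adm[adm$covid_confirmed %in% FALSE, ]
  day <- daily[daily$patient_id %in% adm$patient_id, ]
  scores <- score_patients(adm, day)
  outcomes <- derive_outcomes(adm, day)
  merged <- left_join(scores, outcomes, by = "patient_id")
  suite <- run_accuracy_suite(merged, cutoffs = cutoffs)
  structure(
    list(suite = suite, scores = scores, outcomes = outcomes,
         exclusions = elig$log, n_input = nrow(admission),
         n_analyzed = nrow(adm), subgroup = subgroup),
    class = "pari_analysis"
  )
}

#' @export
print.pari_analysis <- function(x, ...) {
  cat(sprintf("pariscore analysis: %d of %d records analyzed (subgroup: %s)\n\n",
              x$n_analyzed, x$n_input, x$subgroup))
  print(x$suite)
  invisible(x)
}

#' Write analysis reports (AUC table, cutoff table, JSON summary)
#'
#' Emits `auc_comparison.csv` (one row per outcome x predictor with AUC, CI
#' and the DeLong p-value against the reference predictor),
#' `cutoff_metrics.csv` (2x2 counts and metrics per outcome x cutoff),
#' `exclusions.csv`, `scores.csv`, `outcomes.csv` and `summary.json`.
#'
#' @param analysis A `pari_analysis` from [analyze_cohort()].
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_report <- function(analysis, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  suite <- analysis$suite
  auc_tbl <- suite$auc |>
    left_join(select(suite$delong, "outcome", "predictor", "p_vs_ref"),
              by = c("outcome", "predictor"))
  paths <- file.path(dir, c("auc_comparison.csv", "cutoff_metrics.csv",
                            "exclusions.csv", "scores.csv", "outcomes.csv",
                            "summary.json"))
  readr::write_csv(auc_tbl, paths[1])
  readr::write_csv(suite$cutoffs, paths[2])
  readr::write_csv(analysis$exclusions, paths[3])
  readr::write_csv(analysis$scores, paths[4])
  readr::write_csv(analysis$outcomes, paths[5])
  summary <- list(
    n_input = analysis$n_input,
    n_analyzed = analysis$n_analyzed,
    subgroup = analysis$subgroup,
    prevalence_percent = as.list(round(100 * vapply(
      analysis$outcomes[c("aki_72h", "persistent_aki_7d", "rrt_7d", "death_7d")],
      function(x) mean(x, na.rm = TRUE), numeric(1)), 4)),
    auc = auc_tbl,
    youden = suite$youden,
    cutoffs = suite$cutoffs
  )
  jsonlite::write_json(summary, paths[6], auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(paths)
}
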