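admission_columns <- c("patient_id", "age", "sex", "apache2",
                       "covid_confirmed", "icu_los_hours", "death_day",
                       "known_ckd")

#' Read the daily observation CSV
#'
#' One row per urine-output window: `patient_id, day_index,
#' creatinine_mg_dl, uo_ml_kg_h, uo_window_h, rrt, mv, vad,
#' bilirubin_mg_dl, antibiotics, sofa`. Day-level values (creatinine, SOFA,
#' flags) may be repeated across a day's window rows.
#'
#' @param path CSV file path.
#' @return Tibble validated against the schema.
#' @export
read_daily_csv <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(daily_columns, hdr)
  if (length(missing)) {
    pari_abort(paste0("daily observation table is missing column(s): ",
                      paste(missing, collapse = ", ")), "schema")
  }
  daily <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      day_index = readr::col_integer(),
      creatinine_mg_dl = readr::col_double(),
      uo_ml_kg_h = readr::col_double(),
      uo_window_h = readr::col_double(),
      rrt = readr::col_logical(),
      mv = readr::col_logical(),
      vad = readr::col_logical(),
      bilirubin_mg_dl = readr::col_double(),
      antibiotics = readr::col_logical(),
      sofa = readr::col_double()
    )
  )
  check_daily(daily)
  daily
}

#' Read the admission CSV
#'
#' Columns `patient_id, age, sex, apache2, covid_confirmed, icu_los_hours,
#' death_day, known_ckd` plus any comorbidity flags.
#'
#' @param path CSV file path.
#' @return Tibble.
#' @export
read_admission_csv <- function(path) {
  adm <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(), .default = readr::col_guess()
  ))
  missing <- setdiff(admission_columns, names(adm))
  if (length(missing)) {
    pari_abort(paste0("admission table is missing column(s): ",
                      paste(missing, collapse = ", ")), "schema")
  }
  adm
}

#' Write a cohort's CSV trio (admission, daily, ground truth)
#'
#' @param cohort A `pari_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("admission.csv", "daily.csv", "truth.csv"))
  readr::write_csv(cohort$admission, paths[1])
  readr::write_csv(cohort$daily, paths[2])
  readr::write_csv(cohort$truth, paths[3])
  invisible(paths)
}
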