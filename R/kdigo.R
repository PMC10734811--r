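#' @keywords internal
daily_columns <- c("patient_id", "day_index", "creatinine_mg_dl", "uo_ml_kg_h",
                   "uo_window_h", "rrt", "mv", "vad", "bilirubin_mg_dl",
                   "antibiotics", "sofa")

check_daily <- function(daily) {
  missing <- setdiff(daily_columns, names(daily))
  if (length(missing)) {
    pari_abort(paste0("daily observation table is missing column(s): ",
                      paste(missing, collapse = ", ")), "schema")
  }
  if (any(daily$day_index < 0, na.rm = TRUE)) {
    pari_abort("`day_index` must be >= 0.", "schema")
  }
  invisible(daily)
}

# One row per patient-day with the day-level scalars (first non-missing value
# among that day's window rows) plus urine-output availability. Implemented
# with rowsum/duplicated so it stays fast on cohorts of 10^4 patients.
day_scalars <- function(daily) {
  key <- paste(daily$patient_id, daily$day_index, sep = "\r")
  lead_row <- !duplicated(key)
  g <- match(key, key[lead_row])
  n_groups <- sum(lead_row)
  first_by <- function(x) {
    out <- x[rep(NA_integer_, n_groups)]
    idx <- which(!is.na(x))
    keep <- !duplicated(g[idx])
    out[g[idx][keep]] <- x[idx][keep]
    out
  }
  any_true <- function(x) {
    rowsum((x %in% TRUE) + 0L, g, reorder = FALSE)[, 1] > 0L
  }
  any_known <- function(x) {
    rowsum((!is.na(x)) + 0L, g, reorder = FALSE)[, 1] > 0L
  }
  tibble(
    patient_id = daily$patient_id[lead_row],
    day_index = daily$day_index[lead_row],
    creatinine = first_by(daily$creatinine_mg_dl),
    rrt_day = any_true(daily$rrt),
    rrt_known = any_known(daily$rrt),
    uo_known = rowsum((!is.na(daily$uo_ml_kg_h) & !is.na(daily$uo_window_h)) + 0L,
                      g, reorder = FALSE)[, 1] > 0L,
    sofa = first_by(daily$sofa),
    antibiotics = any_true(daily$antibiotics),
    bilirubin = first_by(daily$bilirubin_mg_dl),
    mv = any_true(daily$mv),
    vad = any_true(daily$vad)
  )
}

# Cumulative hours of the qualifying run ending at each window. Runs
# accumulate across consecutive windows (including the midnight boundary)
# and are broken at patient boundaries via `new_patient`.
run_hours <- function(qualifies, hours, new_patient) {
  qualifies[is.na(qualifies)] <- FALSE
  run_id <- cumsum(!qualifies | new_patient) + 1L
  y <- ifelse(qualifies, hours, 0)
  cs <- cumsum(y)
  lead <- !duplicated(run_id)
  offset <- (cs - y)[lead]
  (cs - offset[run_id - run_id[1] + 1L]) * as.numeric(qualifies)
}

# Per patient-day maxima of accumulated oliguria/anuria durations (hours).
uo_durations <- function(daily) {
  w <- daily |>
    filter(!is.na(.data$uo_ml_kg_h), !is.na(.data$uo_window_h)) |>
    arrange(.data$patient_id, .data$day_index)
  if (!nrow(w)) {
    return(tibble(patient_id = character(), day_index = integer(),
                  dur_lt05 = numeric(), dur_lt03 = numeric(), dur_anuria = numeric()))
  }
  new_patient <- c(TRUE, w$patient_id[-1] != w$patient_id[-nrow(w)])
  h05 <- run_hours(w$uo_ml_kg_h < 0.5, w$uo_window_h, new_patient)
  h03 <- run_hours(w$uo_ml_kg_h < 0.3, w$uo_window_h, new_patient)
  h00 <- run_hours(w$uo_ml_kg_h <= 0, w$uo_window_h, new_patient)
  key <- paste(w$patient_id, w$day_index, sep = "\r")
  lead_row <- !duplicated(key)
  g <- match(key, key[lead_row])
  group_max <- function(x) {
    o <- order(g, x)
    last <- !duplicated(g[o], fromLast = TRUE)
    out <- numeric(sum(lead_row))
    out[g[o][last]] <- x[o][last]
    out
  }
  tibble(patient_id = w$patient_id[lead_row], day_index = w$day_index[lead_row],
         dur_lt05 = group_max(h05), dur_lt03 = group_max(h03),
         dur_anuria = group_max(h00))
}

#' Stage acute kidney injury by the KDIGO criteria, per patient-day
#'
#' Applies the KDIGO staging rules to every observed day of every patient.
#' For each day the stage is the maximum over the creatinine criteria
#' (relative to the baseline), the urine-output criteria (accumulated over
#' consecutive sub-daily windows, carrying runs across days), and renal
#' replacement therapy:
#' \describe{
#'   \item{stage 3}{creatinine >= 3x baseline, or creatinine >= 4 mg/dL, or
#'     urine output < 0.3 mL/kg/h for >= 24 h, or anuria >= 12 h, or RRT.}
#'   \item{stage 2}{creatinine 2-2.9x baseline, or urine output
#'     < 0.5 mL/kg/h for >= 12 h.}
#'   \item{stage 1}{creatinine 1.5-1.9x baseline, or a creatinine rise of
#'     >= 0.3 mg/dL within any 48-hour window, or urine output
#'     < 0.5 mL/kg/h for 6-12 h.}
#' }
#' The day grid places the measurement taken at hour `24 * d` on day `d`, so
#' day 0 is admission; the baseline defaults to the day-0 creatinine (the
#' only anchor universally available once known chronic kidney disease is
#' excluded). Days where both creatinine and urine output are unobserved (and
#' no RRT is recorded) receive `NA` stage.
#'
#' @param daily Daily observation table (one row per urine-output window; see
#'   [read_daily_csv()] for the schema).
#' @param baseline Optional named numeric vector of baseline creatinines
#'   (names = patient ids) overriding the day-0 value.
#' @return Tibble with `patient_id`, `day_index`, `stage` (integer 0-3 or
#'   `NA`) and `triggered_by` (one of `"creatinine_ratio"`,
#'   `"creatinine_abs_rise"`, `"creatinine_abs_level"`, `"uo"`, `"anuria"`,
#'   `"rrt"`, `"none"`).
#' @export
kdigo_stages <- function(daily, baseline = NULL) {
  check_daily(daily)
  days <- day_scalars(daily) |>
    left_join(uo_durations(daily), by = c("patient_id", "day_index")) |>
    mutate(dplyr::across(c("dur_lt05", "dur_lt03", "dur_anuria"),
                         ~ if_else(is.na(.x), 0, .x))) |>
    arrange(.data$patient_id, .data$day_index)
  p <- days$patient_id
  d <- as.numeric(days$day_index)
  cr <- days$creatinine
  idx0 <- which(days$day_index == 0L)
  days$base <- cr[idx0][match(p, p[idx0])]
  if (!is.null(baseline)) {
    idx <- match(p, names(baseline))
    days$base <- if_else(!is.na(idx), unname(baseline)[idx], days$base)
  }
  # Creatinine values observed within the trailing 48 h (previous two day
  # records of the same patient, allowing for gaps in the day grid).
  n_rows <- length(cr)
  lag_val <- function(k) {
    lv <- c(rep(NA_real_, k), cr[seq_len(n_rows - k)])
    lp <- c(rep(NA_character_, k), p[seq_len(n_rows - k)])
    ld <- c(rep(NA_real_, k), d[seq_len(n_rows - k)])
    within <- !is.na(lv) & !is.na(lp) & lp == p & (d - ld) >= 1 & (d - ld) <= 2
    ifelse(within, lv, NA_real_)
  }
  if (n_rows > 1) {
    prev_min <- pmin(lag_val(1L), if (n_rows > 2) lag_val(2L) else NA_real_,
                     na.rm = TRUE)
  } else {
    prev_min <- NA_real_
  }
  days$rise48 <- !is.na(cr) & !is.na(prev_min) & (cr - prev_min >= 0.3)
  days$ratio <- cr / days$base

  cr_high <- !is.na(days$creatinine) & days$creatinine >= 4
  ratio_ok <- !is.na(days$ratio)
  s_cr <- dplyr::case_when(
    (ratio_ok & days$ratio >= 3) | cr_high ~ 3L,
    ratio_ok & days$ratio >= 2 ~ 2L,
    (ratio_ok & days$ratio >= 1.5) | days$rise48 ~ 1L,
    TRUE ~ 0L
  )
  s_uo <- dplyr::case_when(
    days$dur_anuria >= 12 | days$dur_lt03 >= 24 ~ 3L,
    days$dur_lt05 >= 12 ~ 2L,
    days$dur_lt05 >= 6 ~ 1L,
    TRUE ~ 0L
  )
  stage <- pmax(s_cr, s_uo, if_else(days$rrt_day, 3L, 0L))
  unassessable <- is.na(days$creatinine) & !days$uo_known & !days$rrt_day
  stage[unassessable] <- NA_integer_

  trig <- dplyr::case_when(
    is.na(stage) ~ "none",
    stage == 0L ~ "none",
    days$rrt_day & stage == 3L ~ "rrt",
    stage == 3L & ratio_ok & days$ratio >= 3 ~ "creatinine_ratio",
    stage == 3L & cr_high ~ "creatinine_abs_level",
    stage == 3L & days$dur_anuria >= 12 ~ "anuria",
    stage == 3L ~ "uo",
    stage == 2L & ratio_ok & days$ratio >= 2 ~ "creatinine_ratio",
    stage == 2L ~ "uo",
    stage == 1L & ratio_ok & days$ratio >= 1.5 ~ "creatinine_ratio",
    stage == 1L & days$rise48 ~ "creatinine_abs_rise",
    TRUE ~ "uo"
  )
  tibble(patient_id = days$patient_id, day_index = days$day_index,
         stage = stage, triggered_by = trig)
}

#' Single-day KDIGO assessment for one patient
#'
#' Convenience wrapper around [kdigo_stages()] for one patient and one
#' assessment day, with an explicit baseline creatinine.
#'
#' @param baseline_cr Baseline serum creatinine in mg/dL (> 0).
#' @param obs Daily observation table for a single patient covering days
#'   `0..day`.
#' @param day Day index to assess.
#' @return List with `day_index`, `stage` and `triggered_by`.
#' @examples
#' obs <- tibble::tibble(patient_id = "P1", day_index = 0:1,
#'   creatinine_mg_dl = c(1, 1.6), uo_ml_kg_h = 1, uo_window_h = 24,
#'   rrt = FALSE, mv = FALSE, vad = FALSE, bilirubin_mg_dl = NA_real_,
#'   antibiotics = FALSE, sofa = 2L)
#' stage_kdigo(1, obs, 1)$stage # 1: ratio 1.6x baseline
#' @export
stage_kdigo <- function(baseline_cr, obs, day) {
  if (!is.numeric(baseline_cr) || length(baseline_cr) != 1 ||
      !is.finite(baseline_cr) || baseline_cr <= 0) {
    pari_abort("`baseline_cr` must be a single positive creatinine in mg/dL.",
               "invalid_input")
  }
  check_daily(obs)
  ids <- unique(obs$patient_id)
  if (length(ids) != 1) {
    pari_abort("`obs` must contain exactly one patient.", "invalid_input")
  }
  if (!day %in% obs$day_index) {
    pari_abort("`obs` does not cover the requested day.", "invalid_input")
  }
  st <- kdigo_stages(obs, baseline = setNames(baseline_cr, ids))
  row <- st[st$day_index == day, ]
  if (is.na(row$stage)) {
    pari_abort("Neither creatinine nor urine output is available on the assessed day.",
               "missing_data")
  }
  list(day_index = as.integer(day), stage = row$stage,
       triggered_by = row$triggered_by)
}
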