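exclusion_reasons <- c("missing_mandatory_renal_data", "icu_stay_lt_72h",
                       "death_lt_72h", "creatinine_gt_4", "known_ckd")

#' Apply the study eligibility filters
#'
#' A record is retained when (i) creatinine, urine output and RRT status are
#' all recorded at the three mandatory times — ICU admission, 24 h and 72 h
#' (day indices 0, 1 and 3); (ii) the ICU stay lasted at least 72 h; (iii)
#' the patient did not die before 72 h; (iv) no screening creatinine
#' (admission through 72 h, days 0-3) exceeds 4 mg/dL; and (v) there is no
#' previously known chronic kidney disease. Every input record appears in
#' the audit log; excluded records carry the first matching reason in the
#' order above, which makes the log deterministic. Mandatory-time checks only
#' consider times the stay reached, so a 48-hour stay with complete data is
#' logged as a short stay, not as missing data, and the short-stay rule is
#' applied to alive discharges (deaths before 72 h fall under the death
#' rule).
#'
#' @param admission Admission table with at least `patient_id`,
#'   `icu_los_hours`, `death_day` and `known_ckd`.
#' @param daily Daily observation table.
#' @return List with `retained` (the admission rows kept, original order) and
#'   `log` (tibble `patient_id`, `reason`, `retained`; `reason` is `NA` for
#'   retained records).
#' @export
apply_eligibility <- function(admission, daily) {
  check_daily(daily)
  days <- day_scalars(daily) |>
    mutate(
      has_cr = !is.na(.data$creatinine),
      has_uo = .data$uo_known,
      has_rrt = .data$rrt_known
    )
  mand <- days |>
    filter(.data$day_index %in% c(0L, 1L, 3L)) |>
    mutate(ok = .data$has_cr & .data$has_uo & .data$has_rrt,
           day = paste0("ok", .data$day_index)) |>
    select("patient_id", "day", "ok") |>
    tidyr::pivot_wider(names_from = "day", values_from = "ok")
  for (col in c("ok0", "ok1", "ok3")) {
    if (!col %in% names(mand)) mand[[col]] <- NA
  }
  screen <- days |>
    filter(.data$day_index <= 3L) |>
    group_by(.data$patient_id) |>
    summarise(cr_gt4 = any(.data$creatinine > 4, na.rm = TRUE),
              .groups = "drop")
  per_patient <- admission |>
    select("patient_id", "icu_los_hours", "death_day", "known_ckd") |>
    left_join(mand, by = "patient_id") |>
    left_join(screen, by = "patient_id")

  los <- per_patient$icu_los_hours
  missing_mand <- (!(per_patient$ok0 %in% TRUE) & 24 * 0 <= los) |
    (!(per_patient$ok1 %in% TRUE) & 24 * 1 <= los) |
    (!(per_patient$ok3 %in% TRUE) & 24 * 3 <= los)
  dead <- !is.na(per_patient$death_day)
  reason <- dplyr::case_when(
    missing_mand ~ "missing_mandatory_renal_data",
    !dead & los < 72 ~ "icu_stay_lt_72h",
    dead & per_patient$death_day < 3 ~ "death_lt_72h",
    per_patient$cr_gt4 %in% TRUE ~ "creatinine_gt_4",
    per_patient$known_ckd %in% TRUE ~ "known_ckd",
    TRUE ~ NA_character_
  )
  log <- tibble(patient_id = per_patient$patient_id, reason = reason,
                retained = is.na(reason))
  list(
    retained = admission[admission$patient_id %in%
                           log$patient_id[log$retained], , drop = FALSE],
    log = log
  )
}

persistent_run <- function(day, stage) {
  ord <- order(day)
  day <- day[ord]
  stage <- stage[ord]
  full <- seq(min(day), max(day))
  st <- stage[match(full, day)]
  q <- !is.na(st) & st >= 2
  r <- rle(q)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  any(r$values & r$lengths >= 4L & full[starts] <= 7L)
}

#' Derive the four binary endpoints per patient
#'
#' \describe{
#'   \item{`aki_72h`}{KDIGO stage 2 or 3 at any assessment within 72 h of
#'     admission (days 0-3, the day-3 record being the 72-hour boundary).}
#'   \item{`persistent_aki_7d`}{a run of consecutive daily assessments at
#'     stage 2-3 spanning more than 72 h — at least 4 consecutive daily
#'     stages — beginning on or before day 7. Persistence may begin after
#'     72 h, so it does not imply `aki_72h`.}
#'   \item{`rrt_7d`}{renal replacement therapy on any of days 0-7; `NA` when
#'     RRT status is unrecorded on some of those days and never positive.}
#'   \item{`death_7d`}{death on or before day 7.}
#' }
#'
#' @param admission Admission table (needs `patient_id`, `death_day`).
#' @param daily Daily observation table.
#' @param stages Optional precomputed [kdigo_stages()] table; computed from
#'   `daily` when omitted. If a supplied stage sequence stops short of the
#'   observed stay (through day 7) for a patient without a terminal event, a
#'   missing-data error is raised.
#' @return Tibble `patient_id`, `aki_72h`, `persistent_aki_7d`, `rrt_7d`,
#'   `death_7d`.
#' @export
derive_outcomes <- function(admission, daily, stages = NULL) {
  check_daily(daily)
  if (is.null(stages)) stages <- kdigo_stages(daily)
  obs_span <- daily |>
    group_by(.data$patient_id) |>
    summarise(last_day = max(.data$day_index), .groups = "drop") |>
    left_join(select(admission, "patient_id", "death_day"), by = "patient_id")
  stage_span <- stages |>
    group_by(.data$patient_id) |>
    summarise(last_staged = max(.data$day_index), .groups = "drop")
  chk <- left_join(obs_span, stage_span, by = "patient_id")
  short <- !is.na(chk$last_day) &
    (is.na(chk$last_staged) | chk$last_staged < pmin(chk$last_day, 7L)) &
    is.na(chk$death_day)
  if (any(short)) {
    pari_abort(paste0("stage sequence shorter than the observed stay for patient(s) ",
                      paste(head(chk$patient_id[short], 5), collapse = ", ")),
               "missing_data")
  }

  renal <- stages |>
    group_by(.data$patient_id) |>
    summarise(
      aki_72h = any(.data$stage[.data$day_index <= 3L] >= 2L, na.rm = TRUE),
      persistent_aki_7d = persistent_run(.data$day_index, .data$stage),
      .groups = "drop"
    )
  rrt <- day_scalars(daily) |>
    filter(.data$day_index <= 7L) |>
    group_by(.data$patient_id) |>
    summarise(
      rrt_7d = if (any(.data$rrt_day)) TRUE
               else if (any(!.data$rrt_known)) NA
               else FALSE,
      .groups = "drop"
    )
  admission |>
    select("patient_id", "death_day") |>
    left_join(renal, by = "patient_id") |>
    left_join(rrt, by = "patient_id") |>
    mutate(death_7d = !is.na(.data$death_day) & .data$death_day <= 7) |>
    select("patient_id", "aki_72h", "persistent_aki_7d", "rrt_7d", "death_7d")
}
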