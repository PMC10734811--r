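#' Score every patient: PARI components plus comparator predictors
#'
#' Computes, per patient, the delta creatinine over the first 24 ICU hours,
#' the admission condition flags (hyperbilirubinemia, sepsis, ventilatory or
#' hemodynamic support), the PARI score, admission SOFA and APACHE II (taken
#' as given numeric inputs), and the KDIGO stage trajectory over days 0-7 in
#' wide columns (`kdigo_stage_day0` ... `kdigo_stage_day7`).
#'
#' Missing bilirubin is treated as no hyperbilirubinemia and missing
#' ventilation/vasoactive flags as absent support (both conservative toward a
#' lower score); patients with a missing SOFA at admission or 24 h are
#' scored as non-septic, and each such fallback is reported in the
#' `n_missing_*` attributes. Patients lacking creatinine at admission or
#' 24 h get `NA` delta and `NA` PARI; they are the ones
#' [apply_eligibility()] removes.
#'
#' @param admission Admission table (see [read_admission_csv()]).
#' @param daily Daily observation table (see [read_daily_csv()]).
#' @return Tibble with one row per patient: identifiers, score components,
#'   `pari`, `sofa`, `apache2`, and KDIGO stage columns for days 0-7.
#' @export
score_patients <- function(admission, daily) {
  check_daily(daily)
  days <- day_scalars(daily)
  at_day <- function(col, d) {
    days |>
      filter(.data$day_index == d) |>
      select("patient_id", value = dplyr::all_of(col))
  }
  cr0 <- at_day("creatinine", 0L) |> rename(cr0 = "value")
  cr1 <- at_day("creatinine", 1L) |> rename(cr1 = "value")
  sofa0 <- at_day("sofa", 0L) |> rename(sofa0 = "value")
  sofa1 <- at_day("sofa", 1L) |> rename(sofa1 = "value")
  abx0 <- at_day("antibiotics", 0L) |> rename(abx0 = "value")
  abx1 <- at_day("antibiotics", 1L) |> rename(abx1 = "value")
  adm <- days |>
    filter(.data$day_index == 0L) |>
    select("patient_id", "bilirubin", "mv", "vad")

  comp <- admission |>
    select("patient_id", "apache2") |>
    left_join(cr0, by = "patient_id") |>
    left_join(cr1, by = "patient_id") |>
    left_join(sofa0, by = "patient_id") |>
    left_join(sofa1, by = "patient_id") |>
    left_join(abx0, by = "patient_id") |>
    left_join(abx1, by = "patient_id") |>
    left_join(adm, by = "patient_id") |>
    mutate(
      delta_cr = .data$cr1 - .data$cr0,
      hyperbili = !is.na(.data$bilirubin) & .data$bilirubin >= 2,
      sepsis = !is.na(.data$sofa0) & !is.na(.data$sofa1) &
        (.data$sofa1 - .data$sofa0 >= 2) &
        (.data$abx0 %in% TRUE) & (.data$abx1 %in% TRUE),
      support = (.data$mv %in% TRUE) | (.data$vad %in% TRUE)
    )

  scorable <- !is.na(comp$delta_cr)
  pari_tbl <- compute_pari(comp$delta_cr[scorable], comp$hyperbili[scorable],
                           comp$sepsis[scorable], comp$support[scorable])
  comp$delta_multiplier <- NA_integer_
  comp$condition_sum <- NA_integer_
  comp$pari <- NA_integer_
  comp$delta_multiplier[scorable] <- pari_tbl$delta_multiplier
  comp$condition_sum[scorable] <- pari_tbl$condition_sum
  comp$pari[scorable] <- pari_tbl$pari

  stages <- kdigo_stages(daily) |>
    filter(.data$day_index <= 7L) |>
    mutate(day = paste0("kdigo_stage_day", .data$day_index)) |>
    select("patient_id", "day", "stage") |>
    tidyr::pivot_wider(names_from = "day", values_from = "stage",
                       names_sort = TRUE)

  out <- comp |>
    mutate(sofa = .data$sofa0) |>
    select("patient_id", "delta_cr", "delta_multiplier", "hyperbili",
           "sepsis", "support", "condition_sum", "pari", "sofa", "apache2") |>
    left_join(stages, by = "patient_id")
  attr(out, "n_missing_sofa") <- sum(is.na(comp$sofa0) | is.na(comp$sofa1))
  attr(out, "n_missing_bilirubin") <- sum(is.na(comp$bilirubin))
  attr(out, "n_unscorable") <- sum(!scorable)
  out
}
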