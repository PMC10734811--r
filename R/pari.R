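#' Band the 24-hour creatinine change into the PARI multiplier
#'
#' The first 24-hour change in serum creatinine (delta creatinine, mg/dL) is
#' mapped onto the discrete PARI multiplier: values below 0.2 mg/dL score 1,
#' values of at least 0.2 score 2, at least 0.3 score 4, and at least
#' 0.4 score 10. Bands are closed on the left and open on the right, so a
#' delta of exactly 0.3 scores 4. Negative deltas (creatinine falling over
#' the first day) land in the lowest band.
#'
#' @param delta Numeric vector of creatinine changes in mg/dL (signed:
#'   value at 24 h minus value at admission).
#' @return Integer vector of multipliers, each one of 1, 2, 4 or 10.
#' @examples
#' band_delta_creatinine(c(-0.1, 0.19, 0.2, 0.3, 0.45))
#' @export
band_delta_creatinine <- function(delta) {
  if (!is.numeric(delta)) {
    pari_abort("`delta` must be numeric (mg/dL).", "invalid_input")
  }
  if (length(delta) && any(!is.finite(delta))) {
    pari_abort("`delta` contains non-finite values; delta creatinine must be a finite number of mg/dL.",
               "invalid_input")
  }
  m <- rep(1L, length(delta))
  m[delta >= 0.2] <- 2L
  m[delta >= 0.3] <- 4L
  m[delta >= 0.4] <- 10L
  m
}

#' Compute the persistent AKI risk index (PARI)
#'
#' PARI is the product of the banded delta-creatinine multiplier and the sum
#' of the admission condition weights: hyperbilirubinemia (total bilirubin
#' >= 2 mg/dL) and sepsis score 2 each, and ventilatory or hemodynamic
#' support (mechanical ventilation or vasoactive drugs) scores 4. When no
#' condition is present the condition sum is taken to be 1, so a patient with
#' stable creatinine and no aggravating condition scores 1.
#'
#' @param delta_creatinine Numeric vector, creatinine at 24 h minus creatinine
#'   at admission (mg/dL). `NA` values raise a missing-data error: patients
#'   without both creatinine measurements cannot be scored and are expected to
#'   be removed by [apply_eligibility()].
#' @param hyperbilirubinemia,sepsis,support Logical vectors (recycled to the
#'   length of `delta_creatinine`). `NA` is treated as `FALSE`, the
#'   conservative choice toward a lower score.
#' @return A tibble with one row per patient: `delta_creatinine`,
#'   `delta_multiplier`, the three condition flags, `condition_sum` and
#'   `pari`.
#' @examples
#' compute_pari(0.45, sepsis = TRUE, support = TRUE)$pari # 10 * (2 + 4) = 60
#' compute_pari(0)$pari                                   # no condition -> 1
#' @export
compute_pari <- function(delta_creatinine, hyperbilirubinemia = FALSE,
                         sepsis = FALSE, support = FALSE) {
  if (anyNA(delta_creatinine)) {
    pari_abort("`delta_creatinine` has missing values: creatinine at admission and 24 h are both required.",
               "missing_data")
  }
  n <- length(delta_creatinine)
  hb <- rep_len(!is.na(hyperbilirubinemia) & hyperbilirubinemia, n)
  sp <- rep_len(!is.na(sepsis) & sepsis, n)
  su <- rep_len(!is.na(support) & support, n)
  cs <- 2L * hb + 2L * sp + 4L * su
  cs[cs == 0L] <- 1L
  mult <- band_delta_creatinine(delta_creatinine)
  tibble(
    delta_creatinine = as.numeric(delta_creatinine),
    delta_multiplier = mult,
    hyperbilirubinemia = hb,
    sepsis = sp,
    support = su,
    condition_sum = cs,
    pari = mult * cs
  )
}

#' Enumerate the attainable PARI values
#'
#' Exhaustively multiplies every delta-creatinine multiplier (1, 2, 4, 10) by
#' every attainable condition sum (1, 2, 4, 6, 8) and returns the sorted set
#' of distinct products. The enumeration yields 14 values with maximum 80.
#' The value list usually cited for the index has 13 entries and omits 32,
#' although the published weights admit it (4 x (2 + 2 + 4) = 32); the
#' omitted value is flagged in the `"extra_values"` attribute rather than
#' silently dropped.
#'
#' @return Sorted integer vector of attainable scores, with attribute
#'   `"extra_values"` holding values attainable from the weights but absent
#'   from the commonly cited 13-value list.
#' @examples
#' enumerate_pari_support()
#' @export
enumerate_pari_support <- function() {
  multipliers <- c(1L, 2L, 4L, 10L)
  condition_sums <- c(1L, 2L, 4L, 6L, 8L)
  support <- sort(unique(as.integer(outer(multipliers, condition_sums))))
  cited <- c(1L, 2L, 4L, 6L, 8L, 10L, 12L, 16L, 20L, 24L, 40L, 60L, 80L)
  attr(support, "extra_values") <- setdiff(support, cited)
  support
}

#' Flag sepsis from SOFA rise plus sustained antibiotics
#'
#' Sepsis is flagged when the SOFA score rises by at least 2 points over the
#' first 24 ICU hours and the patient is on antibiotics for at least 48 hours
#' from admission (antibiotics recorded on the first two daily records).
#'
#' @param sofa_series Integer/numeric vector of daily SOFA scores aligned to
#'   the day grid (element 1 = admission, element 2 = 24 h, ...). The first
#'   two values must be present.
#' @param antibiotics_series Logical vector on the same grid; `NA` counts as
#'   not on antibiotics.
#' @return Single logical.
#' @examples
#' detect_sepsis(c(3, 6, 7), c(TRUE, TRUE, TRUE))  # TRUE
#' detect_sepsis(c(3, 4, 7), c(TRUE, TRUE, TRUE))  # FALSE: rise of 1
#' @export
detect_sepsis <- function(sofa_series, antibiotics_series) {
  if (length(sofa_series) < 2 || anyNA(sofa_series[1:2])) {
    pari_abort("SOFA at admission and at 24 h are both required to assess sepsis.",
               "missing_data")
  }
  abx <- !is.na(antibiotics_series) & antibiotics_series
  (sofa_series[2] - sofa_series[1] >= 2) && length(abx) >= 2 && abx[1] && abx[2]
}
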