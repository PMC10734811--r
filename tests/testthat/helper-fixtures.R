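# Shared fixture builders: single-patient daily tables, and the published
# cutoff-table reconstruction (per-patient scores/labels rebuilt from the
# printed 2x2 group counts).

# One daily row per urine-output window; day-level scalars repeated.
obs_rows <- function(patient_id = "P1", day_index, creatinine = NA_real_,
                     uo = NA_real_, uo_h = NA_real_, rrt = FALSE, mv = FALSE,
                     vad = FALSE, bilirubin = NA_real_, antibiotics = FALSE,
                     sofa = NA_real_) {
  n <- max(lengths(list(day_index, uo, uo_h)))
  tibble::tibble(
    patient_id = patient_id,
    day_index = as.integer(rep_len(day_index, n)),
    creatinine_mg_dl = rep_len(creatinine, n),
    uo_ml_kg_h = rep_len(uo, n),
    uo_window_h = rep_len(uo_h, n),
    rrt = rep_len(rrt, n),
    mv = rep_len(mv, n),
    vad = rep_len(vad, n),
    bilirubin_mg_dl = rep_len(bilirubin, n),
    antibiotics = rep_len(antibiotics, n),
    sofa = rep_len(sofa, n)
  )
}

# A complete eligible patient: creatinine path given as per-day values,
# urine output healthy unless overridden.
make_patient <- function(patient_id, cr_by_day, uo = 1.2, rrt_days = integer(),
                         sofa0 = 3, sofa1 = 3, abx = FALSE, mv = FALSE,
                         vad = FALSE, bilirubin0 = 0.6) {
  days <- seq_along(cr_by_day) - 1L
  dplyr::bind_rows(lapply(days, function(d) {
    obs_rows(patient_id, day_index = d, creatinine = cr_by_day[d + 1L],
             uo = rep(uo, 4), uo_h = rep(6, 4), rrt = d %in% rrt_days,
             mv = mv, vad = vad,
             bilirubin = if (d == 0) bilirubin0 else NA_real_,
             antibiotics = abx, sofa = if (d == 0) sofa0 else sofa1)
  }))
}

make_admission <- function(patient_id, icu_los_hours = 24 * 8 + 12,
                           death_day = NA_integer_, known_ckd = FALSE,
                           apache2 = 12, covid = TRUE) {
  tibble::tibble(patient_id = patient_id, age = 60, sex = "male",
                 apache2 = apache2, covid_confirmed = covid,
                 icu_los_hours = icu_los_hours,
                 death_day = as.integer(death_day), known_ckd = known_ckd)
}

# Published cutoff-table group counts: (positive-group n, events among
# positives, negative-group n, events among negatives) per cutoff x outcome.
table3_counts <- function() {
  tibble::tribble(
    ~cutoff, ~outcome, ~pos_n, ~pos_events, ~neg_n, ~neg_events,
    4, "aki",  228, 68, 310, 24,
    4, "pers", 228, 70, 310, 35,
    4, "rrt",  228, 20, 309, 7,
    4, "mort", 228, 44, 310, 24,
    6, "aki",  159, 56, 379, 36,
    6, "pers", 159, 54, 379, 51,
    6, "rrt",  159, 17, 378, 10,
    6, "mort", 159, 33, 379, 35,
    8, "aki",  85, 37, 453, 55,
    8, "pers", 85, 36, 453, 69,
    8, "rrt",  85, 10, 452, 17,
    8, "mort", 85, 17, 453, 51
  )
}

# Per-patient score/label vectors whose 2x2 table reproduces one row of
# counts: positives get the cutoff value, negatives sit one unit below.
fixture_from_counts <- function(cutoff, pos_n, pos_events, neg_n, neg_events) {
  list(
    scores = c(rep(cutoff, pos_n), rep(cutoff - 1, neg_n)),
    labels = c(rep(c(TRUE, FALSE), c(pos_events, pos_n - pos_events)),
               rep(c(TRUE, FALSE), c(neg_events, neg_n - neg_events)))
  )
}

# Printed metric cells (estimate, ci_lo, ci_hi) x (sens, spec, ppv, npv,
# accuracy) per cutoff x outcome, as published. The sensitivity estimate for
# cutoff 4 / AKI is printed as "73" although its own counts give 68/92 =
# 73.9% (whose Wald CI is exactly the printed 64.9-82.9); the corrected
# value is stored here.
table3_printed <- function() {
  m <- rbind(
    c(73.9,64.9,82.9, 64.1,59.7,68.6, 29.8,23.9,35.8, 92.3,89.3,95.2, 65.8,61.8,69.8),
    c(66.7,57.6,75.7, 63.4,58.9,68.0, 30.7,24.7,36.7, 88.7,85.1,92.2, 64.1,60.0,68.1),
    c(74.1,57.5,90.6, 59.3,55.0,63.6,  8.8, 5.1,12.4, 97.7,96.1,99.4, 60.1,55.9,64.2),
    c(64.7,53.3,76.1, 60.9,56.4,65.3, 19.3,14.2,24.4, 92.3,89.3,95.2, 61.3,57.2,65.5),
    c(60.9,50.9,70.8, 76.9,73.0,80.8, 35.2,27.8,42.6, 90.5,87.5,93.5, 74.2,70.5,77.9),
    c(51.4,41.9,61.0, 75.8,71.7,79.8, 34.0,26.6,41.3, 86.5,83.1,90.0, 71.0,67.2,74.8),
    c(63.0,44.7,81.2, 72.2,68.3,76.1, 10.7, 5.9,15.5, 97.4,95.7,99.0, 71.7,67.9,75.6),
    c(48.5,36.7,60.4, 73.2,69.2,77.2, 20.8,14.5,27.1, 90.8,87.9,93.7, 70.1,66.2,73.9),
    c(40.2,30.2,50.2, 89.2,86.4,92.1, 43.5,33.0,54.1, 87.9,84.9,90.9, 80.9,77.5,84.2),
    c(34.3,25.2,43.4, 88.7,85.7,91.7, 42.4,31.8,52.9, 84.8,81.5,88.1, 78.1,74.6,81.6),
    c(37.0,18.8,55.3, 85.3,82.3,88.4, 11.8, 4.9,18.6, 96.2,94.5,98.0, 82.9,79.7,86.1),
    c(25.0,14.7,35.3, 85.5,82.4,88.7, 20.0,11.5,28.5, 88.7,85.8,91.7, 77.9,74.4,81.4)
  )
  colnames(m) <- as.vector(outer(c("est", "lo", "hi"),
                                 c("sensitivity", "specificity", "ppv", "npv",
                                   "accuracy"),
                                 function(a, b) paste(b, a, sep = "_")))
  m
}

# Brute-force AUC oracle: average over all positive/negative pairs.
pair_auc <- function(scores, labels) {
  x <- scores[labels]
  y <- scores[!labels]
  mean(outer(x, y, ">") + 0.5 * outer(x, y, "=="))
}
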