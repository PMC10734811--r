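toy_cohort <- function() {
  clean1 <- make_patient("ok1", cr_by_day = rep(1, 9))
  clean2 <- make_patient("ok2", cr_by_day = c(1, 1.1, 1.2, 1.2, 1.1, 1, 1, 1, 1))
  miss <- make_patient("miss", cr_by_day = c(1, NA, 1, 1, 1, 1, 1, 1, 1))
  short <- make_patient("short", cr_by_day = c(1, 1))
  dead <- make_patient("dead", cr_by_day = c(1, 1, 1))
  high <- make_patient("high", cr_by_day = c(4.5, 4.4, 4.3, 4.2, 4, 4, 4, 4, 4))
  ckd <- make_patient("ckd", cr_by_day = rep(1.2, 9))
  daily <- dplyr::bind_rows(clean1, clean2, miss, short, dead, high, ckd)
  admission <- dplyr::bind_rows(
    make_admission("ok1"), make_admission("ok2"), make_admission("miss"),
    make_admission("short", icu_los_hours = 48),
    make_admission("dead", icu_los_hours = 50, death_day = 2),
    make_admission("high"),
    make_admission("ckd", known_ckd = TRUE)
  )
  list(admission = admission, daily = daily)
}

test_that("each eligibility rule excludes its record, first match wins", {
  tc <- toy_cohort()
  res <- apply_eligibility(tc$admission, tc$daily)
  expect_setequal(res$retained$patient_id, c("ok1", "ok2"))
  log <- res$log
  expect_identical(nrow(log), nrow(tc$admission)) # every record logged
  reasons <- setNames(log$reason, log$patient_id)
  expect_identical(reasons[["miss"]], "missing_mandatory_renal_data")
  expect_identical(reasons[["short"]], "icu_stay_lt_72h")
  expect_identical(reasons[["dead"]], "death_lt_72h")
  expect_identical(reasons[["high"]], "creatinine_gt_4")
  expect_identical(reasons[["ckd"]], "known_ckd")
  expect_true(all(is.na(reasons[c("ok1", "ok2")])))
  # a record violating several rules gets the first listed reason
  both <- tc$admission
  both$known_ckd[both$patient_id == "high"] <- TRUE
  expect_identical(apply_eligibility(both, tc$daily)$log$reason[
    both$patient_id == "high"], "creatinine_gt_4")
})

test_that("retention is invariant under cohort permutation", {
  tc <- toy_cohort()
  ref <- apply_eligibility(tc$admission, tc$daily)
  set.seed(5)
  adm2 <- tc$admission[sample(nrow(tc$admission)), ]
  day2 <- tc$daily[sample(nrow(tc$daily)), ]
  res2 <- apply_eligibility(adm2, day2)
  expect_setequal(res2$retained$patient_id, ref$retained$patient_id)
  ord <- match(ref$log$patient_id, res2$log$patient_id)
  expect_identical(res2$log$reason[ord], ref$log$reason)
})

test_that("outcome derivation matches the stage-run definitions", {
  # stage 2 on days 1-2 only: AKI at 72 h without persistence
  transient <- make_patient("t", cr_by_day = c(1, 2.2, 2.2, 1.4, 1.1, 1, 1, 1))
  # stage 2 on days 2-5 (four consecutive days): persistent, also AKI <= 72 h
  persistent <- make_patient("p", cr_by_day = c(1, 1.4, 2.2, 2.2, 2.2, 2.2, 1.2, 1))
  # stage 2 on days 4-7: persistent that begins after 72 h, no AKI at 72 h
  late <- make_patient("l", cr_by_day = c(1, 1.1, 1.2, 1.3, 2.2, 2.2, 2.2, 2.2, 1.2))
  adm <- dplyr::bind_rows(make_admission("t"), make_admission("p"),
                          make_admission("l", icu_los_hours = 9 * 24 + 12))
  oc <- derive_outcomes(adm, dplyr::bind_rows(transient, persistent, late))
  oc <- oc[match(c("t", "p", "l"), oc$patient_id), ]
  expect_identical(oc$aki_72h, c(TRUE, TRUE, FALSE))
  expect_identical(oc$persistent_aki_7d, c(FALSE, TRUE, TRUE))
  expect_identical(oc$rrt_7d, c(FALSE, FALSE, FALSE))
  expect_identical(oc$death_7d, c(FALSE, FALSE, FALSE))
})

test_that("three stage-2 days do not qualify as persistent, four do", {
  three <- make_patient("x", cr_by_day = c(1, 2.2, 2.2, 2.2, 1.2, 1, 1, 1))
  four <- make_patient("y", cr_by_day = c(1, 2.2, 2.2, 2.2, 2.2, 1.2, 1, 1))
  oc <- derive_outcomes(dplyr::bind_rows(make_admission("x"), make_admission("y")),
                        dplyr::bind_rows(three, four))
  expect_identical(oc$persistent_aki_7d[oc$patient_id == "x"], FALSE)
  expect_identical(oc$persistent_aki_7d[oc$patient_id == "y"], TRUE)
})

test_that("death and RRT endpoints honour the 7-day window and missingness", {
  p1 <- make_patient("d6", cr_by_day = rep(1, 7))
  p2 <- make_patient("d9", cr_by_day = rep(1, 10))
  p3 <- make_patient("r", cr_by_day = rep(1, 8), rrt_days = 5L)
  p4 <- make_patient("rna", cr_by_day = rep(1, 8))
  p4$rrt[p4$day_index >= 5] <- NA
  adm <- dplyr::bind_rows(
    make_admission("d6", icu_los_hours = 6 * 24 + 8, death_day = 6),
    make_admission("d9", icu_los_hours = 9 * 24 + 8, death_day = 9),
    make_admission("r"), make_admission("rna")
  )
  oc <- derive_outcomes(adm, dplyr::bind_rows(p1, p2, p3, p4))
  expect_identical(oc$death_7d[oc$patient_id == "d6"], TRUE)
  expect_identical(oc$death_7d[oc$patient_id == "d9"], FALSE)
  expect_identical(oc$rrt_7d[oc$patient_id == "r"], TRUE)
  expect_true(is.na(oc$rrt_7d[oc$patient_id == "rna"]))
})

test_that("an RRT outcome implies a stage-3 day for that patient", {
  co <- generate_cohort(sim_config(n_patients = 400, seed = 31))
  st <- kdigo_stages(co$daily)
  oc <- derive_outcomes(co$admission, co$daily, stages = st)
  rrt_pos <- oc$patient_id[oc$rrt_7d %in% TRUE]
  max3 <- tapply(st$stage, st$patient_id, function(s) max(s, na.rm = TRUE))
  expect_true(all(max3[rrt_pos] == 3L))
})

test_that("a truncated stage sequence without a terminal event is an error", {
  daily <- make_patient("q", cr_by_day = rep(1, 8))
  adm <- make_admission("q")
  st <- kdigo_stages(daily)
  expect_error(derive_outcomes(adm, daily, stages = st[st$day_index <= 2, ]),
               class = "pariscore_error_missing_data")
})
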