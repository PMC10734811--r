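#' Simulator configuration
#'
#' Defaults describe an ICU acute-respiratory-failure cohort after the
#' eligibility screen: ~17.1% AKI (stage 2-3) within 72 h, 19.5% persistent
#' AKI within 7 days (56% of which begins within 72 h), 5% RRT and 12.6%
#' death within 7 days, 81.6% confirmed COVID-19, admission creatinine
#' log-normal around a 0.88 mg/dL median, mechanical ventilation in 27% and
#' vasoactive drugs in 18.2% overall (condition prevalences split by AKI
#' status so that support, SOFA rise and AKI co-occur), antibiotics over the
#' first 48 h in 60.8%, and hyperbilirubinemia in 0.7%.
#'
#' Patients are simulated from a latent 7-day renal-trajectory class
#' (`none`, `transient`, `persistent_early`, `persistent_late`): the class
#' fixes a multiplicative creatinine drift profile (peaking at 2.4-2.6x
#' baseline on injury days), the day-1 creatinine multiplier distribution
#' (hence delta creatinine), oliguria episodes, RRT assignment and the
#' 7-day death hazard, so that AKI, RRT, death and high PARI co-occur.
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed; every stochastic step flows from it.
#' @param aki72_prevalence,persistent_prevalence,rrt_prevalence,death7_prevalence
#'   Target marginal rates among generated (eligible) patients.
#' @param persistent_early_share Fraction of persistent-AKI patients whose
#'   qualifying run begins within 72 h.
#' @param death7_given_aki72 7-day death probability among patients with AKI
#'   within 72 h; the no-AKI death rate is derived so the marginal matches
#'   `death7_prevalence` (persistent-late patients, whose stage run ends
#'   after day 7, are given no 7-day death so their run is observable).
#' @param covid_share Probability of confirmed COVID-19.
#' @param baseline_cr_meanlog,baseline_cr_sdlog Log-normal admission
#'   creatinine (mg/dL).
#' @param cr_noise_sdlog Day-to-day multiplicative creatinine noise (log-sd).
#' @param day1_mult_meanlog,day1_mult_sdlog Log-normal day-1 creatinine
#'   multiplier for early-AKI classes (drives delta creatinine).
#' @param transient_peak_mult,persistent_peak_mult Peak creatinine multiple
#'   of baseline on injury days.
#' @param mv_prob,vad_prob,hyperbili_prob Named probabilities (`no_aki`,
#'   `aki`) of admission support and hyperbilirubinemia.
#' @param abx48_prob Probability of antibiotics over the first 48 h.
#' @param sofa_rise_prob Named probability of a >= 2-point SOFA rise in 24 h.
#' @param sofa0_meanlog,sofa0_sdlog,apache_mean,apache_sd,age_mean,age_sd
#'   Severity-score and age distributions by AKI status.
#' @param uo_windows_per_day Sub-daily urine-output windows (default 4 blocks
#'   of 6 h).
#' @param uo_meanlog,uo_sdlog Log-normal urine-output rate (mL/kg/h) on
#'   non-oliguric days.
#' @param oliguria_share Fraction of AKI-class patients with oliguric injury
#'   days.
#' @param oliguria_meanlog,oliguria_sdlog Oliguric-day urine-output rate.
#' @param los_meanlog,los_sdlog Log-normal discharge day for survivors.
#' @param max_day Last simulated day index.
#' @param rrt_missing_rate Per-patient probability that RRT status is
#'   unrecorded after day 3 (yielding a missing RRT outcome).
#' @param violation_fraction Default fraction mutated by
#'   [inject_exclusion_violations()].
#' @return List of class `pari_sim_config`.
#' @export
sim_config <- function(n_patients = 538, seed = 2020,
                       aki72_prevalence = 0.171,
                       persistent_prevalence = 0.195,
                       persistent_early_share = 59 / 105,
                       rrt_prevalence = 0.05,
                       death7_prevalence = 0.126,
                       death7_given_aki72 = 0.337,
                       covid_share = 0.816,
                       baseline_cr_meanlog = log(0.88),
                       baseline_cr_sdlog = 0.41,
                       cr_noise_sdlog = 0.08,
                       day1_mult_meanlog = log(1.25),
                       day1_mult_sdlog = 0.3,
                       transient_peak_mult = 2.4,
                       persistent_peak_mult = 2.6,
                       mv_prob = c(no_aki = 0.226, aki = 0.478),
                       vad_prob = c(no_aki = 0.164, aki = 0.272),
                       hyperbili_prob = c(no_aki = 0.0045, aki = 0.022),
                       abx48_prob = 0.608,
                       sofa_rise_prob = c(no_aki = 0.15, aki = 0.45),
                       sofa0_meanlog = c(no_aki = log(3), aki = log(6)),
                       sofa0_sdlog = 0.55,
                       apache_mean = c(no_aki = 12.5, aki = 19),
                       apache_sd = c(no_aki = 6.5, aki = 8),
                       age_mean = c(no_aki = 61, aki = 66),
                       age_sd = 16,
                       uo_windows_per_day = 4L,
                       uo_meanlog = log(1.05),
                       uo_sdlog = 0.3,
                       oliguria_share = 0.35,
                       oliguria_meanlog = log(0.40),
                       oliguria_sdlog = 0.15,
                       los_meanlog = log(7),
                       los_sdlog = 0.55,
                       max_day = 14L,
                       rrt_missing_rate = 1 / 538,
                       violation_fraction = 0) {
  cfg <- as.list(environment())
  rates <- c(aki72_prevalence, persistent_prevalence, persistent_early_share,
             rrt_prevalence, death7_prevalence, death7_given_aki72,
             covid_share, abx48_prob, mv_prob, vad_prob, hyperbili_prob,
             sofa_rise_prob, oliguria_share, rrt_missing_rate,
             violation_fraction)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1)) {
    pari_abort("all rates/probabilities must lie in [0, 1].", "config")
  }
  if (n_patients < 0) pari_abort("`n_patients` must be >= 0.", "config")
  p_pe <- persistent_prevalence * persistent_early_share
  p_pl <- persistent_prevalence - p_pe
  p_tr <- aki72_prevalence - p_pe
  p_none <- 1 - aki72_prevalence - p_pl
  if (p_tr < 0 || p_none < 0) {
    pari_abort("inconsistent prevalence targets: transient or unaffected class probability is negative.",
               "config")
  }
  if (rrt_prevalence > persistent_prevalence) {
    pari_abort("`rrt_prevalence` cannot exceed `persistent_prevalence` (RRT is assigned within persistent classes).",
               "config")
  }
  d_none <- (death7_prevalence - aki72_prevalence * death7_given_aki72) / p_none
  if (d_none < 0 || d_none > 1) {
    pari_abort("death targets are inconsistent: derived no-AKI death probability is outside [0, 1].",
               "config")
  }
  cfg$class_probs <- c(none = p_none, transient = p_tr,
                       persistent_early = p_pe, persistent_late = p_pl)
  cfg$rrt_given_persistent <- if (persistent_prevalence > 0) {
    rrt_prevalence / persistent_prevalence
  } else 0
  cfg$death_prob <- c(none = d_none, transient = death7_given_aki72,
                      persistent_early = death7_given_aki72,
                      persistent_late = 0)
  structure(cfg, class = "pari_sim_config")
}

# Class-specific multiplicative creatinine drift profile.
class_multiplier <- function(class, day, m1, cfg) {
  tp <- cfg$transient_peak_mult
  pp <- cfg$persistent_peak_mult
  out <- rep(1, length(day))
  tr <- class == "transient"
  out[tr & day == 1] <- m1[tr & day == 1]
  out[tr & day %in% 2:3] <- tp
  out[tr & day == 4] <- 1.4
  out[tr & day >= 5] <- 1.1
  pe <- class == "persistent_early"
  out[pe & day == 1] <- m1[pe & day == 1]
  out[pe & day %in% 2:7] <- pp
  out[pe & day %in% 8:9] <- 1.6
  out[pe & day >= 10] <- 1.2
  pl <- class == "persistent_late"
  out[pl & day == 1] <- 1.1
  out[pl & day == 2] <- 1.2
  out[pl & day == 3] <- 1.4
  out[pl & day %in% 4:8] <- pp
  out[pl & day %in% 9:10] <- 1.8
  out[pl & day >= 11] <- 1.3
  out
}

empty_cohort <- function(config) {
  list(
    admission = tibble(patient_id = character(), age = numeric(),
                       sex = character(), apache2 = numeric(),
                       covid_confirmed = logical(), heart_disease = logical(),
                       hypertension = logical(), diabetes = logical(),
                       obesity = logical(), icu_los_hours = numeric(),
                       death_day = integer(), known_ckd = logical()),
    daily = tibble(patient_id = character(), day_index = integer(),
                   creatinine_mg_dl = numeric(), uo_ml_kg_h = numeric(),
                   uo_window_h = numeric(), rrt = logical(), mv = logical(),
                   vad = logical(), bilirubin_mg_dl = numeric(),
                   antibiotics = logical(), sofa = numeric()),
    truth = tibble(patient_id = character(), latent_class = character(),
                   rrt_assigned = logical(), oliguric = logical(),
                   death_day = integer(),
                   intended_violation = character()),
    config = config
  )
}

#' Generate a synthetic ICU cohort
#'
#' Draws a latent renal-trajectory class per patient, then emits an admission
#' table, a daily observation table (one row per urine-output window) and a
#' ground-truth table. Trajectories are rejection-sampled so that no
#' screening creatinine (days 0-3) exceeds 4 mg/dL: the generator emulates
#' the analyzed, post-eligibility population whose marginal rates the
#' defaults target. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return List of class `pari_cohort` with elements `admission`, `daily`,
#'   `truth` and `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "pari_sim_config")) {
    pari_abort("`config` must come from sim_config().", "config")
  }
  set.seed(config$seed)
  n <- config$n_patients
  if (n == 0) return(structure(empty_cohort(config), class = "pari_cohort"))

  ids <- sprintf("P%05d", seq_len(n))
  cls <- sample(names(config$class_probs), n, replace = TRUE,
                prob = config$class_probs)
  aki <- cls %in% c("transient", "persistent_early")
  grp <- if_else(aki, "aki", "no_aki")

  baseline <- rlnorm(n, config$baseline_cr_meanlog, config$baseline_cr_sdlog)
  covid <- runif(n) < config$covid_share
  mv <- runif(n) < config$mv_prob[grp]
  vad <- runif(n) < config$vad_prob[grp]
  hyperbili <- runif(n) < config$hyperbili_prob[grp]
  abx48 <- runif(n) < config$abx48_prob
  sofa0 <- pmin(24, round(rlnorm(n, config$sofa0_meanlog[grp], config$sofa0_sdlog)))
  sofa_rise <- runif(n) < config$sofa_rise_prob[grp]
  sofa_delta <- if_else(sofa_rise, sample(2:4, n, replace = TRUE),
                        sample(-1:1, n, replace = TRUE))
  sofa1 <- pmin(24, pmax(0, sofa0 + sofa_delta))
  apache <- pmin(71, pmax(0, round(rnorm(n, config$apache_mean[grp],
                                         config$apache_sd[grp]))))
  age <- pmax(18, pmin(100, round(rnorm(n, config$age_mean[grp], config$age_sd))))
  sex <- if_else(runif(n) < 0.548, "male", "female")
  rrt_assigned <- cls %in% c("persistent_early", "persistent_late") &
    runif(n) < config$rrt_given_persistent
  oliguric <- aki & runif(n) < config$oliguria_share
  oliguric <- oliguric | (cls == "persistent_late" &
                            runif(n) < config$oliguria_share)

  dies <- runif(n) < config$death_prob[cls]
  death_day <- rep(NA_integer_, n)
  death_day[dies & cls %in% c("none", "transient")] <-
    sample(3:7, sum(dies & cls %in% c("none", "transient")), replace = TRUE)
  death_day[dies & cls == "persistent_early"] <-
    sample(6:7, sum(dies & cls == "persistent_early"), replace = TRUE)
  min_stay <- c(none = 3L, transient = 3L, persistent_early = 6L,
                persistent_late = 8L)[cls]
  discharge <- pmax(min_stay,
                    pmin(config$max_day,
                         round(rlnorm(n, config$los_meanlog, config$los_sdlog))))
  last_day <- if_else(!is.na(death_day), as.numeric(death_day),
                      as.numeric(discharge))

  counts <- as.integer(last_day) + 1L
  pid_idx <- rep(seq_len(n), counts)
  day <- sequence(counts) - 1L
  m1 <- rep(1, n)
  m1[aki] <- rlnorm(sum(aki), config$day1_mult_meanlog, config$day1_mult_sdlog)
  mult <- class_multiplier(cls[pid_idx], day, m1[pid_idx], config)
  cr <- baseline[pid_idx] * mult * exp(rnorm(length(day), 0, config$cr_noise_sdlog))

  # Condition on the eligibility screen: redraw patients whose creatinine
  # exceeds 4 mg/dL anywhere on days 0-3.
  for (iter in 1:100) {
    bad <- unique(pid_idx[day <= 3 & cr > 4])
    if (!length(bad)) break
    baseline[bad] <- rlnorm(length(bad), config$baseline_cr_meanlog,
                            config$baseline_cr_sdlog)
    rows <- pid_idx %in% bad
    cr[rows] <- baseline[pid_idx[rows]] * mult[rows] *
      exp(rnorm(sum(rows), 0, config$cr_noise_sdlog))
  }
  if (length(unique(pid_idx[day <= 3 & cr > 4]))) {
    cr[day <= 3 & cr > 4] <- 3.95
  }

  rrt_day <- (cls[pid_idx] == "persistent_early" & rrt_assigned[pid_idx] &
                day %in% 4:6) |
             (cls[pid_idx] == "persistent_late" & rrt_assigned[pid_idx] &
                day %in% 5:7)
  sofa_day <- if_else(day == 0L, as.numeric(sofa0[pid_idx]),
                      if_else(day == 1L, as.numeric(sofa1[pid_idx]),
                              pmin(24, pmax(0, sofa1[pid_idx] +
                                              round(rnorm(length(day), 0, 1.2))))))
  abx_day <- (day <= 1L & abx48[pid_idx]) | (day >= 2L & runif(length(day)) < 0.35)
  bili_day <- if_else(day == 0L,
                      if_else(hyperbili[pid_idx],
                              runif(length(day), 2, 6),
                              pmin(1.9, rlnorm(length(day), log(0.6), 0.4))),
                      NA_real_)
  rrt_rec <- rep(TRUE, length(day))
  rrt_unrecorded <- runif(n) < config$rrt_missing_rate & !rrt_assigned
  rrt_col <- if_else(rrt_unrecorded[pid_idx] & day >= 4L, NA, rrt_day)

  w <- config$uo_windows_per_day
  wh <- 24 / w
  nw <- length(day) * w
  row_idx <- rep(seq_along(day), each = w)
  olig_day <- oliguric[pid_idx] & mult >= 2
  uo_rate <- if_else(olig_day[row_idx],
                     rlnorm(nw, config$oliguria_meanlog, config$oliguria_sdlog),
                     rlnorm(nw, config$uo_meanlog, config$uo_sdlog))

  daily <- tibble(
    patient_id = ids[pid_idx][row_idx],
    day_index = day[row_idx],
    creatinine_mg_dl = cr[row_idx],
    uo_ml_kg_h = uo_rate,
    uo_window_h = wh,
    rrt = rrt_col[row_idx],
    mv = mv[pid_idx][row_idx],
    vad = vad[pid_idx][row_idx],
    bilirubin_mg_dl = bili_day[row_idx],
    antibiotics = abx_day[row_idx],
    sofa = sofa_day[row_idx]
  )
  admission <- tibble(
    patient_id = ids, age = age, sex = sex, apache2 = apache,
    covid_confirmed = covid,
    heart_disease = runif(n) < 0.195,
    hypertension = runif(n) < 0.494,
    diabetes = runif(n) < 0.31,
    obesity = runif(n) < 0.385,
    icu_los_hours = if_else(!is.na(death_day), 24 * last_day + 8,
                            24 * last_day + 12),
    death_day = death_day,
    known_ckd = FALSE
  )
  truth <- tibble(
    patient_id = ids, latent_class = cls, rrt_assigned = rrt_assigned,
    oliguric = oliguric, death_day = death_day,
    intended_violation = NA_character_
  )
  structure(list(admission = admission, daily = daily, truth = truth,
                 config = config),
            class = "pari_cohort")
}

#' Mutate a fraction of records to violate exactly one eligibility rule each
#'
#' Selected patients are altered to trip a single exclusion rule (cycling
#' through missing mandatory renal data, short ICU stay, death before 72 h,
#' screening creatinine above 4 mg/dL, and known chronic kidney disease),
#' and the intended violation is recorded in the ground-truth table so
#' filter-audit tests can verify that [apply_eligibility()] removes exactly
#' these records for exactly these reasons.
#'
#' @param cohort A `pari_cohort` from [generate_cohort()].
#' @param fraction Fraction of patients to mutate (defaults to
#'   `config$violation_fraction`).
#' @param seed Seed for violator selection (defaults to `config$seed + 1000`).
#' @return The mutated cohort (same structure).
#' @export
inject_exclusion_violations <- function(cohort, fraction = NULL, seed = NULL) {
  if (!inherits(cohort, "pari_cohort")) {
    pari_abort("`cohort` must come from generate_cohort().", "config")
  }
  cfg <- cohort$config
  if (is.null(fraction)) fraction <- cfg$violation_fraction
  if (!is.finite(fraction) || fraction < 0 || fraction > 1) {
    pari_abort("`fraction` must lie in [0, 1].", "config")
  }
  if (is.null(seed)) seed <- cfg$seed + 1000L
  n <- nrow(cohort$admission)
  k <- round(fraction * n)
  if (k == 0) return(cohort)
  set.seed(seed)
  violators <- sample(cohort$admission$patient_id, k)
  types <- rep_len(exclusion_reasons, k)
  adm <- cohort$admission
  daily <- cohort$daily
  truth <- cohort$truth
  truth$intended_violation[match(violators, truth$patient_id)] <- types

  miss <- violators[types == "missing_mandatory_renal_data"]
  if (length(miss)) {
    subtype <- rep_len(c("cr_24h", "uo_72h", "rrt_0h"), length(miss))
    blank_cr <- daily$patient_id %in% miss[subtype == "cr_24h"] & daily$day_index == 1L
    daily$creatinine_mg_dl[blank_cr] <- NA_real_
    blank_uo <- daily$patient_id %in% miss[subtype == "uo_72h"] & daily$day_index == 3L
    daily$uo_ml_kg_h[blank_uo] <- NA_real_
    blank_rrt <- daily$patient_id %in% miss[subtype == "rrt_0h"] & daily$day_index == 0L
    daily$rrt[blank_rrt] <- NA
  }
  short <- violators[types == "icu_stay_lt_72h"]
  if (length(short)) {
    daily <- daily[!(daily$patient_id %in% short & daily$day_index > 1L), ]
    i <- match(short, adm$patient_id)
    adm$icu_los_hours[i] <- 48
    adm$death_day[i] <- NA_integer_
  }
  early_death <- violators[types == "death_lt_72h"]
  if (length(early_death)) {
    daily <- daily[!(daily$patient_id %in% early_death & daily$day_index > 1L), ]
    i <- match(early_death, adm$patient_id)
    adm$icu_los_hours[i] <- 32
    adm$death_day[i] <- 1L
  }
  high_cr <- violators[types == "creatinine_gt_4"]
  if (length(high_cr)) {
    rows <- daily$patient_id %in% high_cr & daily$day_index == 0L
    bump <- 4.5 + runif(length(high_cr), 0, 1.5)
    daily$creatinine_mg_dl[rows] <-
      bump[match(daily$patient_id[rows], high_cr)]
  }
  ckd <- violators[types == "known_ckd"]
  adm$known_ckd[adm$patient_id %in% ckd] <- TRUE

  structure(list(admission = adm, daily = daily, truth = truth, config = cfg),
            class = "pari_cohort")
}
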