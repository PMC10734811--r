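#' Run the full diagnostic-accuracy suite
#'
#' For each outcome and each predictor: empirical AUC with DeLong 95% CI.
#' For each outcome: a paired DeLong comparison of the reference predictor
#' (PARI by default) against every other predictor, the Youden-optimal
#' reference cutoff, and 2x2 metrics for the reference predictor at the
#' Youden cutoff and at the configured fixed cutoffs (4, 6 and 8 by
#' default, matching the ">= cutoff" positivity convention). Missing
#' outcomes and predictor values are handled pairwise per analysis: each
#' AUC/comparison uses the patients complete for exactly the variables it
#' needs. An outcome with fewer than two events (or two non-events) is
#' skipped with a warning.
#'
#' @param data Tibble with one row per patient holding predictor and outcome
#'   columns (e.g. the join of [score_patients()] and [derive_outcomes()]).
#' @param predictors Character vector of predictor column names.
#' @param outcomes Character vector of logical outcome column names.
#' @param reference Predictor compared against the others and used for
#'   cutoff analyses.
#' @param cutoffs Fixed thresholds for the reference predictor.
#' @return Object of class `pari_accuracy_suite`: list of tibbles `auc`
#'   (outcome, predictor, auc, ci_lo, ci_hi, n, n_pos), `delong` (outcome,
#'   predictor, auc_ref, auc, z, p_vs_ref, n), `youden` (outcome, cutoff, j)
#'   and `cutoffs` (outcome, cutoff, counts and metric rows in percent).
#' @export
run_accuracy_suite <- function(data,
                               predictors = c("pari", "delta_cr", "sofa", "apache2"),
                               outcomes = c("aki_72h", "persistent_aki_7d",
                                            "rrt_7d", "death_7d"),
                               reference = "pari",
                               cutoffs = c(4, 6, 8)) {
  stopifnot(reference %in% predictors)
  missing_cols <- setdiff(c(predictors, outcomes), names(data))
  if (length(missing_cols)) {
    pari_abort(paste0("`data` lacks column(s): ",
                      paste(missing_cols, collapse = ", ")), "schema")
  }
  if (is.unsorted(cutoffs) || any(cutoffs <= 0)) {
    pari_abort("`cutoffs` must be positive and sorted.", "config")
  }
  auc_rows <- list()
  dl_rows <- list()
  yj_rows <- list()
  ct_rows <- list()
  for (oc in outcomes) {
    y_all <- data[[oc]]
    usable <- !is.na(y_all)
    if (sum(y_all[usable]) < 2 || sum(!y_all[usable]) < 2) {
      warn(sprintf("outcome `%s` has fewer than 2 events or 2 non-events; skipped.", oc))
      next
    }
    for (pr in predictors) {
      keep <- usable & !is.na(data[[pr]])
      r <- empirical_auc(data[[pr]][keep], y_all[keep], predictor = pr)
      auc_rows[[length(auc_rows) + 1L]] <- tibble(
        outcome = oc, predictor = pr, auc = r$auc,
        ci_lo = r$ci95[1], ci_hi = r$ci95[2],
        n = sum(keep), n_pos = r$n_pos
      )
    }
    for (pr in setdiff(predictors, reference)) {
      keep <- usable & !is.na(data[[reference]]) & !is.na(data[[pr]])
      cmp <- delong_test(data[[reference]][keep], data[[pr]][keep],
                         y_all[keep], names = c(reference, pr))
      dl_rows[[length(dl_rows) + 1L]] <- tibble(
        outcome = oc, predictor = pr, auc_ref = cmp$auc_a, auc = cmp$auc_b,
        z = cmp$z, p_vs_ref = cmp$p, n = sum(keep)
      )
    }
    keep <- usable & !is.na(data[[reference]])
    yj <- youden_cutoff(data[[reference]][keep], y_all[keep])
    yj_rows[[length(yj_rows) + 1L]] <- tibble(outcome = oc, cutoff = yj$cutoff,
                                              j = yj$j)
    for (ct in unique(c(yj$cutoff, cutoffs))) {
      cm <- confusion_at_cutoff(data[[reference]][keep], y_all[keep], ct)
      ct_rows[[length(ct_rows) + 1L]] <- cm$metrics |>
        mutate(outcome = oc, cutoff = ct, tp = cm$tp, fp = cm$fp,
               fn = cm$fn, tn = cm$tn, at_youden = ct == yj$cutoff) |>
        select("outcome", "cutoff", "at_youden", "tp", "fp", "fn", "tn",
               "metric", "estimate", "ci_lo", "ci_hi")
    }
  }
  structure(
    list(
      auc = bind_rows(auc_rows), delong = bind_rows(dl_rows),
      youden = bind_rows(yj_rows), cutoffs = bind_rows(ct_rows),
      reference = reference
    ),
    class = "pari_accuracy_suite"
  )
}

#' @export
print.pari_accuracy_suite <- function(x, ...) {
  cat("Diagnostic accuracy suite (reference predictor:", x$reference, ")\n\n")
  cat("AUCs:\n")
  print(as.data.frame(x$auc), digits = 3, row.names = FALSE)
  cat("\nPaired DeLong comparisons vs", x$reference, ":\n")
  print(as.data.frame(x$delong), digits = 3, row.names = FALSE)
  cat("\nYouden-optimal cutoffs:\n")
  print(as.data.frame(x$youden), digits = 3, row.names = FALSE)
  invisible(x)
}
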