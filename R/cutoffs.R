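#' Youden-optimal cutoff
#'
#' Evaluates Youden's J (sensitivity + specificity - 1) at every distinct
#' observed score used as a "positive if score >= cutoff" threshold and
#' returns the maximizer; ties are broken toward the smallest cutoff. Only
#' observed values can change the empirical J, so the scan over observed
#' scores is an exhaustive search over all real thresholds.
#'
#' @inheritParams empirical_auc
#' @return Object of class `youden_result`: list with `cutoff` and `j`
#'   (J on the 0-1 scale).
#' @export
youden_cutoff <- function(scores, labels) {
  if (!is.numeric(scores) || any(!is.finite(scores))) {
    pari_abort("`scores` must be finite numerics.", "invalid_input")
  }
  labels <- check_labels(labels)
  cand <- sort(unique(scores))
  pos <- scores[labels]
  neg <- scores[!labels]
  j <- vapply(cand, function(ct) mean(pos >= ct) + mean(neg < ct) - 1,
              numeric(1))
  best <- which.max(j) # first maximum = smallest cutoff on the sorted grid
  structure(list(cutoff = cand[best], j = j[best]), class = "youden_result")
}

#' @export
print.youden_result <- function(x, ...) {
  cat(sprintf("Youden-optimal cutoff: >= %g (J = %.3f)\n", x$cutoff, x$j))
  invisible(x)
}

wald_ci <- function(k, n) {
  if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
  p <- k / n
  half <- qnorm(0.975) * sqrt(p * (1 - p) / n)
  100 * c(p, max(0, p - half), min(1, p + half))
}

#' 2x2 diagnostic metrics at a fixed cutoff
#'
#' Classifies patients as test-positive when `score >= cutoff`, tabulates the
#' 2x2 confusion counts against the outcome, and reports sensitivity,
#' specificity, positive and negative predictive values and accuracy as
#' percentages with Wald 95% confidence intervals
#' (`p +/- 1.96 sqrt(p(1-p)/n)` on each metric's own denominator, clipped to
#' `[0, 100]`). A metric whose denominator is empty (e.g. PPV with no
#' test-positives) is reported as `NA`, not 0. Rows with missing labels are
#' dropped first.
#'
#' @inheritParams empirical_auc
#' @param cutoff Finite threshold; positivity is `score >= cutoff`.
#' @return Object of class `cutoff_metrics`: list with `cutoff`, counts
#'   (`tp`, `fp`, `fn`, `tn`, `n_pos`, `n_neg`) and `metrics`, a tibble
#'   (`metric`, `estimate`, `ci_lo`, `ci_hi`) in percent.
#' @examples
#' s <- c(rep(8, 85), rep(1, 453))
#' y <- c(rep(TRUE, 37), rep(FALSE, 48), rep(TRUE, 55), rep(FALSE, 398))
#' confusion_at_cutoff(s, y, 8)
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || !is.finite(cutoff)) {
    pari_abort("`cutoff` must be a single finite number.", "invalid_input")
  }
  keep <- !is.na(labels)
  scores <- scores[keep]
  labels <- check_labels(labels[keep])
  pos_test <- scores >= cutoff
  tp <- sum(pos_test & labels)
  fp <- sum(pos_test & !labels)
  fn <- sum(!pos_test & labels)
  tn <- sum(!pos_test & !labels)
  rows <- list(
    sensitivity = wald_ci(tp, tp + fn),
    specificity = wald_ci(tn, tn + fp),
    ppv = wald_ci(tp, tp + fp),
    npv = wald_ci(tn, tn + fn),
    accuracy = wald_ci(tp + tn, tp + fp + fn + tn)
  )
  metrics <- tibble(
    metric = names(rows),
    estimate = unname(vapply(rows, `[`, numeric(1), 1)),
    ci_lo = unname(vapply(rows, `[`, numeric(1), 2)),
    ci_hi = unname(vapply(rows, `[`, numeric(1), 3))
  )
  structure(
    list(cutoff = cutoff, tp = tp, fp = fp, fn = fn, tn = tn,
         n_pos = tp + fn, n_neg = fp + tn, metrics = metrics),
    class = "cutoff_metrics"
  )
}

#' @export
print.cutoff_metrics <- function(x, ...) {
  cat(sprintf("Cutoff >= %g: TP %d FP %d FN %d TN %d\n",
              x$cutoff, x$tp, x$fp, x$fn, x$tn))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-11s %5.1f%% (95%% CI %.1f - %.1f)\n", m$metric[i],
                m$estimate[i], m$ci_lo[i], m$ci_hi[i]))
  }
  invisible(x)
}
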