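check_labels <- function(labels) {
  labels <- as.logical(labels)
  if (anyNA(labels)) {
    pari_abort("`labels` must be TRUE/FALSE without missing values (drop missing outcomes first).",
               "invalid_input")
  }
  if (!any(labels) || all(labels)) {
    pari_abort("both outcome classes are required (at least one positive and one negative).",
               "degenerate_labels")
  }
  labels
}

# Midrank placement values (DeLong): for each positive the fraction of
# negatives it beats (ties count half), and symmetrically for negatives.
delong_placements <- function(scores, labels) {
  x <- scores[labels]
  y <- scores[!labels]
  m <- length(x)
  n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(x, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y, ties.method = "average")) / m
  list(v10 = v10, v01 = v01, m = m, n = n, auc = mean(v10))
}

#' Empirical AUC with DeLong variance and confidence interval
#'
#' The area under the empirical ROC curve equals the tie-corrected
#' concordance probability `P(score_pos > score_neg) + 0.5 P(equal)`,
#' computed by midranks. The variance is the DeLong estimate from placement
#' values, and the 95% CI is `auc +/- 1.96 sqrt(var)` clipped to `[0, 1]`.
#'
#' @param scores Numeric predictor values (finite).
#' @param labels Logical outcome (TRUE = event). Both classes must occur.
#' @param predictor Optional display name.
#' @return Object of class `roc_result`: list with `predictor`, `auc`,
#'   `variance`, `ci95` (length-2), `n_pos`, `n_neg`.
#' @examples
#' empirical_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc # 1
#' @export
empirical_auc <- function(scores, labels, predictor = "score") {
  if (!is.numeric(scores) || any(!is.finite(scores))) {
    pari_abort("`scores` must be finite numerics.", "invalid_input")
  }
  labels <- check_labels(labels)
  if (length(scores) != length(labels)) {
    pari_abort("`scores` and `labels` must be the same length.", "invalid_input")
  }
  pl <- delong_placements(scores, labels)
  s10 <- if (pl$m > 1) var(pl$v10) else 0
  s01 <- if (pl$n > 1) var(pl$v01) else 0
  v <- s10 / pl$m + s01 / pl$n
  ci <- pmin(1, pmax(0, pl$auc + c(-1, 1) * qnorm(0.975) * sqrt(v)))
  structure(
    list(predictor = predictor, auc = pl$auc, variance = v, ci95 = ci,
         n_pos = pl$m, n_neg = pl$n),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC (%s): AUC %.3f (95%% CI %.3f - %.3f), %d events / %d non-events\n",
              x$predictor, x$auc, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Paired DeLong test comparing two correlated AUCs
#'
#' Compares the AUCs of two predictors measured on the same patients for the
#' same outcome, using the DeLong variance-covariance of the placement
#' values: `z = (auc_a - auc_b) / sqrt(var_a + var_b - 2 cov_ab)` with a
#' two-sided normal p-value. Identical predictors give `z = 0`, `p = 1`.
#'
#' @param scores_a,scores_b Aligned numeric predictor vectors.
#' @param labels Logical outcome vector; both classes must occur.
#' @param names Character pair naming the predictors.
#' @return Object of class `delong_comparison`: list with `predictor_a`,
#'   `predictor_b`, `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels, names = c("a", "b")) {
  labels <- check_labels(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    pari_abort("score vectors and labels must be aligned.", "invalid_input")
  }
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  if (isTRUE(all.equal(scores_a, scores_b))) {
    out <- list(predictor_a = names[1], predictor_b = names[2],
                auc_a = pa$auc, auc_b = pb$auc, z = 0, p = 1)
    return(structure(out, class = "delong_comparison"))
  }
  va <- var(pa$v10) / pa$m + var(pa$v01) / pa$n
  vb <- var(pb$v10) / pb$m + var(pb$v01) / pb$n
  cab <- stats::cov(pa$v10, pb$v10) / pa$m + stats::cov(pa$v01, pb$v01) / pa$n
  vd <- va + vb - 2 * cab
  d <- pa$auc - pb$auc
  if (vd <= .Machine$double.eps) {
    if (abs(d) < sqrt(.Machine$double.eps)) {
      z <- 0
    } else {
      pari_abort("variance of the AUC difference is zero while the AUCs differ.",
                 "degenerate_variance")
    }
  } else {
    z <- d / sqrt(vd)
  }
  structure(
    list(predictor_a = names[1], predictor_b = names[2],
         auc_a = pa$auc, auc_b = pb$auc, z = z, p = 2 * pnorm(-abs(z))),
    class = "delong_comparison"
  )
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("DeLong: AUC(%s) %.3f vs AUC(%s) %.3f, z = %.3f, p = %.4g\n",
              x$predictor_a, x$auc_a, x$predictor_b, x$auc_b, x$z, x$p))
  invisible(x)
}
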