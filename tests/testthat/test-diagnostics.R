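test_that("empirical AUC handles ties, separation and matches pair counting", {
  expect_equal(empirical_auc(rep(3, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_equal(empirical_auc(c(1, 2, 3, 10, 11), c(F, F, F, T, T))$auc, 1)
  set.seed(101)
  for (i in 1:60) {
    n <- sample(8:60, 1)
    scores <- if (i %% 2) rnorm(n) else sample(0:6, n, replace = TRUE)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    expect_equal(empirical_auc(scores, labels)$auc, pair_auc(scores, labels))
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(102)
  scores <- rnorm(80)
  labels <- runif(80) < 0.4
  a0 <- empirical_auc(scores, labels)$auc
  expect_equal(empirical_auc(exp(scores), labels)$auc, a0)
  expect_equal(empirical_auc(rank(scores), labels)$auc, a0)
  expect_equal(empirical_auc(scores^3 + 5 * scores, labels)$auc, a0)
})

test_that("AUC variance and CI agree with the reference DeLong implementation", {
  skip_if_not_installed("pROC")
  set.seed(103)
  scores <- c(rnorm(50, 1), rnorm(70))
  labels <- rep(c(TRUE, FALSE), c(50, 70))
  r <- empirical_auc(scores, labels)
  pr <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)))
  expect_equal(r$variance, as.numeric(pROC::var(pr, method = "delong")))
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(r$ci95, ci[c(1, 3)], tolerance = 1e-8)
})

test_that("degenerate label sets are rejected", {
  expect_error(empirical_auc(1:4, rep(TRUE, 4)),
               class = "pariscore_error_degenerate_labels")
  expect_error(empirical_auc(1:4, rep(FALSE, 4)),
               class = "pariscore_error_degenerate_labels")
  expect_error(youden_cutoff(1:4, rep(TRUE, 4)),
               class = "pariscore_error_degenerate_labels")
})

test_that("paired DeLong test is antisymmetric and exact under identity", {
  set.seed(104)
  y <- runif(120) < 0.35
  a <- rnorm(120) + y
  b <- 0.5 * a + rnorm(120, sd = 0.8) + 0.3 * y
  ab <- delong_test(a, b, y)
  ba <- delong_test(b, a, y)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  same <- delong_test(a, a, y)
  expect_identical(same$p, 1)
  expect_identical(same$z, 0)
})

test_that("paired DeLong p-value matches the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(105)
  y <- rep(c(TRUE, FALSE), c(45, 75))
  a <- rnorm(120) + 0.9 * y
  b <- 0.6 * a + rnorm(120, sd = 0.9) + 0.4 * y
  got <- delong_test(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                        pROC::roc(y, b, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(got$p, as.numeric(ref$p.value))
  expect_equal(abs(got$z), abs(as.numeric(ref$statistic)))
})

test_that("Youden scan equals exhaustive threshold search", {
  set.seed(106)
  grid_j <- function(scores, labels, cutoff) {
    mean(scores[labels] >= cutoff) + mean(scores[!labels] < cutoff) - 1
  }
  for (i in 1:40) {
    n <- sample(10:80, 1)
    support <- enumerate_pari_support()
    scores <- sample(support, n, replace = TRUE,
                     prob = rev(seq_along(support)))
    labels <- runif(n) < stats::plogis(scale(scores))
    if (!any(labels) || all(labels)) next
    got <- youden_cutoff(scores, labels)
    # exhaustive search over every real threshold: midpoints, observed
    # values and sentinels beyond the range
    cand <- sort(unique(c(scores, scores - 0.5, min(scores) - 1,
                          max(scores) + 1)))
    j_all <- vapply(cand, function(ct) grid_j(scores, labels, ct), numeric(1))
    expect_equal(got$j, max(j_all))
    expect_equal(grid_j(scores, labels, got$cutoff), got$j)
    # ties break toward the smallest observed cutoff
    obs_j <- vapply(sort(unique(scores)),
                    function(ct) grid_j(scores, labels, ct), numeric(1))
    expect_identical(got$cutoff,
                     sort(unique(scores))[which.max(obs_j)])
  }
  # perfect separation: J = 1 at the smallest positive-group score
  got <- youden_cutoff(c(1, 2, 3, 10, 12), c(F, F, F, T, T))
  expect_identical(got$cutoff, 10)
  expect_identical(got$j, 1)
})

test_that("confusion counts are conserved and CIs are Wald", {
  set.seed(107)
  scores <- sample(0:20, 200, replace = TRUE)
  labels <- runif(200) < 0.3
  cm <- confusion_at_cutoff(scores, labels, 8)
  expect_identical(cm$tp + cm$fp + cm$fn + cm$tn, 200L)
  expect_identical(cm$tp + cm$fn, sum(labels))
  sens <- cm$tp / (cm$tp + cm$fn)
  half <- 1.96 * sqrt(sens * (1 - sens) / (cm$tp + cm$fn))
  row <- cm$metrics[cm$metrics$metric == "sensitivity", ]
  expect_equal(row$estimate, 100 * sens)
  expect_equal(row$ci_lo, 100 * (sens - half), tolerance = 1e-4)
  expect_equal(row$ci_hi, 100 * (sens + half), tolerance = 1e-4)
})

test_that("extreme cutoffs yield boundary metrics and NA for empty denominators", {
  scores <- c(1, 2, 5, 9)
  labels <- c(FALSE, TRUE, FALSE, TRUE)
  lo <- confusion_at_cutoff(scores, labels, 0)
  expect_equal(lo$metrics$estimate[lo$metrics$metric == "sensitivity"], 100)
  expect_equal(lo$metrics$estimate[lo$metrics$metric == "specificity"], 0)
  expect_true(is.na(lo$metrics$estimate[lo$metrics$metric == "npv"]))
  hi <- confusion_at_cutoff(scores, labels, 100)
  expect_true(is.na(hi$metrics$estimate[hi$metrics$metric == "ppv"]))
  expect_equal(hi$metrics$estimate[hi$metrics$metric == "specificity"], 100)
})

test_that("the suite runs per outcome with pairwise-complete missingness", {
  set.seed(108)
  n <- 300
  pari <- sample(enumerate_pari_support(), n, replace = TRUE)
  data <- tibble::tibble(
    patient_id = sprintf("S%03d", 1:n),
    pari = as.numeric(pari),
    delta_cr = rnorm(n, 0.05, 0.15) + 0.002 * pari,
    sofa = pmin(20, pmax(0, round(rnorm(n, 4, 3)))),
    apache2 = pmin(40, pmax(0, round(rnorm(n, 13, 6)))),
    aki_72h = runif(n) < stats::plogis(-2 + 0.08 * pari),
    persistent_aki_7d = runif(n) < 0.2,
    rrt_7d = ifelse(runif(n) < 0.02, NA, runif(n) < 0.05),
    death_7d = runif(n) < 0.13
  )
  suite <- run_accuracy_suite(data)
  expect_identical(nrow(suite$auc), 16L) # 4 outcomes x 4 predictors
  expect_identical(nrow(suite$delong), 12L)
  n_rrt <- suite$auc$n[suite$auc$outcome == "rrt_7d"][1]
  expect_identical(n_rrt, sum(!is.na(data$rrt_7d)))
  expect_true(all(suite$auc$n[suite$auc$outcome == "aki_72h"] == n))
  # identical predictor duplicated -> p exactly 1
  data$pari_copy <- data$pari
  s2 <- run_accuracy_suite(data, predictors = c("pari", "pari_copy"),
                           outcomes = "aki_72h")
  expect_identical(s2$delong$p_vs_ref, 1)
  # an outcome with < 2 events is skipped with a warning
  data$rare <- c(TRUE, rep(FALSE, n - 1))
  expect_warning(s3 <- run_accuracy_suite(data, outcomes = c("aki_72h", "rare")),
                 "fewer than 2 events")
  expect_setequal(unique(s3$auc$outcome), "aki_72h")
})
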