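# Diagnostic performance: ROC/AUC identities, Youden cutoff, AUC bins,
# bootstrap coverage, Kruskal-Wallis with Dunn post hoc tests.

test_that("trapezoid and rank-statistic AUC agree on every instance", {
  set.seed(1)
  for (rep in 1:50) {
    n <- sample(6:30, 1)
    scores <- round(rnorm(n), sample(0:2, 1))   # ties included
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(labels) || !any(labels)) next
    expect_equal(auc_trapezoid(roc_curve(scores, labels)),
                 auc_rank(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  scores <- rnorm(40)
  labels <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_rank(scores, labels), ref, tolerance = 1e-10)
})

test_that("ROC curves are monotone staircases from (0,0) to (1,1)", {
  set.seed(3)
  scores <- rnorm(25)
  labels <- rep(c(TRUE, FALSE), length.out = 25)
  roc <- roc_curve(scores, labels)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  expect_error(roc_curve(scores, rep(TRUE, 25)), "both classes")
})

test_that("AUC bins map boundary values to the upper class", {
  expect_identical(classify_auc(0.97), "excellent")
  expect_identical(classify_auc(0.9), "excellent")
  expect_identical(classify_auc(0.85), "good")
  expect_identical(classify_auc(0.8), "good")
  expect_identical(classify_auc(0.75), "fair")
  expect_identical(classify_auc(0.65), "poor")
  expect_identical(classify_auc(0.55), "fail")
  expect_identical(classify_auc(0.5), "not discriminant")
  expect_identical(classify_auc(0.3), "not discriminant")
})

test_that("perfect separation gives AUC 1, J = 1 and infinite LR+", {
  scores <- c(1, 2, 3, 11, 12, 13)
  labels <- rep(c(FALSE, TRUE), each = 3)
  res <- roc_analysis(scores, labels, n_boot = 100, seed = 1)
  expect_equal(res$auc, 1)
  expect_identical(res$auc_class, "excellent")
  cut <- youden_cutoff(scores, labels)
  expect_equal(cut$youden_j, 1)
  expect_true(cut$cutoff > 3 && cut$cutoff <= 11)
  expect_identical(cut$lr_positive, Inf)
})

test_that("Youden cutoff equals exhaustive threshold search", {
  set.seed(4)
  for (rep in 1:20) {
    scores <- round(c(rnorm(4, 1), rnorm(4)), 1)
    labels <- rep(c(TRUE, FALSE), each = 4)
    cut <- youden_cutoff(scores, labels)
    # exhaustive oracle over all candidate thresholds
    cand <- sort(unique(scores))
    j <- vapply(cand, function(t) {
      mean(scores[labels] >= t) + mean(scores[!labels] < t) - 1
    }, numeric(1))
    expect_equal(cut$youden_j, max(j), tolerance = 1e-12)
    expect_equal(cut$cutoff, cand[which(j == max(j))[1]])  # tie -> lower
  }
})

test_that("LR+ is sensitivity over one minus specificity", {
  set.seed(5)
  scores <- c(rnorm(25, 1.5), rnorm(25))
  labels <- rep(c(TRUE, FALSE), each = 25)
  cut <- youden_cutoff(scores, labels)
  expect_equal(cut$lr_positive, cut$sensitivity / (1 - cut$specificity))
  # Clopper-Pearson CIs bracket the point estimates
  expect_true(cut$sensitivity_ci[1] <= cut$sensitivity &&
                cut$sensitivity >= 0 && cut$sensitivity_ci[2] >= cut$sensitivity)
})

test_that("bootstrap CI covers the true AUC in most replicates", {
  # normal shift model: true AUC = pnorm(delta / sqrt(2))
  delta <- 1
  true_auc <- pnorm(delta / sqrt(2))
  set.seed(6)
  covered <- vapply(1:100, function(b) {
    scores <- c(rnorm(25, delta), rnorm(25))
    labels <- rep(c(TRUE, FALSE), each = 25)
    ci <- roc_analysis(scores, labels, n_boot = 400, seed = b)$auc_ci
    ci[1] <= true_auc && true_auc <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("bootstrap and DeLong intervals roughly agree", {
  set.seed(7)
  scores <- c(rnorm(30, 1), rnorm(30))
  labels <- rep(c(TRUE, FALSE), each = 30)
  b <- roc_analysis(scores, labels, n_boot = 2000, seed = 1)
  d <- roc_analysis(scores, labels, ci_method = "delong")
  expect_equal(b$auc, d$auc)
  expect_lt(max(abs(b$auc_ci - d$auc_ci)), 0.05)
})

test_that("Kruskal-Wallis H matches the hand formula on a ranked toy", {
  values <- c(2.1, 2.5, 2.3, 3.1, 3.5, 3.3, 5.0, 5.2, 5.4)
  groups <- rep(c("a", "b", "c"), each = 3)
  res <- kruskal_dunn(values, groups)
  # textbook H = 12 / (N (N + 1)) * sum n_i Rbar_i^2 - 3 (N + 1), no ties
  r <- rank(values)
  rb <- tapply(r, groups, mean)
  H <- 12 / (9 * 10) * sum(3 * rb^2) - 3 * 10
  expect_equal(res$statistic, H, tolerance = 1e-10)
  expect_identical(nrow(res$pairwise), 3L)
})

test_that("identical groups give H ~ 0 and null pairwise tests", {
  values <- rep(c(1, 2, 3, 4), 3)
  groups <- rep(c("a", "b", "c"), each = 4)
  res <- kruskal_dunn(values, groups)
  expect_lt(res$statistic, 1e-10)
  expect_true(all(res$pairwise$p_adjusted > 0.9))
})

test_that("only the genuinely shifted pair is significant among four groups", {
  set.seed(8)
  values <- c(rnorm(12, 5), rnorm(12, 0.5), rnorm(12, 0.4), rnorm(12, 0.45))
  groups <- rep(c("MB", "control", "LGG", "other"), each = 12)
  res <- kruskal_dunn(values, groups)
  expect_lt(res$omnibus_p, 0.001)
  sig <- res$pairwise[res$pairwise$p_adjusted <= 0.05, ]
  expect_true(all(sig$group1 == "MB" | sig$group2 == "MB"))
  non_mb <- res$pairwise$group1 != "MB" & res$pairwise$group2 != "MB"
  expect_true(all(res$pairwise$p_adjusted[non_mb] > 0.05))
})

test_that("underpopulated groups are excluded with a warning", {
  expect_warning(res <- kruskal_dunn(c(1, 2, 3, 4, 9),
                                     c("a", "a", "b", "b", "c")),
                 "excluded: c")
  expect_identical(rownames(res$summaries), c("a", "b"))
  expect_error(suppressWarnings(kruskal_dunn(c(1, 2, 3), c("a", "a", "b"))),
               "at least 2 groups")
})

test_that("diagnostic summary reports medians and IQRs per group", {
  scores <- c(1.1, 1.4, 1.9, 1.2, 0.4, 0.5, 0.46, 0.3)
  labels <- rep(c(TRUE, FALSE), each = 4)
  s <- diagnostic_summary(scores, labels, n_boot = 100, seed = 1)
  expect_equal(s$group_summaries["positive", "median"],
               median(scores[1:4]))
  expect_equal(s$group_summaries["negative", "q1"],
               unname(quantile(scores[5:8], 0.25)))
  expect_s3_class(s, "diagnostic_summary")
})
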