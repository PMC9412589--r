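# Differential expression: Welch tests, presence filter, per-protein AUC,
# post-hoc power, volcano cutoff, compound criterion.

test_that("row-wise Welch tests match t.test on data with missing values", {
  set.seed(1)
  v <- matrix(rnorm(20 * 12, 25), 20, 12,
              dimnames = list(paste0("P", 1:20), paste0("s", 1:12)))
  v[sample(length(v), 30)] <- NA
  is_mb <- rep(c(FALSE, TRUE), each = 6)
  res <- row_welch_tests(v, is_mb)
  for (i in 1:20) {
    x <- v[i, !is_mb]; y <- v[i, is_mb]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) {
      expect_true(is.na(res$p[i]))
    } else {
      tt <- t.test(y, x)
      expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
      expect_equal(res$log2_fc[i], unname(diff(rev(tt$estimate))),
                   tolerance = 1e-10)
    }
  }
  # Student variant against var.equal = TRUE
  res_s <- row_welch_tests(v, is_mb, student = TRUE)
  i <- which(res$n_control >= 2 & res$n_mb >= 2)[1]
  x <- v[i, !is_mb]; y <- v[i, is_mb]
  tt <- t.test(y[!is.na(y)], x[!is.na(x)], var.equal = TRUE)
  expect_equal(res_s$p[i], tt$p.value, tolerance = 1e-10)
})

test_that("identical group values give t = 0 and p = 1", {
  v <- matrix(rep(c(1, 2, 3), 4), 1, 12)
  rownames(v) <- "P1"
  res <- row_welch_tests(v, rep(c(FALSE, TRUE), each = 6))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(res$log2_fc, 0)
})

test_that("planted fold changes are recovered without material bias", {
  cfg <- synthetic_config(
    n_proteins = 300, n_samples_per_cell = 6,
    module_specs = list(),
    de_specs = list(list(n_proteins = 60, log2_fc = 2, fractions = "total")),
    exclusive_specs = default_exclusive_specs(0),
    dropout_midpoint = -Inf, noise_sd = 0.5, seed = 21)
  gen <- generate_dataset(cfg)
  de <- diff_expression(gen$matrix, "total")
  planted <- gen$truth$protein_id[gen$truth$discriminant]
  est <- de$log2_fc[match(planted, de$protein_id)]
  expect_lt(abs(median(est) - 2), 0.3)
})

test_that("presence filter applies the one-of-two-conditions rule", {
  det <- rbind(P1 = c(rep(TRUE, 5), FALSE, rep(FALSE, 6)),
               P2 = c(rep(TRUE, 4), FALSE, FALSE, rep(TRUE, 4), FALSE, FALSE))
  is_mb <- rep(c(TRUE, FALSE), each = 6)
  pf <- presence_filter(det, is_mb, threshold = 0.7)
  expect_true(pf["P1", "pass"])            # 5/6 in MB, 0/6 in control
  expect_false(pf["P2", "pass"])           # 4/6 in both groups
  expect_true(all(presence_filter(det, is_mb, threshold = 0)$pass))
  expect_equal(pf["P1", "presence_mb"], 5 / 6)
})

test_that("rank AUC equals trapezoid integration of the explicit ROC curve", {
  # toy 3-vs-3
  v <- matrix(c(1.2, 3.4, 2.2, 5.1, 4.4, 6.0), 1, 6)
  rownames(v) <- "P1"
  is_mb <- rep(c(FALSE, TRUE), each = 3)
  res <- protein_auc(v, is_mb)
  roc <- roc_curve(as.numeric(v), is_mb)
  expect_equal(res$auc, auc_trapezoid(roc), tolerance = 1e-12)
  # property over random instances with ties
  set.seed(2)
  for (rep in 1:25) {
    scores <- sample(round(rnorm(14), 1))
    labels <- sample(rep(c(TRUE, FALSE), 7))
    expect_equal(auc_rank(scores, labels),
                 auc_trapezoid(roc_curve(scores, labels)), tolerance = 1e-12)
  }
  # perfect separation and identical distributions
  v2 <- matrix(c(1, 2, 3, 11, 12, 13), 1, 6, dimnames = list("P", NULL))
  expect_equal(protein_auc(v2, is_mb)$auc, 1)
  v3 <- matrix(rep(c(5, 6, 7), 2), 1, 6, dimnames = list("P", NULL))
  expect_equal(protein_auc(v3, is_mb)$auc, 0.5)
})

test_that("post-hoc power matches limits and a Monte-Carlo oracle", {
  expect_equal(posthoc_power(0, 6, 6), 0.05, tolerance = 1e-10)
  expect_gt(posthoc_power(20, 6, 6), 0.999)
  # d = 2.0 at 6 vs 6: Monte Carlo with 50k simulated two-sample t tests
  set.seed(3)
  n_sim <- 50000
  x <- matrix(rnorm(n_sim * 6), n_sim)
  y <- matrix(rnorm(n_sim * 6, mean = 2), n_sim)
  mx <- rowMeans(x); my <- rowMeans(y)
  vp <- (apply(x, 1, var) + apply(y, 1, var)) / 2
  tt <- (my - mx) / sqrt(vp * (2 / 6))
  reject <- 2 * pt(-abs(tt), 10) <= 0.05
  expect_lt(abs(posthoc_power(2, 6, 6) - mean(reject)), 0.01)
  # independent closed-form oracle
  expect_equal(posthoc_power(2, 6, 6),
               power.t.test(n = 6, delta = 2, sd = 1)$power, tolerance = 1e-6)
})

test_that("volcano cutoff respects asymptote and strict boundary", {
  # left of or at the asymptote: never flagged
  expect_false(volcano_threshold(1, 100))
  expect_false(volcano_threshold(0.5, 100))
  # point exactly on the curve is not flagged
  c0 <- (2 - 1) * (-log10(0.05))
  x <- 1.7
  expect_false(volcano_threshold(x, c0 / (x - 1)))
  expect_true(volcano_threshold(x, c0 / (x - 1) + 1e-9))
  # the default curve passes through (2, -log10 0.05); (2.5, 2.0) clears it
  expect_true(volcano_threshold(2.5, 2.0))
  expect_error(volcano_threshold(2, 1, c = -1), "c")
})

test_that("zero-variance proteins report degenerate power correctly", {
  m <- toy_matrix(n_proteins = 2, n_per_cell = 2, seed = 60)
  is_mb <- m$annotations$group == "MB"
  v <- m$values
  v[1, ] <- 5                          # identical everywhere
  v[2, ] <- ifelse(is_mb, 7, 5)        # constant within groups, shifted
  m <- intensity_matrix(v, m$annotations)
  de <- diff_expression(m, "total")
  expect_equal(de$power[de$protein_id == "P001"], 0)
  expect_equal(de$power[de$protein_id == "P002"], 1)
})

test_that("significance requires all five criteria", {
  cfg <- synthetic_config(
    n_proteins = 200, n_samples_per_cell = 6, module_specs = list(),
    de_specs = list(list(n_proteins = 20, log2_fc = 2, fractions = "total")),
    exclusive_specs = default_exclusive_specs(0), seed = 31)
  gen <- generate_dataset(cfg)
  de <- diff_expression(gen$matrix, "total")
  flags <- as.matrix(de[, c("pass_p", "pass_fc", "pass_presence",
                            "pass_auc", "pass_power")])
  expect_identical(de$significant, unname(rowSums(flags) == 5))
  # a protein passing only four criteria is not significant
  four <- which(rowSums(flags) == 4)
  if (length(four)) expect_false(any(de$significant[four]))
})

test_that("the compound criterion controls the null and recovers planted effects", {
  # operating characteristics at the 6-vs-6 design
  null_gen <- generate_dataset(null_config(n_proteins = 1000, n_per_cell = 6,
                                           seed = 41))
  de0 <- diff_expression(null_gen$matrix, "total")
  expect_lte(mean(de0$significant), 0.01)

  cfg <- synthetic_config(
    n_proteins = 1000, n_samples_per_cell = 6, module_specs = list(),
    de_specs = list(list(n_proteins = 50, log2_fc = 2,
                         fractions = c("total", "CPLL", "Mv", "Ex"))),
    exclusive_specs = default_exclusive_specs(0), seed = 42)
  gen <- generate_dataset(cfg)
  de <- diff_expression(gen$matrix, "total")
  planted <- gen$truth$protein_id[gen$truth$discriminant]
  sig <- de$protein_id[de$significant]
  recall <- length(intersect(sig, planted)) / length(planted)
  fdp <- if (length(sig)) length(setdiff(sig, planted)) / length(sig) else 0
  expect_gte(recall, 0.8)
  expect_lte(fdp, 0.1)
})

test_that("recall is monotone in the planted effect size", {
  recalls <- vapply(c(0.8, 1.6, 3), function(fc) {
    cfg <- synthetic_config(
      n_proteins = 300, n_samples_per_cell = 6, module_specs = list(),
      de_specs = list(list(n_proteins = 30, log2_fc = fc, fractions = "total")),
      exclusive_specs = default_exclusive_specs(0), dropout_midpoint = -Inf,
      seed = 55)
    gen <- generate_dataset(cfg)
    de <- diff_expression(gen$matrix, "total")
    planted <- gen$truth$protein_id[gen$truth$discriminant]
    length(intersect(de$protein_id[de$significant], planted)) / length(planted)
  }, numeric(1))
  expect_true(all(diff(recalls) >= 0))
})
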