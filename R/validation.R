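## Diagnostic-performance layer: empirical ROC with trapezoid AUC and
## bootstrap (or DeLong) confidence intervals, the qualitative AUC bins,
## Youden-index cutoff with Clopper-Pearson CIs and likelihood ratio, and
## Kruskal-Wallis with Dunn post hoc z-tests for multi-group assay data.

#' Empirical ROC curve
#'
#' Sweeps every observed score as a threshold (predict positive when
#' `score >= threshold`), returning the staircase from (0, 0) to (1, 1).
#'
#' @param scores numeric assay values.
#' @param labels logical or two-level vector; `TRUE` / second level is the
#'   positive (diseased) class.
#' @return Data frame with `threshold`, `fpr`, `tpr`, ordered by
#'   increasing FPR.
#' @export
roc_curve <- function(scores, labels) {
  pos <- as_positive(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thresholds, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(scores[!pos] >= t), numeric(1))
  data.frame(threshold = thresholds, fpr = fpr, tpr = tpr)
}

#' @noRd
as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  f <- as.factor(labels)
  if (nlevels(f) != 2) stop("labels must have exactly two levels")
  f == levels(f)[2]
}

#' Trapezoid AUC of an ROC curve
#' @param roc data frame from [roc_curve()].
#' @return Area under the curve in `[0, 1]`.
#' @export
auc_trapezoid <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  fpr <- roc$fpr[o]
  tpr <- roc$tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Rank-statistic (Mann-Whitney) AUC
#'
#' `U / (n1 * n2)` with midranks for ties: the probability that a random
#' positive scores above a random negative. Identical to the trapezoid
#' area under the empirical ROC.
#'
#' @param scores numeric assay values.
#' @param labels positive-class indicator, as in [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  pos <- as_positive(labels)
  r <- rank(scores)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Qualitative AUC classification
#'
#' Maps an AUC to the conventional diagnostic bins, boundary values going
#' to the upper bin: exactly 0.5 is "not discriminant", (0.5, 0.6) "fail",
#' \[0.6, 0.7) "poor", \[0.7, 0.8) "fair", \[0.8, 0.9) "good",
#' \[0.9, 1\] "excellent". Values below 0.5 (an inverted marker) are
#' reported "not discriminant".
#'
#' @param auc AUC value.
#' @return One of the six class labels.
#' @export
classify_auc <- function(auc) {
  if (is.na(auc)) return(NA_character_)
  if (auc >= 0.9) "excellent"
  else if (auc >= 0.8) "good"
  else if (auc >= 0.7) "fair"
  else if (auc >= 0.6) "poor"
  else if (auc > 0.5) "fail"
  else "not discriminant"
}

#' ROC analysis with AUC confidence interval
#'
#' Empirical ROC, trapezoid AUC, a stratified-bootstrap percentile
#' confidence interval (default) or the DeLong asymptotic interval, and
#' the qualitative AUC class.
#'
#' @param scores numeric assay values.
#' @param labels positive-class indicator.
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @param conf_level confidence level (default 0.95).
#' @param ci_method `"bootstrap"` or `"delong"`.
#' @return List with `roc`, `auc`, `auc_ci`, `auc_class`.
#' @export
roc_analysis <- function(scores, labels, n_boot = 2000, seed = 1,
                         conf_level = 0.95, ci_method = c("bootstrap", "delong")) {
  ci_method <- match.arg(ci_method)
  pos <- as_positive(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  roc <- roc_curve(scores, pos)
  auc <- auc_trapezoid(roc)
  alpha <- 1 - conf_level
  if (ci_method == "bootstrap") {
    set.seed(seed)
    i_pos <- which(pos)
    i_neg <- which(!pos)
    boot <- vapply(seq_len(n_boot), function(b) {
      bp <- sample(i_pos, replace = TRUE)
      bn <- sample(i_neg, replace = TRUE)
      auc_rank(c(scores[bp], scores[bn]),
               c(rep(TRUE, length(bp)), rep(FALSE, length(bn))))
    }, numeric(1))
    ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2)))
  } else {
    ## DeLong: variance from placement values
    x <- scores[pos]
    y <- scores[!pos]
    v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
    v01 <- vapply(y, function(yi) mean((x > yi) + 0.5 * (x == yi)), numeric(1))
    v <- stats::var(v10) / length(x) + stats::var(v01) / length(y)
    z <- stats::qnorm(1 - alpha / 2)
    ci <- clip(auc + c(-1, 1) * z * sqrt(v), 0, 1)
  }
  list(roc = roc, auc = auc, auc_ci = ci, auc_class = classify_auc(auc))
}

#' Youden-index cutoff and diagnostic performance
#'
#' Exhaustive search over all observed thresholds (predict positive when
#' `score >= cutoff`) for the cutoff maximizing Youden's
#' `J = sensitivity + specificity - 1`; ties are broken toward the lower
#' cutoff. Sensitivity and specificity carry Clopper-Pearson (exact
#' binomial) confidence intervals; the positive likelihood ratio is
#' `sensitivity / (1 - specificity)`, reported `Inf` at specificity 1.
#'
#' @param scores numeric assay values.
#' @param labels positive-class indicator.
#' @param conf_level confidence level for the binomial CIs (default 0.95).
#' @return List with `cutoff`, `youden_j`, `sensitivity`,
#'   `sensitivity_ci`, `specificity`, `specificity_ci`, `lr_positive`.
#' @export
youden_cutoff <- function(scores, labels, conf_level = 0.95) {
  pos <- as_positive(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  cand <- sort(unique(scores))
  sens <- vapply(cand, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(scores[!pos] < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]          # ties -> lower cutoff
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  tp <- round(sens[best] * n_pos)
  tn <- round(spec[best] * n_neg)
  sens_ci <- stats::binom.test(tp, n_pos, conf.level = conf_level)$conf.int
  spec_ci <- stats::binom.test(tn, n_neg, conf.level = conf_level)$conf.int
  lr <- if (spec[best] == 1) Inf else sens[best] / (1 - spec[best])
  list(cutoff = cand[best], youden_j = j[best],
       sensitivity = sens[best], sensitivity_ci = as.numeric(sens_ci),
       specificity = spec[best], specificity_ci = as.numeric(spec_ci),
       lr_positive = lr)
}

#' Full diagnostic summary of an assay
#'
#' Combines [roc_analysis()], [youden_cutoff()] and per-group
#' median/interquartile summaries into one report.
#'
#' @param scores numeric assay values.
#' @param labels positive-class indicator.
#' @param n_boot,seed,conf_level,ci_method passed to [roc_analysis()].
#' @return Object of class `diagnostic_summary`.
#' @export
diagnostic_summary <- function(scores, labels, n_boot = 2000, seed = 1,
                               conf_level = 0.95,
                               ci_method = c("bootstrap", "delong")) {
  pos <- as_positive(labels)
  roc <- roc_analysis(scores, pos, n_boot = n_boot, seed = seed,
                      conf_level = conf_level, ci_method = ci_method)
  cut <- youden_cutoff(scores, pos, conf_level = conf_level)
  groups <- ifelse(pos, "positive", "negative")
  summ <- do.call(rbind, lapply(split(scores, groups), function(v) {
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7)
    data.frame(median = qs[2], q1 = qs[1], q3 = qs[3], n = length(v))
  }))
  structure(c(roc, cut, list(group_summaries = summ)),
            class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.3f-%.3f), %s\n", x$auc, x$auc_ci[1], x$auc_ci[2],
              x$auc_class))
  cat(sprintf("Youden cutoff %.3g: sensitivity %.3f (%.3f-%.3f), specificity %.3f (%.3f-%.3f), LR+ %s\n",
              x$cutoff, x$sensitivity, x$sensitivity_ci[1], x$sensitivity_ci[2],
              x$specificity, x$specificity_ci[1], x$specificity_ci[2],
              format(round(x$lr_positive, 2))))
  cat("Group summaries (median [Q1-Q3]):\n")
  print(x$group_summaries, digits = 3)
  invisible(x)
}

#' @export
plot.diagnostic_summary <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "s", xlab = "1 - specificity",
                 ylab = "Sensitivity", main = sprintf("ROC (AUC %.2f)", x$auc),
                 ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Kruskal-Wallis omnibus test with Dunn post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H across the groups, followed by Dunn's
#' pairwise z-tests on the mean ranks with BH adjustment, and per-group
#' median/interquartile summaries (type-7 linear-interpolation quantiles).
#' Groups with fewer than two values are excluded with a warning.
#'
#' @param values numeric vector of assay values.
#' @param groups grouping vector of the same length.
#' @return Object of class `kruskal_dunn`: `omnibus_p`, `statistic`,
#'   `pairwise` (data frame with `group1`, `group2`, `z`, `p`,
#'   `p_adjusted`), `summaries` (median, q1, q3, n per group).
#' @export
kruskal_dunn <- function(values, groups) {
  groups <- as.character(groups)
  keep_groups <- names(which(table(groups) >= 2))
  dropped <- setdiff(unique(groups), keep_groups)
  if (length(dropped)) {
    warning("group(s) with < 2 values excluded: ",
            paste(dropped, collapse = ", "))
  }
  keep <- groups %in% keep_groups
  values <- values[keep]
  groups <- groups[keep]
  if (length(unique(groups)) < 2) stop("need at least 2 groups with >= 2 values")
  kw <- stats::kruskal.test(values, factor(groups))
  n <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, groups, mean)
  sizes <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(names(mean_ranks), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]
    g2 <- pairs[2, i]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / sizes[g1] + 1 / sizes[g2]))
    z <- (mean_ranks[g1] - mean_ranks[g2]) / se
    data.frame(group1 = g1, group2 = g2, z = unname(z),
               p = unname(2 * stats::pnorm(-abs(z))), stringsAsFactors = FALSE)
  }))
  pairwise$p_adjusted <- stats::p.adjust(pairwise$p, method = "BH")
  summaries <- do.call(rbind, lapply(split(values, groups), function(v) {
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7)
    data.frame(median = unname(qs[2]), q1 = unname(qs[1]),
               q3 = unname(qs[3]), n = length(v))
  }))
  structure(
    list(statistic = unname(kw$statistic), omnibus_p = kw$p.value,
         pairwise = pairwise, summaries = summaries),
    class = "kruskal_dunn"
  )
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.3f, p = %.3g\n", x$statistic, x$omnibus_p))
  cat("Dunn pairwise comparisons (BH-adjusted):\n")
  print(x$pairwise, digits = 3)
  cat("Group summaries:\n")
  print(x$summaries, digits = 3)
  invisible(x)
}
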