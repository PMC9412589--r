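## Per-fraction control-vs-MB differential expression under a compound
## criterion: BH-adjusted Welch t-test p <= alpha, fold change >= fc,
## detection presence >= 70% in at least one group, per-protein ROC
## AUC > 0.7, and post-hoc power >= 0.8. A protein is significant only if
## all five pass. Missing values are excluded from the t/AUC computations;
## detection itself is judged by the presence filter.

#' Row-wise Welch two-sample t-tests
#'
#' Vectorized Welch (unequal-variance) t-tests of MB vs control per
#' protein, on detected log2 values only. Proteins with fewer than two
#' detected values in either group are reported untested (`NA`
#' statistics). `student = TRUE` switches to the pooled-variance test.
#'
#' @param values proteins-by-samples log2 matrix with `NA` non-detections.
#' @param is_mb logical vector over samples (TRUE = MB).
#' @param student use Student's pooled-variance t instead of Welch.
#' @return Data frame with `mean_control`, `mean_mb`, `log2_fc`
#'   (MB - control), `t`, `df`, `p`, `n_control`, `n_mb`, `sd_pooled`.
#' @export
row_welch_tests <- function(values, is_mb, student = FALSE) {
  det <- !is.na(values)
  v0 <- values
  v0[!det] <- 0
  stat_group <- function(cols) {
    n <- rowSums(det[, cols, drop = FALSE])
    s1 <- rowSums(v0[, cols, drop = FALSE])
    s2 <- rowSums(v0[, cols, drop = FALSE]^2)
    m <- ifelse(n > 0, s1 / n, NA_real_)
    v <- ifelse(n > 1, (s2 - n * m^2) / (n - 1), NA_real_)
    v <- pmax(v, 0)                    # guard tiny negative rounding
    list(n = n, mean = m, var = v)
  }
  g1 <- stat_group(which(!is_mb))      # control
  g2 <- stat_group(which(is_mb))       # MB
  diff <- g2$mean - g1$mean
  testable <- g1$n >= 2 & g2$n >= 2
  if (student) {
    df <- g1$n + g2$n - 2
    vp <- ((g1$n - 1) * g1$var + (g2$n - 1) * g2$var) / df
    se <- sqrt(vp * (1 / g1$n + 1 / g2$n))
  } else {
    a <- g1$var / g1$n
    b <- g2$var / g2$n
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (g1$n - 1) + b^2 / (g2$n - 1))
  }
  t_stat <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
  p <- ifelse(is.finite(t_stat), 2 * stats::pt(-abs(t_stat), df),
              ifelse(is.infinite(t_stat), 0, NA_real_))
  p[se == 0 & diff == 0] <- 1
  p[!testable] <- NA_real_
  t_stat[!testable] <- NA_real_
  n_tot <- g1$n + g2$n
  sd_pooled <- sqrt(((g1$n - 1) * g1$var + (g2$n - 1) * g2$var) /
                      pmax(n_tot - 2, 1))
  data.frame(mean_control = g1$mean, mean_mb = g2$mean, log2_fc = diff,
             t = t_stat, df = df, p = p, n_control = g1$n, n_mb = g2$n,
             sd_pooled = sd_pooled, row.names = rownames(values))
}

#' Detection-presence filter
#'
#' A protein passes when its detection frequency reaches `threshold` in at
#' least one of the two clinical groups ("identity in the samples of one of
#' two conditions", read as label-free detection frequency).
#'
#' @param detected proteins-by-samples logical detection mask.
#' @param is_mb logical vector over samples.
#' @param threshold required detection fraction (default 0.7).
#' @return Data frame with `presence_control`, `presence_mb`, `pass`.
#' @export
presence_filter <- function(detected, is_mb, threshold = 0.7) {
  pc <- rowMeans(detected[, !is_mb, drop = FALSE])
  pm <- rowMeans(detected[, is_mb, drop = FALSE])
  data.frame(presence_control = pc, presence_mb = pm,
             pass = pc >= threshold | pm >= threshold,
             row.names = rownames(detected))
}

#' Per-protein ROC AUC from the rank statistic
#'
#' AUC of each protein's detected log2 values as a classifier score for MB
#' vs control, computed as the Mann-Whitney U statistic divided by
#' `n1 * n2` (midranks for ties). `auc` is oriented as P(MB score > control
#' score); `auc_oriented = max(auc, 1 - auc)` is the direction-free value
#' used by the significance criterion, with `direction` recording which
#' group scores higher.
#'
#' @param values proteins-by-samples log2 matrix with `NA` non-detections.
#' @param is_mb logical vector over samples.
#' @return Data frame with `auc`, `auc_oriented`, `direction`.
#' @export
protein_auc <- function(values, is_mb) {
  n <- nrow(values)
  auc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    x <- values[i, !is_mb]
    y <- values[i, is_mb]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) < 1 || length(y) < 1) next
    r <- rank(c(x, y))
    ry <- r[(length(x) + 1):(length(x) + length(y))]
    u <- sum(ry) - length(y) * (length(y) + 1) / 2
    auc[i] <- u / (length(x) * length(y))
  }
  data.frame(auc = auc, auc_oriented = pmax(auc, 1 - auc),
             direction = ifelse(is.na(auc), NA_character_,
                                ifelse(auc >= 0.5, "MB", "control")),
             row.names = rownames(values))
}

#' Post-hoc power of a two-sample t-test
#'
#' Power of a two-sided two-sample t-test at significance `alpha` for the
#' observed standardized effect `d`, via the noncentral t distribution with
#' noncentrality `d * sqrt(n1 n2 / (n1 + n2))`. With zero pooled variance
#' the power is 1 for a nonzero mean difference and 0 otherwise.
#'
#' @param d observed standardized effect size (vectorized).
#' @param n1,n2 group sizes.
#' @param alpha two-sided significance level (default 0.05).
#' @return Power in `[0, 1]`, same length as `d`.
#' @export
posthoc_power <- function(d, n1, n2, alpha = 0.05) {
  if (any(n1 < 1) || any(n2 < 1)) stop("group sizes must be positive")
  df <- n1 + n2 - 2
  ncp <- abs(d) * sqrt(n1 * n2 / (n1 + n2))
  tc <- stats::qt(1 - alpha / 2, df)
  pw <- stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp)
  pw[is.infinite(d)] <- 1
  pw[is.na(d)] <- NA_real_
  pw
}

#' Volcano-plot hyperbolic cutoff
#'
#' Flags points lying above the cutoff curve `y = c / (x - x0)` in the
#' volcano plane, with `x = |log2 FC|` and `y = -log10(adjusted p)`. Points
#' at or left of the vertical asymptote `x = x0` are never flagged, and a
#' point exactly on the curve is not flagged (strict inequalities). The
#' default `c` makes the curve pass through the conventional corner
#' (`x = 2`, `y = -log10(0.05)`), i.e. `c = (2 - x0) * (-log10(0.05))`.
#'
#' @param x `|log2 FC|` values.
#' @param y `-log10(adjusted p)` values.
#' @param x0 vertical asymptote (default 1, the two-fold bound).
#' @param c curve constant (> 0).
#' @return Logical flags.
#' @export
volcano_threshold <- function(x, y, x0 = 1, c = (2 - x0) * (-log10(0.05))) {
  if (c <= 0) stop("c must be > 0")
  if (x0 < 0) stop("x0 must be >= 0")
  x > x0 & y > c / (x - x0)
}

#' Per-fraction differential expression under the compound criterion
#'
#' Runs the five-part significance rule on the control-vs-MB comparison of
#' one fraction: (1) BH-adjusted Welch t p <= `alpha`, (2) fold change
#' `|log2 FC| >= log2(fc)`, (3) detection presence >= `presence` in at
#' least one group, (4) per-protein ROC AUC (orientation-free) > `auc`,
#' (5) post-hoc power >= `power`. BH adjustment is performed within the
#' fraction over the tested proteins.
#'
#' @param matrix an [intensity_matrix()].
#' @param fraction fraction to test (`"total"`, `"CPLL"`, `"Mv"`, `"Ex"`).
#' @param alpha adjusted-p threshold.
#' @param fc fold-change threshold on the linear scale (2 means two-fold).
#' @param presence detection-frequency threshold.
#' @param auc AUC threshold (strict inequality).
#' @param power post-hoc power threshold.
#' @param student use Student's t instead of Welch.
#' @return A `diffexpr_table` data frame: per-protein statistics, pass
#'   flags per criterion, and the overall `significant` flag (conjunction
#'   of all five; untested proteins are not significant).
#' @export
diff_expression <- function(matrix, fraction, alpha = 0.05, fc = 2,
                            presence = 0.7, auc = 0.7, power = 0.8,
                            student = FALSE) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  check_range(alpha, "alpha", 0, 1)
  check_range(presence, "presence", 0, 1)
  check_range(auc, "auc", 0, 1)
  check_range(power, "power", 0, 1)
  sub <- subset_fraction(matrix, fraction)
  is_mb <- sub$annotations$group == "MB"
  if (!any(is_mb) || all(is_mb)) {
    stop("fraction '", fraction, "' lacks one of the two clinical groups")
  }
  tt <- row_welch_tests(sub$values, is_mb, student = student)
  tt$p_adjusted <- NA_real_
  tested <- !is.na(tt$p)
  tt$p_adjusted[tested] <- stats::p.adjust(tt$p[tested], method = "BH")
  pres <- presence_filter(sub$detected, is_mb, threshold = presence)
  roc <- protein_auc(sub$values, is_mb)
  d <- ifelse(tt$sd_pooled > 0, tt$log2_fc / tt$sd_pooled,
              ifelse(tt$log2_fc == 0, 0, Inf))
  pw <- rep(NA_real_, nrow(tt))
  testable <- tt$n_control >= 2 & tt$n_mb >= 2 & !is.na(d)
  pw[testable] <- posthoc_power(d[testable], tt$n_control[testable],
                                tt$n_mb[testable], alpha = alpha)
  # degenerate zero-variance proteins: power 1 for a real difference
  # (d = Inf, handled above), 0 when the groups are literally identical
  pw[testable & tt$sd_pooled == 0 & tt$log2_fc == 0] <- 0
  out <- data.frame(
    protein_id = rownames(sub$values), fraction = fraction,
    mean_control = tt$mean_control, mean_mb = tt$mean_mb,
    log2_fc = tt$log2_fc, p = tt$p, p_adjusted = tt$p_adjusted,
    presence_control = pres$presence_control,
    presence_mb = pres$presence_mb,
    auc = roc$auc, auc_oriented = roc$auc_oriented,
    power = pw, stringsAsFactors = FALSE
  )
  out$pass_p <- !is.na(out$p_adjusted) & out$p_adjusted <= alpha
  out$pass_fc <- !is.na(out$log2_fc) & abs(out$log2_fc) >= log2(fc)
  out$pass_presence <- pres$pass
  out$pass_auc <- !is.na(out$auc_oriented) & out$auc_oriented > auc
  out$pass_power <- !is.na(out$power) & out$power >= power
  out$significant <- out$pass_p & out$pass_fc & out$pass_presence &
    out$pass_auc & out$pass_power
  rownames(out) <- NULL
  class(out) <- c("diffexpr_table", "data.frame")
  out
}

#' Differential expression across all fractions
#'
#' Applies [diff_expression()] to every fraction present and pools the
#' unique significant proteins.
#'
#' @param matrix an [intensity_matrix()].
#' @param fractions fractions to test; defaults to all present.
#' @param ... thresholds passed to [diff_expression()].
#' @return List with `tables` (one `diffexpr_table` per fraction) and
#'   `significant` (deduplicated protein ids significant in any fraction).
#' @export
diff_expression_all <- function(matrix, fractions = NULL, ...) {
  if (is.null(fractions)) {
    fractions <- intersect(FRACTIONS, unique(matrix$annotations$fraction))
  }
  tables <- lapply(fractions, function(f) diff_expression(matrix, f, ...))
  names(tables) <- fractions
  sig <- unique(unlist(lapply(tables, function(t) t$protein_id[t$significant]),
                       use.names = FALSE))
  list(tables = tables, significant = sig)
}

#' @export
print.diffexpr_table <- function(x, ...) {
  cat("Differential expression, fraction '", x$fraction[1], "': ",
      nrow(x), " proteins, ", sum(x$significant), " significant\n", sep = "")
  cat("  criterion pass counts: p", sum(x$pass_p), "| FC", sum(x$pass_fc),
      "| presence", sum(x$pass_presence), "| AUC", sum(x$pass_auc),
      "| power", sum(x$pass_power), "\n")
  invisible(x)
}
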