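## Dual feature prioritization: PLS-DA (NIPALS, class-vector response) with
## VIP scores, and linear-SVM recursive feature elimination with a
## stratified 65/35 learning/validation split and fourfold cross-validation
## on the learning part. The two rankings are combined into a consensus
## panel with a Spearman concordance diagnostic.

#' Impute non-detections at half the minimum detected intensity
#'
#' Standard low-abundance imputation for classifier inputs: a missing log2
#' value becomes the protein's minimum detected log2 value minus 1 (half
#' the raw minimum). Proteins with no detections fall back to the global
#' minimum minus 1. Detection information is not consumed here; it is
#' handled by the differential-expression presence filter.
#'
#' @param matrix an [intensity_matrix()].
#' @return A complete [intensity_matrix()] (all entries detected).
#' @export
impute_half_min <- function(matrix) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  values <- matrix$values
  global_min <- min(values, na.rm = TRUE)
  row_min <- apply(values, 1, function(x) {
    if (all(is.na(x))) global_min else min(x, na.rm = TRUE)
  })
  fill <- row_min - 1
  idx <- which(is.na(values), arr.ind = TRUE)
  if (nrow(idx)) values[idx] <- fill[idx[, 1]]
  intensity_matrix(values, matrix$annotations)
}

#' Fit a PLS-DA model by NIPALS
#'
#' Partial least squares discriminant analysis on a two-class response:
#' sequential NIPALS extraction of components maximizing covariance between
#' the standardized feature matrix and the centered 0/1 class vector. Each
#' weight vector is unit-normalized with a deterministic sign convention
#' (the largest-magnitude weight is positive). Extraction stops early if a
#' component carries no score variance.
#'
#' @param x samples-by-features numeric matrix (complete), or an
#'   [intensity_matrix()] (imputed with [impute_half_min()] and transposed).
#' @param labels two-class factor/character vector over samples; the second
#'   class level is coded 1.
#' @param n_components components to extract (default 2).
#' @return Object of class `plsda_model`: `weights` (features x A),
#'   `scores` (samples x A), `loadings`, `q` (response loadings), `ssy`
#'   (class variance explained per component), `classes`, centering/scaling
#'   vectors.
#' @export
plsda_fit <- function(x, labels, n_components = 2) {
  if (inherits(x, "intensity_matrix")) x <- t(impute_half_min(x)$values)
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must contain exactly two classes")
  y <- as.numeric(labels == levels(labels)[2])
  x_center <- colMeans(x)
  x_scale <- apply(x, 2, stats::sd)
  x_scale[x_scale == 0] <- 1
  xs <- scale(x, center = x_center, scale = x_scale)
  y_center <- mean(y)
  yr <- y - y_center
  n <- nrow(xs)
  p <- ncol(xs)
  a_max <- min(n_components, p, n - 1)
  W <- matrix(0, p, a_max)
  Tm <- matrix(0, n, a_max)
  P <- matrix(0, p, a_max)
  q <- numeric(a_max)
  ssy <- numeric(a_max)
  xr <- xs
  a_used <- 0L
  for (a in seq_len(a_max)) {
    w <- drop(crossprod(xr, yr))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    if (w[which.max(abs(w))] < 0) w <- -w
    t_a <- drop(xr %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-12) break
    p_a <- drop(crossprod(xr, t_a)) / tt
    q_a <- sum(yr * t_a) / tt
    xr <- xr - tcrossprod(t_a, p_a)
    yr <- yr - t_a * q_a
    a_used <- a
    W[, a] <- w
    Tm[, a] <- t_a
    P[, a] <- p_a
    q[a] <- q_a
    ssy[a] <- q_a^2 * tt
  }
  if (a_used == 0L) stop("no PLS component could be extracted (response orthogonal to features)")
  keep <- seq_len(a_used)
  feature_names <- colnames(x)
  structure(
    list(weights = structure(W[, keep, drop = FALSE],
                             dimnames = list(feature_names, NULL)),
         scores = Tm[, keep, drop = FALSE],
         loadings = P[, keep, drop = FALSE],
         q = q[keep], ssy = ssy[keep],
         classes = levels(labels), y = y,
         x_center = x_center, x_scale = x_scale),
    class = "plsda_model"
  )
}

#' @export
print.plsda_model <- function(x, ...) {
  cat("PLS-DA model:", nrow(x$weights), "features,",
      ncol(x$weights), "components\n")
  cat("  class variance explained per component:",
      paste(sprintf("%.3f", x$ssy / sum((x$y - mean(x$y))^2)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt( p * sum_a [ SSY_a * w_ja^2 ] / sum_a SSY_a )` with unit
#' weight vectors, so the mean squared VIP is exactly 1
#' (`sum_j VIP_j^2 = p`). Components with zero explained class variance are
#' skipped with a warning.
#'
#' @param model a [plsda_fit()] model.
#' @return Named numeric vector of VIP scores (one per feature).
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  keep <- model$ssy > 0
  if (!all(keep)) {
    warning(sum(!keep), " degenerate component(s) with zero explained class variance skipped")
  }
  W <- model$weights[, keep, drop = FALSE]
  ssy <- model$ssy[keep]
  p <- nrow(W)
  vip <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  names(vip) <- rownames(model$weights)
  vip
}

#' Linear-SVM recursive feature elimination ranking
#'
#' Splits samples into a stratified learning (65%) and held-out validation
#' (35%) part, then ranks features by recursive feature elimination on the
#' learning part: a linear soft-margin SVM is refit repeatedly and the
#' feature with the smallest squared weight is dropped; the reversed
#' elimination order gives the ranks (rank 1 = last survivor = most
#' important). Classification accuracy is reported as stratified fourfold
#' cross-validation on the learning part (full feature set) and as a
#' confusion matrix on the held-out part.
#'
#' @param x samples-by-features complete numeric matrix, or an
#'   [intensity_matrix()] (imputed and transposed).
#' @param labels two-class vector over samples; the second level is treated
#'   as positive ("MB" when present).
#' @param seed RNG seed controlling the split and folds.
#' @param split learning fraction (default 0.65).
#' @param folds cross-validation folds on the learning part (default 4).
#' @param cost SVM regularization parameter C (default 1).
#' @return List with `ranks` (named permutation of `1..p`) and `report`
#'   (class `classifier_report`: `confusion` TP/FP/TN/FN on the held-out
#'   part, `holdout_accuracy`, `cv_accuracy_mean`, `cv_accuracy_sd`,
#'   `seed`).
#' @export
svm_rank <- function(x, labels, seed = 1, split = 0.65, folds = 4, cost = 1) {
  if (inherits(x, "intensity_matrix")) x <- t(impute_half_min(x)$values)
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must contain exactly two classes")
  xs <- scale(x)
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  set.seed(seed)
  idx_by_class <- split(seq_len(nrow(xs)), labels)
  learn_idx <- sort(unlist(lapply(idx_by_class, function(idx) {
    sample(idx, round(split * length(idx)))
  }), use.names = FALSE))
  hold_idx <- setdiff(seq_len(nrow(xs)), learn_idx)
  y_learn <- droplevels(labels[learn_idx])
  if (any(table(y_learn) < 4)) {
    stop("fewer than 4 samples per class in the learning split")
  }
  x_learn <- xs[learn_idx, , drop = FALSE]

  fit_svm <- function(xmat, yfac) {
    e1071::svm(x = xmat, y = yfac, kernel = "linear", cost = cost,
               scale = FALSE)
  }
  svm_weights <- function(model) drop(crossprod(model$coefs, model$SV))

  ## recursive feature elimination
  p <- ncol(xs)
  active <- seq_len(p)
  elim_order <- integer(0)
  while (length(active) > 1) {
    m <- fit_svm(x_learn[, active, drop = FALSE], y_learn)
    w2 <- svm_weights(m)^2
    drop_pos <- which.min(w2)
    elim_order <- c(elim_order, active[drop_pos])
    active <- active[-drop_pos]
  }
  elim_order <- c(elim_order, active)    # survivor eliminated last
  ranks <- integer(p)
  ranks[rev(elim_order)] <- seq_len(p)   # rank 1 = most important
  names(ranks) <- colnames(xs)

  ## stratified fourfold CV on the learning part
  make_folds <- function(fold_seed) {
    set.seed(fold_seed)
    fold <- integer(length(learn_idx))
    for (cl in levels(y_learn)) {
      pos <- which(y_learn == cl)
      fold[pos] <- sample(rep_len(seq_len(folds), length(pos)))
    }
    fold
  }
  fold_seed <- seed + 1L
  fold <- make_folds(fold_seed)
  attempts <- 0L
  while (any(vapply(seq_len(folds), function(f) {
    nlevels(droplevels(y_learn[fold != f])) < 2
  }, logical(1))) && attempts < 10L) {
    fold_seed <- fold_seed + 1L
    attempts <- attempts + 1L
    warning("a CV fold lacked a class; refolding with a new seed")
    fold <- make_folds(fold_seed)
  }
  cv_acc <- vapply(seq_len(folds), function(f) {
    m <- fit_svm(x_learn[fold != f, , drop = FALSE],
                 droplevels(y_learn[fold != f]))
    mean(predict(m, x_learn[fold == f, , drop = FALSE]) == y_learn[fold == f])
  }, numeric(1))

  ## held-out confusion matrix (second class level = positive)
  final <- fit_svm(x_learn, y_learn)
  pred <- predict(final, xs[hold_idx, , drop = FALSE])
  truth <- labels[hold_idx]
  positive <- levels(labels)[2]
  confusion <- c(
    TP = sum(pred == positive & truth == positive),
    FP = sum(pred == positive & truth != positive),
    TN = sum(pred != positive & truth != positive),
    FN = sum(pred != positive & truth == positive)
  )
  report <- structure(
    list(confusion = confusion,
         holdout_accuracy = unname((confusion["TP"] + confusion["TN"]) /
                                     sum(confusion)),
         cv_accuracy_mean = mean(cv_acc), cv_accuracy_sd = stats::sd(cv_acc),
         positive_class = positive, seed = seed),
    class = "classifier_report"
  )
  list(ranks = ranks, report = report)
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("Linear-SVM classifier report (positive class:", x$positive_class, ")\n")
  cat(sprintf("  fourfold CV accuracy: %.3f +/- %.3f\n",
              x$cv_accuracy_mean, x$cv_accuracy_sd))
  cat(sprintf("  held-out accuracy: %.3f  (TP %d, FP %d, TN %d, FN %d)\n",
              x$holdout_accuracy, x$confusion["TP"], x$confusion["FP"],
              x$confusion["TN"], x$confusion["FN"]))
  invisible(x)
}

#' Consensus ranked panel from VIP and SVM rankings
#'
#' Combines the two prioritizations: a protein enters the consensus when
#' its VIP exceeds `vip_threshold` (greater-than-average importance) and
#' its SVM rank is at most `top_k` (default: the number of VIP-selected
#' proteins, so both methods nominate comparably sized panels). The panel
#' is ordered by the mean of the two rank positions; concordance is the
#' Spearman correlation between the VIP-descending ranks and the SVM ranks
#' over the consensus proteins.
#'
#' @param vip named VIP scores from [vip_scores()].
#' @param svm_ranks named SVM ranks from [svm_rank()].
#' @param vip_threshold VIP selection threshold (default 1).
#' @param top_k SVM-rank selection cutoff.
#' @return Object of class `ranked_panel`: data frame with `protein_id`,
#'   `vip`, `svm_rank`, `selected_vip`, `selected_svm`, `consensus`,
#'   ordered by mean rank; attributes `concordance` (Spearman rho) and
#'   `top_k`.
#' @export
consensus_panel <- function(vip, svm_ranks, vip_threshold = 1, top_k = NULL) {
  if (!setequal(names(vip), names(svm_ranks))) {
    stop("VIP and SVM rankings must cover the same protein set")
  }
  svm_ranks <- svm_ranks[names(vip)]
  selected_vip <- vip > vip_threshold
  if (is.null(top_k)) top_k <- max(sum(selected_vip), 1L)
  selected_svm <- svm_ranks <= top_k
  consensus <- selected_vip & selected_svm
  vip_rank <- rank(-vip, ties.method = "average")
  panel <- data.frame(
    protein_id = names(vip), vip = unname(vip),
    svm_rank = unname(svm_ranks), vip_rank = unname(vip_rank),
    selected_vip = unname(selected_vip), selected_svm = unname(selected_svm),
    consensus = unname(consensus), stringsAsFactors = FALSE
  )
  panel$mean_rank <- (panel$vip_rank + panel$svm_rank) / 2
  panel <- panel[order(panel$mean_rank, panel$svm_rank), ]
  rownames(panel) <- NULL
  concordance <- if (sum(consensus) >= 2) {
    suppressWarnings(stats::cor(vip_rank[consensus], svm_ranks[consensus],
                                method = "spearman"))
  } else {
    NA_real_
  }
  if (!any(consensus)) warning("empty consensus panel")
  structure(panel, class = c("ranked_panel", "data.frame"),
            concordance = concordance, top_k = top_k)
}

#' @export
print.ranked_panel <- function(x, ...) {
  cat("Ranked panel:", sum(x$consensus), "consensus proteins of", nrow(x),
      "ranked (top_k =", attr(x, "top_k"), ")\n")
  cat(sprintf("  VIP/SVM rank concordance (Spearman rho): %.3f\n",
              attr(x, "concordance")))
  print.data.frame(utils::head(x[x$consensus, ], 10))
  invisible(x)
}

#' Full dual prioritization of an intensity matrix
#'
#' Imputes, fits PLS-DA, computes VIP scores, runs SVM-RFE and combines
#' both into the consensus panel.
#'
#' @param matrix an [intensity_matrix()]; samples of all fractions are
#'   pooled as observations with the clinical group as the class.
#' @param proteins optional protein-id subset to rank (e.g. the
#'   differential-expression significant list).
#' @param seed RNG seed for the SVM split and folds.
#' @param n_components PLS-DA components (default 2).
#' @param vip_threshold,top_k consensus rules, see [consensus_panel()].
#' @param ... passed to [svm_rank()].
#' @return List with `panel` (a `ranked_panel`), `pls` (the PLS-DA model),
#'   `vip`, `svm` (ranks + report).
#' @export
rank_proteins <- function(matrix, proteins = NULL, seed = 1, n_components = 2,
                          vip_threshold = 1, top_k = NULL, ...) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  if (!is.null(proteins)) {
    keep <- rownames(matrix$values) %in% proteins
    if (!any(keep)) stop("none of the requested proteins are in the matrix")
    matrix <- intensity_matrix(matrix$values[keep, , drop = FALSE],
                               matrix$annotations)
  }
  x <- t(impute_half_min(matrix)$values)
  labels <- factor(matrix$annotations$group, levels = c("control", "MB"))
  pls <- plsda_fit(x, labels, n_components = n_components)
  vip <- vip_scores(pls)
  svm <- svm_rank(x, labels, seed = substream_seed(seed, "ranking"), ...)
  panel <- consensus_panel(vip, svm$ranks, vip_threshold = vip_threshold,
                           top_k = top_k)
  list(panel = panel, pls = pls, vip = vip, svm = svm)
}
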