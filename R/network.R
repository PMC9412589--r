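## Weighted co-expression network, implemented from first principles:
## soft-threshold selection against a scale-free topology fit, power
## adjacency, topological overlap, module detection by average-linkage
## clustering of TOM dissimilarity with a minimum module size, module
## eigengenes, and module-trait correlation.

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivity values, then regresses `log10(frequency)` on
#' `log10(mean connectivity)` across occupied bins; the R-squared of that
#' regression is the scale-free fit index. A network whose degree
#' distribution follows a power law attains a fit near 1.
#'
#' @param connectivity vector of per-node connectivities (k_i).
#' @param n_bins number of equal-width bins (default 10).
#' @return List with `r_squared`, `slope`, `n_bins_used`.
#' @export
scale_free_fit <- function(connectivity, n_bins = 10) {
  k <- connectivity[is.finite(connectivity) & connectivity > 0]
  if (length(k) < 2 || min(k) == max(k)) {
    stop("fewer than 2 usable bins: connectivities constant or absent")
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  breaks[1] <- breaks[1] - 1e-9
  bin <- cut(k, breaks = breaks, labels = FALSE)
  freq <- tapply(k, bin, length)
  mean_k <- tapply(k, bin, mean)
  usable <- freq > 0 & mean_k > 0
  if (sum(usable) < 2) stop("fewer than 2 usable bins in the connectivity histogram")
  x <- log10(mean_k[usable])
  y <- log10(freq[usable])
  fit <- stats::lm(y ~ x)
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       n_bins_used = sum(usable))
}

#' Protein-protein correlation on pairwise-complete values
#'
#' Pearson correlation between protein log2 profiles using
#' pairwise-complete detected values. Proteins sharing fewer than
#' `min_shared` observations with every other protein are excluded with a
#' warning; isolated incomputable pairs are set to zero correlation.
#' @noRd
protein_correlation <- function(matrix, min_shared = 3) {
  values <- if (inherits(matrix, "intensity_matrix")) matrix$values else matrix
  det <- !is.na(values)
  shared <- tcrossprod(det * 1)
  diag(shared) <- 0
  isolated <- apply(shared, 1, max) < min_shared
  if (any(isolated)) {
    warning(sum(isolated), " protein(s) with < ", min_shared,
            " paired observations against all others excluded from the network")
    values <- values[!isolated, , drop = FALSE]
  }
  rho <- suppressWarnings(
    stats::cor(t(values), use = "pairwise.complete.obs"))
  rho[!is.finite(rho)] <- 0
  diag(rho) <- 1
  rho
}

#' Weighted network adjacency
#'
#' Power adjacency `a_ij = |cor(x_i, x_j)|^beta` (unsigned network) or
#' `a_ij = ((1 + cor)/2)^beta` (signed), with unit diagonal. Correlations
#' are Pearson on pairwise-complete log2 values.
#'
#' @param matrix an [intensity_matrix()] or a proteins-by-samples matrix.
#' @param beta soft-threshold power (>= 1).
#' @param signed use the signed transformation.
#' @return Symmetric adjacency matrix with entries in `[0, 1]`.
#' @export
adjacency_matrix <- function(matrix, beta, signed = FALSE) {
  if (!is.numeric(beta) || beta < 1) stop("beta must be >= 1")
  rho <- protein_correlation(matrix)
  a <- if (signed) ((1 + rho) / 2)^beta else abs(rho)^beta
  diag(a) <- 1
  a
}

#' Choose the soft-threshold power
#'
#' For each candidate power the adjacency is formed, per-protein
#' connectivity `k_i = sum_{j != i} a_ij` computed, and the scale-free
#' topology fit R-squared evaluated ([scale_free_fit()]). The selected power
#' is the smallest candidate whose fit reaches `fit_target`; if none does,
#' the best-fitting power is returned with a warning.
#'
#' @param matrix an [intensity_matrix()] or numeric matrix.
#' @param candidate_powers powers to scan (default `c(1:10, 12, 14, 16, 18, 20)`).
#' @param fit_target required scale-free fit R-squared (default 0.8).
#' @param signed signed network transformation.
#' @return List with `beta` and `fit_table` (power, r_squared, slope,
#'   mean_connectivity per candidate).
#' @export
pick_soft_threshold <- function(matrix, candidate_powers = c(1:10, seq(12, 20, 2)),
                                fit_target = 0.8, signed = FALSE) {
  rho <- protein_correlation(matrix)
  base <- if (signed) (1 + rho) / 2 else abs(rho)
  rows <- lapply(candidate_powers, function(beta) {
    a <- base^beta
    diag(a) <- 0
    k <- rowSums(a)
    fit <- tryCatch(scale_free_fit(k), error = function(e) list(r_squared = NA_real_, slope = NA_real_))
    data.frame(power = beta, r_squared = fit$r_squared, slope = fit$slope,
               mean_connectivity = mean(k))
  })
  fit_table <- do.call(rbind, rows)
  ok <- which(!is.na(fit_table$r_squared) & fit_table$r_squared >= fit_target)
  if (length(ok)) {
    beta <- fit_table$power[ok[1]]
  } else {
    best <- which.max(fit_table$r_squared)
    beta <- fit_table$power[best]
    warning(sprintf(
      "no candidate power reached scale-free fit R^2 >= %.2f; using power %d (R^2 = %.2f)",
      fit_target, beta, fit_table$r_squared[best]))
  }
  list(beta = beta, fit_table = fit_table)
}

#' Topological overlap matrix
#'
#' Neighborhood-sharing similarity of a weighted network: for `i != j`,
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' `TOM_ii = 1`. Values lie in `[0, 1]` for a valid adjacency and measure
#' how much two proteins share network neighbors beyond their direct edge.
#'
#' @param adjacency symmetric adjacency matrix with unit diagonal and
#'   entries in `[0, 1]`.
#' @return The TOM, same shape as `adjacency`.
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a) || any(abs(a - t(a)) > 1e-10)) {
    stop("adjacency must be square and symmetric")
  }
  if (any(a < -1e-12) || any(a > 1 + 1e-12)) {
    stop("adjacency entries must lie in [0, 1]")
  }
  a0 <- a
  diag(a0) <- 0
  k <- rowSums(a0)
  l <- a0 %*% a0                       # l_ij = sum_u a_iu a_uj, u != i, j
  k_min <- outer(k, k, pmin)
  tom <- (l + a0) / (k_min + 1 - a0)
  tom[!is.finite(tom)] <- 0
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules from topological overlap
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity
#' `1 - TOM` with a static cut. When `cut_height` is not given, the cut is
#' chosen deterministically from the tree itself: every merge height is
#' scanned and the lowest height resolving the largest number of clusters
#' of at least `min_size` members is used. Clusters smaller than `min_size`
#' are merged into the background ("grey"); surviving modules are labelled
#' `module1, module2, ...` in order of decreasing size. A degenerate
#' all-equal TOM yields a single module.
#'
#' @param tom topological overlap matrix.
#' @param min_size minimum module size (default 20).
#' @param cut_height static cut height in `[0, 1]`; `NULL` for the
#'   most-resolved-cut rule above.
#' @return Named character vector of module labels per protein.
#' @export
detect_modules <- function(tom, min_size = 20, cut_height = NULL) {
  n <- nrow(tom)
  if (min_size > n) stop("min_size exceeds the number of proteins")
  tree <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  if (is.null(cut_height)) {
    heights <- sort(unique(tree$height))
    best_n <- -1L
    cut_height <- heights[length(heights)]
    for (h in heights) {
      sizes_h <- table(stats::cutree(tree, h = h))
      n_valid <- sum(sizes_h >= min_size)
      if (n_valid > best_n) {
        best_n <- n_valid
        cut_height <- h
      }
    }
  }
  raw <- stats::cutree(tree, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  labels <- rep("grey", n)
  if (length(keep)) {
    keep <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(keep)) {
      labels[raw == as.integer(keep[i])] <- paste0("module", i)
    }
  }
  names(labels) <- rownames(tom)
  labels
}

#' Module eigengenes
#'
#' The eigengene of a module is the first right singular vector of the
#' row-standardized member expression (equivalently the first principal
#' component across samples), unit-normalized and oriented so its mean
#' correlation with member proteins is positive. Missing values are
#' mean-imputed within the standardization step only (a standardized
#' missing entry becomes 0).
#'
#' @param matrix an [intensity_matrix()].
#' @param labels module labels from [detect_modules()] (background label
#'   `"grey"` is skipped).
#' @return List with `eigengenes` (samples x modules, unit columns) and
#'   `explained_variance` (fraction per module).
#' @export
module_eigengenes <- function(matrix, labels) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  modules <- setdiff(sort(unique(labels)), "grey")
  if (!length(modules)) stop("no non-background modules in 'labels'")
  n <- ncol(matrix$values)
  eigengenes <- matrix(NA_real_, n, length(modules),
                       dimnames = list(colnames(matrix$values), modules))
  expl <- numeric(length(modules))
  names(expl) <- modules
  for (m in seq_along(modules)) {
    members <- which(labels == modules[m])
    if (length(members) < 2) stop("module '", modules[m], "' has < 2 members")
    x <- matrix$values[members, , drop = FALSE]
    mu <- rowMeans(x, na.rm = TRUE)
    s <- apply(x, 1, stats::sd, na.rm = TRUE)
    s[!is.finite(s) | s == 0] <- 1
    xs <- (x - mu) / s
    xs[is.na(xs)] <- 0                 # mean imputation after standardization
    dec <- svd(xs)
    if (dec$d[1] <= 1e-12) stop("module '", modules[m], "' has rank-0 data")
    me <- dec$v[, 1]
    if (mean(stats::cor(me, t(xs))) < 0) me <- -me
    eigengenes[, m] <- me
    expl[m] <- dec$d[1]^2 / sum(dec$d^2)
  }
  list(eigengenes = eigengenes, explained_variance = expl)
}

#' Binary trait indicators from sample annotations
#'
#' One 0/1 indicator per clinical group and per fraction (`MB`, `control`,
#' `total`, `CPLL`, `Mv`, `Ex`).
#'
#' @param annotations annotation data frame of an [intensity_matrix()].
#' @return Samples-by-traits 0/1 matrix.
#' @export
trait_indicators <- function(annotations) {
  traits <- cbind(
    MB = as.integer(annotations$group == "MB"),
    control = as.integer(annotations$group == "control"),
    total = as.integer(annotations$fraction == "total"),
    CPLL = as.integer(annotations$fraction == "CPLL"),
    Mv = as.integer(annotations$fraction == "Mv"),
    Ex = as.integer(annotations$fraction == "Ex")
  )
  rownames(traits) <- annotations$sample_id
  traits
}

#' Module-trait correlation
#'
#' Spearman correlation between each module eigengene and each 0/1 trait
#' indicator, with Benjamini-Hochberg adjustment across all module-trait
#' pairs. A pair is flagged significant when `|rho| > rho_threshold` and
#' the adjusted two-sided p-value is at most `alpha`.
#'
#' @param eigengenes samples-by-modules matrix from [module_eigengenes()].
#' @param traits samples-by-traits 0/1 matrix from [trait_indicators()].
#' @param rho_threshold correlation magnitude required (default 0.7).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return Data frame with columns `module`, `trait`, `rho`, `p`,
#'   `p_adjusted`, `significant`.
#' @export
module_trait_correlation <- function(eigengenes, traits, rho_threshold = 0.7,
                                     alpha = 0.05) {
  traits <- as.matrix(traits)
  if (any(apply(traits, 2, function(t) length(unique(t))) < 2)) {
    bad <- colnames(traits)[apply(traits, 2, function(t) length(unique(t)) < 2)][1]
    stop("trait '", bad, "' is constant")
  }
  grid <- expand.grid(module = colnames(eigengenes), trait = colnames(traits),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ct <- suppressWarnings(stats::cor.test(
      eigengenes[, grid$module[i]], traits[, grid$trait[i]],
      method = "spearman", exact = FALSE))
    data.frame(module = grid$module[i], trait = grid$trait[i],
               rho = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out$significant <- abs(out$rho) > rho_threshold & out$p_adjusted <= alpha
  out
}

#' Build the full co-expression network
#'
#' Runs soft-threshold selection, adjacency, topological overlap, module
#' detection, module eigengenes and module-trait correlation in one call.
#'
#' Proteins entering the network are first filtered for detection
#' completeness (`min_detection`): sparsely detected proteins (for example
#' those exclusive to a single group-fraction cell) yield degenerate
#' pairwise-complete correlations and artifactual tight clusters, so they
#' are left in the background rather than passed to the network.
#'
#' @param matrix an [intensity_matrix()].
#' @param min_module_size minimum proteins per module (default 20).
#' @param fit_target scale-free fit target for power selection (default 0.8).
#' @param candidate_powers powers scanned by [pick_soft_threshold()].
#' @param signed use a signed network.
#' @param cut_height static tree-cut height; `NULL` for the adaptive rule
#'   of [detect_modules()].
#' @param min_detection minimum fraction of samples a protein must be
#'   detected in to enter the network (default 0.5).
#' @return Object of class `coexpression_network` with `beta`, `fit_table`,
#'   `tom`, `labels` (all proteins; filtered ones are background),
#'   `eigengenes`, `explained_variance`, `trait_correlations`, `min_size`.
#' @export
build_network <- function(matrix, min_module_size = 20, fit_target = 0.8,
                          candidate_powers = c(1:10, seq(12, 20, 2)),
                          signed = FALSE, cut_height = NULL,
                          min_detection = 0.5) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  keep <- rowMeans(matrix$detected) >= min_detection
  if (sum(keep) < min_module_size) {
    stop("fewer than one module's worth of proteins pass the detection filter")
  }
  net_mat <- intensity_matrix(matrix$values[keep, , drop = FALSE],
                              matrix$annotations)
  pick <- pick_soft_threshold(net_mat, candidate_powers, fit_target, signed)
  adj <- adjacency_matrix(net_mat, beta = pick$beta, signed = signed)
  tom <- topological_overlap(adj)
  labels_net <- detect_modules(tom, min_size = min_module_size,
                               cut_height = cut_height)
  labels <- stats::setNames(rep("grey", nrow(matrix$values)),
                            rownames(matrix$values))
  labels[names(labels_net)] <- labels_net
  me <- if (any(labels != "grey")) {
    module_eigengenes(matrix, labels)
  } else {
    list(eigengenes = NULL, explained_variance = numeric(0))
  }
  traits <- trait_indicators(matrix$annotations)
  trait_cor <- if (!is.null(me$eigengenes)) {
    module_trait_correlation(me$eigengenes, traits)
  } else {
    NULL
  }
  structure(
    list(beta = pick$beta, fit_table = pick$fit_table, tom = tom,
         labels = labels, eigengenes = me$eigengenes,
         explained_variance = me$explained_variance,
         trait_correlations = trait_cor, min_size = min_module_size),
    class = "coexpression_network"
  )
}

#' @export
print.coexpression_network <- function(x, ...) {
  sizes <- table(x$labels[x$labels != "grey"])
  cat("Co-expression network (beta =", x$beta, ")\n")
  cat("  modules:", length(sizes),
      if (length(sizes)) paste0("(sizes ", paste(sort(as.integer(sizes),
                                                      decreasing = TRUE),
                                                 collapse = ", "), ")") else "",
      "\n")
  cat("  background proteins:", sum(x$labels == "grey"), "\n")
  if (!is.null(x$trait_correlations)) {
    sig <- x$trait_correlations[x$trait_correlations$significant, , drop = FALSE]
    cat("  significant module-trait pairs:", nrow(sig), "\n")
  }
  invisible(x)
}
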