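## Unsupervised sample-structure screen: Spearman dissimilarity, Torgerson
## classical MDS (double-centered Gram eigendecomposition), k-means
## clustering and a MAD-based outlier rule.

#' Spearman dissimilarity between samples
#'
#' Pairwise sample dissimilarity `d = 1 - rho` from Spearman rank
#' correlation of the log2 intensities, using pairwise-complete detected
#' values. `d` is symmetric with a zero diagonal; a perfectly rank-reversed
#' pair attains the maximum `d = 2`.
#'
#' @param matrix an [intensity_matrix()] (or a bare proteins-by-samples
#'   numeric matrix).
#' @param min_shared minimum number of proteins detected in both samples of
#'   a pair (default 3); fewer is an error naming the pair.
#' @return Symmetric samples-by-samples dissimilarity matrix.
#' @export
spearman_dissimilarity <- function(matrix, min_shared = 3) {
  values <- if (inherits(matrix, "intensity_matrix")) matrix$values else matrix
  det <- !is.na(values)
  shared <- crossprod(det)
  off <- shared[upper.tri(shared)]
  if (any(off < min_shared)) {
    idx <- which(shared < min_shared & upper.tri(shared), arr.ind = TRUE)[1, ]
    stop("samples '", colnames(values)[idx[1]], "' and '",
         colnames(values)[idx[2]], "' share fewer than ", min_shared,
         " detected proteins")
  }
  rho <- stats::cor(values, method = "spearman", use = "pairwise.complete.obs")
  d <- 1 - rho
  diag(d) <- 0
  d
}

#' Torgerson classical multidimensional scaling
#'
#' Classical (metric) MDS: double centering of squared dissimilarities to a
#' Gram matrix followed by eigendecomposition, keeping the top `k`
#' positive-eigenvalue axes. Axis signs are fixed deterministically: each
#' axis is flipped so its largest-magnitude coordinate is positive.
#'
#' @param dissimilarities square symmetric dissimilarity matrix.
#' @param k number of output dimensions (default 2).
#' @return List with `coordinates` (samples x k), `eigenvalues`
#'   (non-increasing, all returned).
#' @export
classical_mds <- function(dissimilarities, k = 2) {
  d <- as.matrix(dissimilarities)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
    stop("dissimilarities must be square and symmetric")
  }
  fit <- suppressWarnings(stats::cmdscale(d, k = min(k, nrow(d) - 1), eig = TRUE))
  eig <- fit$eig
  if (all(eig <= 1e-12)) stop("degenerate geometry: no positive eigenvalues")
  coords <- fit$points
  if (ncol(coords) < k) {
    coords <- cbind(coords, matrix(0, nrow(coords), k - ncol(coords)))
  }
  for (j in seq_len(ncol(coords))) {
    i_max <- which.max(abs(coords[, j]))
    if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("MDS", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = sort(eig, decreasing = TRUE))
}

#' k-means clustering with multiple restarts
#'
#' Lloyd/Hartigan-Wong k-means on embedding coordinates with `n_restarts`
#' random initializations under a fixed seed; the best-inertia solution is
#' returned, so results are deterministic given the seed and inertia is
#' non-increasing in the number of restarts.
#'
#' @param coordinates samples-by-dims numeric matrix.
#' @param k number of clusters (1 <= k <= number of samples).
#' @param seed RNG seed.
#' @param n_restarts number of random restarts (default 50).
#' @return List with `labels` (named integer vector), `inertia` (total
#'   within-cluster sum of squares), `centers`.
#' @export
kmeans_clusters <- function(coordinates, k, seed = 1, n_restarts = 50) {
  coordinates <- as.matrix(coordinates)
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(coordinates)) stop("k exceeds the number of samples")
  set.seed(seed)
  if (k == nrow(coordinates)) {
    labels <- seq_len(nrow(coordinates))
    names(labels) <- rownames(coordinates)
    return(list(labels = labels, inertia = 0, centers = coordinates))
  }
  fit <- stats::kmeans(coordinates, centers = k, nstart = n_restarts,
                       iter.max = 100)
  labels <- fit$cluster
  names(labels) <- rownames(coordinates)
  list(labels = labels, inertia = fit$tot.withinss, centers = fit$centers)
}

#' Flag outlying samples by median Spearman correlation
#'
#' A sample is flagged when its median Spearman correlation to all other
#' samples falls more than `n_mad` MADs below the cohort median of those
#' per-sample medians.
#'
#' @param matrix an [intensity_matrix()] or numeric matrix.
#' @param n_mad flagging threshold in MAD units (default 3).
#' @return Named logical vector, one entry per sample.
#' @export
flag_outliers <- function(matrix, n_mad = 3) {
  values <- if (inherits(matrix, "intensity_matrix")) matrix$values else matrix
  rho <- stats::cor(values, method = "spearman", use = "pairwise.complete.obs")
  diag(rho) <- NA
  med_cor <- apply(rho, 2, stats::median, na.rm = TRUE)
  center <- stats::median(med_cor)
  spread <- stats::mad(med_cor)
  flags <- if (spread == 0) rep(FALSE, length(med_cor)) else
    med_cor < center - n_mad * spread
  names(flags) <- colnames(values)
  flags
}

#' Full sample-structure screen
#'
#' Convenience wrapper running [spearman_dissimilarity()],
#' [classical_mds()], [kmeans_clusters()] and [flag_outliers()] in one call.
#'
#' @param matrix an [intensity_matrix()].
#' @param k clusters for k-means; defaults to the number of
#'   group-by-fraction cells present.
#' @param seed RNG seed for k-means restarts.
#' @return Object of class `mds_screen` with `coordinates`, `eigenvalues`,
#'   `cluster_labels`, `outlier_flags`.
#' @export
mds_screen <- function(matrix, k = NULL, seed = 1) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  if (is.null(k)) {
    k <- nrow(unique(matrix$annotations[, c("group", "fraction")]))
  }
  d <- spearman_dissimilarity(matrix)
  emb <- classical_mds(d, k = 2)
  km <- kmeans_clusters(emb$coordinates, k = k,
                        seed = substream_seed(seed, "mds"))
  structure(
    list(coordinates = emb$coordinates, eigenvalues = emb$eigenvalues,
         cluster_labels = km$labels, inertia = km$inertia,
         outlier_flags = flag_outliers(matrix)),
    class = "mds_screen"
  )
}

#' @export
print.mds_screen <- function(x, ...) {
  cat("MDS sample screen:", nrow(x$coordinates), "samples,",
      length(unique(x$cluster_labels)), "k-means clusters\n")
  n_out <- sum(x$outlier_flags)
  cat("  outliers flagged:", n_out, "\n")
  invisible(x)
}

#' @export
plot.mds_screen <- function(x, ...) {
  graphics::plot(x$coordinates[, 1], x$coordinates[, 2],
                 col = x$cluster_labels, pch = ifelse(x$outlier_flags, 4, 19),
                 xlab = "MDS1", ylab = "MDS2",
                 main = "Classical MDS sample screen", ...)
  invisible(x)
}
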