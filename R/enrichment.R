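## Two-group gene-set enrichment: hypergeometric over-representation of
## flat GMT term sets within the significant proteins, a bounded [-1, 1]
## per-term rank value combining coverage, fold-change direction and
## FDR-adjusted p, and the x = y scatter geometry comparing the two groups.

#' Hypergeometric over-representation p-value of one term
#'
#' One-sided tail probability of observing at least the seen overlap
#' between a term's members and the significant set when drawing from the
#' quantified universe.
#'
#' @param members character vector of term member ids.
#' @param significant character vector of significant protein ids (must be
#'   a subset of `universe`).
#' @param universe character vector of all quantified protein ids.
#' @return List with `k` (significant members), `K` (members in universe),
#'   `p`.
#' @export
term_enrichment_p <- function(members, significant, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  significant <- unique(significant)
  if (length(setdiff(significant, universe))) {
    stop("significant set must be contained in the universe")
  }
  members <- intersect(unique(members), universe)
  k <- length(intersect(members, significant))
  K <- length(members)
  p <- stats::phyper(k - 1, length(significant),
                     length(universe) - length(significant), K,
                     lower.tail = FALSE)
  list(k = k, K = K, p = p)
}

#' Bounded per-term enrichment rank value
#'
#' A score in `[-1, 1]` for a term in one group, combining term coverage,
#' fold-change direction and the FDR-adjusted over-representation p:
#' `s = clip( orient * sqrt(k / K) * (1 - q), -1, 1 )`, where `orient` is
#' +1 when the term's mean log2 fold change (MB minus control) favors the
#' scored group and -1 otherwise. The extremes -1 and 1 correspond to
#' minimal and maximal enrichment in the group; `q = 1` gives 0.
#'
#' The published analysis states the ingredients of this score (coverage
#' relative to all proteins, mean fold change, FDR-adjusted p) and its
#' bounds, but not its functional form; this function is one concrete
#' instantiation of those constraints and is deliberately isolated so
#' alternatives can be swapped in.
#'
#' @param k significant members of the term.
#' @param K members of the term in the universe.
#' @param n_universe size of the quantified universe (consistency check).
#' @param mean_log2_fc mean log2 fold change (MB - control) of the term's
#'   detected members.
#' @param q FDR-adjusted enrichment p in `[0, 1]`.
#' @param group scored group, `"MB"` or `"control"`.
#' @return The rank value `s` in `[-1, 1]`.
#' @export
rank_value <- function(k, K, n_universe = NULL, mean_log2_fc, q,
                       group = c("MB", "control")) {
  group <- match.arg(group)
  if (K == 0) {
    warning("term with no members in the universe skipped")
    return(NA_real_)
  }
  if (k > K) stop("k cannot exceed K")
  if (!is.null(n_universe) && K > n_universe) stop("K cannot exceed the universe size")
  if (is.na(q) || q < 0 || q > 1) stop("q must lie in [0, 1]")
  orient <- sign(mean_log2_fc)
  if (group == "control") orient <- -orient
  if (orient == 0) orient <- 0
  clip(orient * sqrt(k / K) * (1 - q), -1, 1)
}

#' Signed distance of enrichment points from the x = y line
#'
#' In the scatter of `(s_MB, s_control)` per term, points on the diagonal
#' through (-1, -1) and (1, 1) are equally enriched in both groups; the
#' signed perpendicular distance `d = (s_MB - s_control) / sqrt(2)` is
#' positive for MB-enriched terms (above the line) and negative for
#' control-enriched ones.
#'
#' @param s_mb,s_control rank values of the terms in each group.
#' @return Numeric vector of signed distances.
#' @export
scatter_geometry <- function(s_mb, s_control) {
  (s_mb - s_control) / sqrt(2)
}

#' Two-group term enrichment table
#'
#' Scores every gene set against the significant proteins of a two-group
#' comparison: hypergeometric over-representation with BH adjustment
#' across terms, the per-group rank values, and the x = y scatter distance.
#'
#' @param gene_sets named list of term member vectors (or [read_gmt()]
#'   output).
#' @param log2_fc named vector of log2 fold changes (MB - control) over the
#'   quantified universe; its names define the universe.
#' @param significant character vector of significant protein ids.
#' @return An `enrichment_table` data frame: `term`, `k`, `K`,
#'   `mean_log2_fc`, `p`, `q`, `s_mb`, `s_control`, `d`, sorted by
#'   decreasing `|d|`.
#' @export
enrich_two_group <- function(gene_sets, log2_fc, significant) {
  universe <- names(log2_fc)
  if (is.null(universe) || !length(universe)) stop("empty universe")
  sets <- lapply(gene_sets, function(gs) if (is.list(gs)) gs$members else gs)
  stats_list <- lapply(sets, term_enrichment_p, significant = significant,
                       universe = universe)
  k <- vapply(stats_list, `[[`, numeric(1), "k")
  K <- vapply(stats_list, `[[`, numeric(1), "K")
  p <- vapply(stats_list, `[[`, numeric(1), "p")
  q <- stats::p.adjust(p, method = "BH")
  mean_fc <- vapply(seq_along(sets), function(i) {
    m <- intersect(sets[[i]], universe)
    if (!length(m)) return(NA_real_)
    mean(log2_fc[m], na.rm = TRUE)
  }, numeric(1))
  s_mb <- mapply(function(k_, K_, fc_, q_) {
    if (K_ == 0) return(NA_real_)
    rank_value(k_, K_, length(universe), fc_, q_, "MB")
  }, k, K, mean_fc, q)
  s_control <- mapply(function(k_, K_, fc_, q_) {
    if (K_ == 0) return(NA_real_)
    rank_value(k_, K_, length(universe), fc_, q_, "control")
  }, k, K, mean_fc, q)
  out <- data.frame(term = names(gene_sets), k = k, K = K,
                    mean_log2_fc = mean_fc, p = p, q = q,
                    s_mb = s_mb, s_control = s_control,
                    d = scatter_geometry(s_mb, s_control),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$d), out$q), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat("Term enrichment:", nrow(x), "terms;",
      sum(x$d > 0, na.rm = TRUE), "MB-enriched,",
      sum(x$d < 0, na.rm = TRUE), "control-enriched\n")
  print.data.frame(utils::head(x, 8), digits = 3)
  invisible(x)
}
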