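## Ingest layer: protein-group intensity tables (MaxQuant-style TSV dialect),
## sample annotations, GMT gene sets, median normalization and the
## detection/overlap (Venn) accounting.

#' Construct an intensity matrix container
#'
#' The central data container of the package: a proteins-by-samples matrix of
#' log2 intensities with an explicit detection mask and per-sample clinical
#' annotations (group and biochemical fraction). Missing values and the mask
#' are kept congruent: `values[i, j]` is `NA` exactly when `detected[i, j]`
#' is `FALSE`.
#'
#' @param values numeric matrix of log2 intensities, proteins in rows and
#'   samples in columns; `NA` marks a non-detection. Row and column names are
#'   required and must be unique.
#' @param annotations data frame with columns `sample_id`, `group`
#'   (`"control"` or `"MB"`) and `fraction` (`"total"`, `"CPLL"`, `"Mv"` or
#'   `"Ex"`), one row per sample of `values`.
#' @return An object of class `intensity_matrix` with elements `values`,
#'   `detected` and `annotations`.
#' @export
intensity_matrix <- function(values, annotations) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("format error in column 'protein_id': protein ids must be present and unique")
  }
  if (is.null(colnames(values))) stop("'values' must have sample names as colnames")
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  required <- c("sample_id", "group", "fraction")
  missing_cols <- setdiff(required, names(annotations))
  if (length(missing_cols)) {
    stop("format error: annotation table lacks column '", missing_cols[1], "'")
  }
  if (anyDuplicated(annotations$sample_id)) {
    stop("format error in column 'sample_id': duplicated sample ids")
  }
  if (!setequal(colnames(values), annotations$sample_id)) {
    stop("format error: annotation sample ids do not match intensity columns")
  }
  bad_group <- setdiff(unique(annotations$group), c("control", "MB"))
  if (length(bad_group)) {
    stop("format error in column 'group': unknown level '", bad_group[1], "'")
  }
  bad_frac <- setdiff(unique(annotations$fraction), c("total", "CPLL", "Mv", "Ex"))
  if (length(bad_frac)) {
    stop("format error in column 'fraction': unknown level '", bad_frac[1], "'")
  }
  annotations <- annotations[match(colnames(values), annotations$sample_id), , drop = FALSE]
  rownames(annotations) <- NULL
  structure(
    list(values = values, detected = !is.na(values), annotations = annotations),
    class = "intensity_matrix"
  )
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat("Intensity matrix:", nrow(x$values), "proteins x", ncol(x$values), "samples\n")
  cat("  detected values:",
      sprintf("%d (%.1f%%)", sum(x$detected), 100 * mean(x$detected)), "\n")
  tab <- table(x$annotations$group, x$annotations$fraction)
  cat("  samples per group x fraction:\n")
  print(tab)
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Subset an intensity matrix to the samples of one fraction
#'
#' @param matrix an [intensity_matrix()].
#' @param fraction one of `"total"`, `"CPLL"`, `"Mv"`, `"Ex"`.
#' @return An `intensity_matrix` restricted to that fraction's samples.
#' @export
subset_fraction <- function(matrix, fraction) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  keep <- matrix$annotations$fraction == fraction
  if (!any(keep)) stop("no samples in fraction '", fraction, "'")
  intensity_matrix(matrix$values[, keep, drop = FALSE],
                   matrix$annotations[keep, , drop = FALSE])
}

#' Read a protein-group intensity table
#'
#' Reads a tab-separated protein-group table in the usual label-free search
#' engine dialect: one row per protein group, an identifier column and one
#' raw-intensity column per sample. Zeros and empty cells denote
#' non-detection (the search engine reports no quantification, not a measured
#' zero) and are recorded as missing; detected intensities are log2
#' transformed on read.
#'
#' @param path TSV file path.
#' @param annotations sample-annotation data frame (see [intensity_matrix()])
#'   or path to a TSV with columns `sample_id`, `group`, `fraction`.
#' @param id_column name of the protein-identifier column.
#' @param intensity_prefix prefix prepended to sample ids to form intensity
#'   column names (e.g. `"Intensity "`); use `""` when columns are named by
#'   bare sample id.
#' @return An [intensity_matrix()].
#' @export
read_protein_table <- function(path, annotations, id_column = "Protein IDs",
                               intensity_prefix = "") {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!id_column %in% names(tab)) {
    stop("format error: id column '", id_column, "' not found in ", path)
  }
  if (anyDuplicated(tab[[id_column]])) {
    stop("format error in column '", id_column, "': duplicated protein ids")
  }
  if (is.character(annotations) && length(annotations) == 1L) {
    annotations <- utils::read.delim(annotations, stringsAsFactors = FALSE)
  }
  wanted <- paste0(intensity_prefix, annotations$sample_id)
  missing_samples <- annotations$sample_id[!wanted %in% names(tab)]
  if (length(missing_samples)) {
    stop("format error: no intensity column for sample '", missing_samples[1], "'")
  }
  numeric_cols <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))], id_column)
  extra <- setdiff(numeric_cols, wanted)
  if (length(extra)) {
    warning("ignoring ", length(extra), " intensity column(s) without annotation: ",
            paste(utils::head(extra, 3), collapse = ", "),
            if (length(extra) > 3) ", ..." else "")
  }
  raw <- as.matrix(tab[, wanted, drop = FALSE])
  mode(raw) <- "numeric"
  raw[!is.finite(raw) | raw <= 0] <- NA_real_
  values <- log2(raw)
  dimnames(values) <- list(tab[[id_column]], annotations$sample_id)
  intensity_matrix(values, annotations)
}

#' Write an intensity matrix as a TSV protein table
#'
#' Inverse of [read_protein_table()]: log2 intensities are written back on
#' the raw scale with non-detections as 0, so a write-then-read round trip
#' reproduces the matrix.
#'
#' @param matrix an [intensity_matrix()].
#' @param path output TSV path.
#' @param id_column,intensity_prefix column naming, as in [read_protein_table()].
#' @return `path`, invisibly.
#' @export
write_protein_table <- function(matrix, path, id_column = "Protein IDs",
                                intensity_prefix = "") {
  stopifnot(inherits(matrix, "intensity_matrix"))
  raw <- 2^matrix$values
  raw[!matrix$detected] <- 0
  out <- data.frame(rownames(matrix$values), raw, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c(id_column, paste0(intensity_prefix, colnames(matrix$values)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sample-annotation table
#' @param matrix an [intensity_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(matrix, path) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  utils::write.table(matrix$annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Median-center the samples of an intensity matrix
#'
#' Per-sample median normalization of the log2 intensities: every sample's
#' median detected intensity is shifted to the grand median (the median of
#' all detected values before normalization). The detection mask, protein
#' ordering and missing entries are untouched. With `per_fraction = TRUE`
#' samples are aligned to their fraction's grand median instead.
#'
#' @param matrix an [intensity_matrix()].
#' @param per_fraction normalize within each fraction separately.
#' @return A normalized [intensity_matrix()].
#' @export
normalize_intensities <- function(matrix, per_fraction = FALSE) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  values <- matrix$values
  n_det <- colSums(matrix$detected)
  if (any(n_det == 0)) {
    stop("sample '", colnames(values)[which(n_det == 0)[1]],
         "' has no detected values")
  }
  groups <- if (per_fraction) matrix$annotations$fraction else rep("all", ncol(values))
  for (g in unique(groups)) {
    cols <- which(groups == g)
    grand <- stats::median(values[, cols], na.rm = TRUE)
    med <- apply(values[, cols, drop = FALSE], 2, stats::median, na.rm = TRUE)
    values[, cols] <- sweep(values[, cols, drop = FALSE], 2, med - grand)
  }
  intensity_matrix(values, matrix$annotations)
}

#' Detection/overlap accounting over named protein sets
#'
#' Computes the Venn-style accounting used when comparing protein
#' identifications across groups or fractions: per-set sizes, pairwise and
#' global intersections, per-set exclusive counts, and percentages of a
#' stated denominator under an explicit decimal policy. Published accountings
#' mix truncation and rounding of percentages, so the policy is
#' caller-specified rather than guessed.
#'
#' @param sets named list of character vectors of protein ids.
#' @param denominator denominator for percentages; defaults to the size of
#'   the union of all sets.
#' @param decimals digits kept in percentages.
#' @param rounding `"round"` or `"truncate"`.
#' @return An object of class `overlap_summary`: list with `sizes`,
#'   `pairwise` (intersection-count matrix), `global_intersection`,
#'   `exclusive` (count per set of ids in no other set), `denominator`,
#'   and `percent(count)` applied versions `sizes_pct`, `exclusive_pct`,
#'   `global_intersection_pct`.
#' @export
#' @examples
#' overlap_summary(list(a = c("P1", "P2", "P3"), b = c("P2", "P4")),
#'                 denominator = 4, decimals = 1)
overlap_summary <- function(sets, denominator = NULL, decimals = 1,
                            rounding = c("round", "truncate")) {
  rounding <- match.arg(rounding)
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stop("'sets' must be a named list of id vectors")
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  if (is.null(denominator)) denominator <- length(universe)
  if (!is.numeric(denominator) || denominator <= 0) {
    stop("denominator must be a positive count")
  }
  pct <- function(count) {
    x <- 100 * count / denominator
    f <- 10^decimals
    if (rounding == "truncate") trunc(x * f) / f else round(x * f) / f
  }
  n <- length(sets)
  pairwise <- matrix(0L, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      pairwise[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  global_int <- if (n > 0) length(Reduce(intersect, sets)) else 0L
  exclusive <- vapply(seq_len(n), function(i) {
    others <- unique(unlist(sets[-i], use.names = FALSE))
    length(setdiff(sets[[i]], others))
  }, integer(1))
  names(exclusive) <- names(sets)
  sizes <- vapply(sets, length, integer(1))
  structure(
    list(
      sizes = sizes, pairwise = pairwise, global_intersection = global_int,
      exclusive = exclusive, denominator = denominator,
      sizes_pct = pct(sizes), exclusive_pct = pct(exclusive),
      global_intersection_pct = pct(global_int),
      percent = pct, decimals = decimals, rounding = rounding
    ),
    class = "overlap_summary"
  )
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("Overlap summary over", length(x$sizes), "sets (denominator",
      x$denominator, ")\n")
  tab <- data.frame(size = x$sizes, size_pct = x$sizes_pct,
                    exclusive = x$exclusive, exclusive_pct = x$exclusive_pct)
  print(tab)
  cat("shared by all sets:", x$global_intersection,
      sprintf("(%s%%)", format(x$global_intersection_pct)), "\n")
  invisible(x)
}

#' Percentage of a count under an explicit decimal policy
#'
#' Worked-example arithmetic for published identification accountings:
#' `100 * count / denominator`, truncated or rounded to `decimals` digits.
#'
#' @param count numerator count.
#' @param denominator denominator count.
#' @param decimals digits kept.
#' @param rounding `"round"` or `"truncate"`.
#' @return The percentage as a bare number, e.g. `67.7`.
#' @export
percent_of <- function(count, denominator, decimals = 1,
                       rounding = c("round", "truncate")) {
  rounding <- match.arg(rounding)
  if (denominator <= 0) stop("denominator must be a positive count")
  x <- 100 * count / denominator
  f <- 10^decimals
  if (rounding == "truncate") trunc(x * f) / f else round(x * f) / f
}

#' Read a GMT gene-set file
#'
#' GMT is the tab-separated gene-set format: one set per line as
#' `term<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a term are collapsed.
#'
#' @param path GMT file path.
#' @return Named list; each element is `list(description =, members =)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    }
    term <- fields[1]
    if (term %in% names(out)) stop("malformed GMT line ", i, ": duplicate term '", term, "'")
    out[[term]] <- list(description = fields[2],
                        members = unique(fields[-(1:2)]))
  }
  out
}

#' Write a GMT gene-set file
#' @param gene_sets named list as returned by [read_gmt()] (bare character
#'   vectors are accepted and given empty descriptions).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(term) {
    gs <- gene_sets[[term]]
    if (is.character(gs)) gs <- list(description = "", members = gs)
    paste(c(term, gs$description, gs$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
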