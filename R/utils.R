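#' @keywords internal
"_PACKAGE"

## Shared small helpers. Nothing here is exported.

#' Clip values into an interval
#' @noRd
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a per-stage RNG seed from a master seed
#'
#' Stages draw from distinct substreams so that rerunning one stage with the
#' same master seed reproduces it regardless of what ran before. Kept below
#' 2^31 - 1 so the result is always a valid integer seed.
#' @noRd
substream_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  offsets <- c(
    synthetic = 1L, mds = 2L, network = 3L, diffexpr = 4L,
    ranking = 5L, enrichment = 6L, validation = 7L, pipeline = 8L
  )
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(master_seed) * 101 + offsets[[stage]]) %% .Machine$integer.max)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number in (-1, 1].
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y"))
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  if (n < 2) return(1)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Stop with a labelled configuration/format error
#' @noRd
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

#' Check a scalar threshold lies in a closed range
#' @noRd
check_range <- function(value, field, lo, hi) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < lo || value > hi) {
    config_error(field, sprintf("must be a number in [%s, %s]", lo, hi))
  }
  invisible(value)
}
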