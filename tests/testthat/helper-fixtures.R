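# Shared fixtures, built in code at test time.

# Small complete intensity matrix with annotations, no missing values.
toy_matrix <- function(n_proteins = 10, n_per_cell = 2, seed = 42, sd = 1) {
  set.seed(seed)
  ann <- expand.grid(rep = seq_len(n_per_cell),
                     fraction = c("total", "CPLL", "Mv", "Ex"),
                     group = c("control", "MB"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ann <- data.frame(
    sample_id = sprintf("%s_%s_%d", ann$group, ann$fraction, ann$rep),
    group = ann$group, fraction = ann$fraction, stringsAsFactors = FALSE)
  values <- matrix(rnorm(n_proteins * nrow(ann), mean = 25, sd = sd),
                   n_proteins, nrow(ann),
                   dimnames = list(sprintf("P%03d", seq_len(n_proteins)),
                                   ann$sample_id))
  intensity_matrix(values, ann)
}

# Null generator configuration: no planted structure, no dropout.
null_config <- function(n_proteins = 200, n_per_cell = 3, seed = 1) {
  synthetic_config(
    n_proteins = n_proteins, n_samples_per_cell = n_per_cell,
    module_specs = list(), de_specs = list(),
    exclusive_specs = default_exclusive_specs(0),
    dropout_midpoint = -Inf, seed = seed)
}

# Brute-force topological overlap by triple loop (independent oracle).
tom_brute_force <- function(a) {
  n <- nrow(a)
  a0 <- a
  diag(a0) <- 0
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a0[i, u] * a0[u, j]
      ki <- sum(a0[i, -i])
      kj <- sum(a0[j, -j])
      tom[i, j] <- (l + a0[i, j]) / (min(ki, kj) + 1 - a0[i, j])
    }
  }
  tom
}

# Random valid adjacency (symmetric, unit diagonal, entries in [0, 1]).
random_adjacency <- function(n) {
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# Exhaustive hypergeometric upper-tail by direct summation (oracle).
hyper_tail_brute <- function(k, K, n_sig, N) {
  j <- k:min(K, n_sig)
  sum(choose(K, j) * choose(N - K, n_sig - j)) / choose(N, n_sig)
}
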