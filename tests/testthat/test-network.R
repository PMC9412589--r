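# Co-expression network: soft threshold, adjacency, TOM, modules,
# eigengenes, module-trait correlation.

test_that("scale-free fit is ~1 on an exact power-law degree sequence", {
  # construct connectivities whose binned frequencies follow k^-2 exactly
  k_levels <- 2^(0:7)
  counts <- round(1e4 / k_levels^2)
  k <- rep(k_levels, counts)
  fit <- scale_free_fit(k, n_bins = 8)
  expect_gt(fit$r_squared, 0.97)
  expect_lt(fit$slope, 0)
  expect_error(scale_free_fit(c(1, 1, 1)), "bins")
})

test_that("a single candidate power is a forced choice with a warning", {
  m <- toy_matrix(n_proteins = 30, seed = 7)
  expect_warning(pick <- pick_soft_threshold(m, candidate_powers = 1,
                                             fit_target = 0.999),
                 "no candidate power")
  expect_identical(pick$beta, 1)
})

test_that("soft-threshold selection is deterministic on the default config", {
  gen <- generate_dataset(synthetic_config(seed = 1))
  mat <- normalize_intensities(gen$matrix)
  p1 <- suppressWarnings(pick_soft_threshold(mat))
  p2 <- suppressWarnings(pick_soft_threshold(mat))
  expect_identical(p1$beta, p2$beta)
  expect_equal(p1$fit_table, p2$fit_table)
})

test_that("adjacency is |cor|^beta with unit diagonal", {
  # two perfectly correlated proteins at beta 1
  v <- rbind(P1 = 1:6, P2 = 2 * (1:6) + 3, P3 = c(2, 1, 4, 3, 6, 5))
  colnames(v) <- paste0("s", 1:6)
  a1 <- adjacency_matrix(v, beta = 1)
  expect_equal(a1["P1", "P2"], 1, tolerance = 1e-12)
  # beta = 6, |cor| = 0.5 -> 0.015625: y = 0.5 x + sqrt(0.75) z with x, z
  # zero-mean and orthogonal gives cor(x, y) = 0.5 exactly
  x <- c(-1, 1, -1, 1, -1, 1, -1, 1)
  z <- c(1, 1, -1, -1, 1, 1, -1, -1)
  y <- 0.5 * x + sqrt(0.75) * z
  v2 <- rbind(P1 = x, P2 = y)
  colnames(v2) <- paste0("s", 1:8)
  a6 <- adjacency_matrix(v2, beta = 6)
  expect_equal(a6["P1", "P2"], 0.5^6, tolerance = 1e-12)
  expect_true(all(diag(a1) == 1))
  expect_error(adjacency_matrix(v, beta = 0.5), "beta")
})

test_that("adjacency matches brute-force per-pair correlation then power", {
  set.seed(8)
  v <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("P", 1:10), paste0("s", 1:6)))
  a <- adjacency_matrix(v, beta = 4)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(a[i, j], abs(cor(v[i, ], v[j, ]))^4, tolerance = 1e-12)
  }
})

test_that("TOM matches hand substitution on two proteins and zero on no edges", {
  a12 <- 0.4
  a <- matrix(c(1, a12, a12, 1), 2, 2)
  tom <- topological_overlap(a)
  # l = 0, k = a12 for both: TOM = (0 + a12) / (a12 + 1 - a12) = a12
  expect_equal(tom[1, 2], a12, tolerance = 1e-12)
  expect_equal(diag(tom), c(1, 1))
  tom_id <- topological_overlap(diag(5))
  expect_true(all(tom_id[upper.tri(tom_id)] == 0))
  expect_error(topological_overlap(matrix(2, 3, 3)), "\\[0, 1\\]")
})

test_that("TOM equals brute-force triple-loop evaluation on random matrices", {
  set.seed(9)
  for (rep in 1:30) {
    n <- sample(2:12, 1)
    a <- random_adjacency(n)
    expect_lt(max(abs(topological_overlap(a) - tom_brute_force(a))), 1e-12)
  }
})

test_that("TOM stays within [0, 1] and symmetric for valid adjacencies", {
  set.seed(10)
  for (rep in 1:20) {
    a <- random_adjacency(sample(3:10, 1))
    tom <- topological_overlap(a)
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom), tolerance = 1e-12)
  }
})

# Block-diagonal TOM fixture: tight blocks, a loosely coherent background,
# and near-zero similarity across groups.
block_tom <- function(sizes, within = 0.8, background = 0.12, cross = 0.03,
                      seed = 1) {
  set.seed(seed)
  n <- sum(sizes) + 40
  tom <- matrix(cross + runif(n * n, 0, 0.01), n, n)
  bg_idx <- sum(sizes) + seq_len(40)
  tom[bg_idx, bg_idx] <- background + runif(1600, 0, 0.01)
  start <- 0
  for (s in sizes) {
    idx <- start + seq_len(s)
    tom[idx, idx] <- within + matrix(runif(s * s, 0, 0.02), s, s)
    start <- start + s
  }
  tom <- (tom + t(tom)) / 2
  diag(tom) <- 1
  dimnames(tom) <- list(paste0("P", 1:n), paste0("P", 1:n))
  tom
}

test_that("planted TOM blocks of 30 are recovered exactly", {
  tom <- block_tom(c(30, 30))
  labels <- detect_modules(tom, min_size = 20)
  truth <- c(rep("a", 30), rep("b", 30), rep("grey", 40))
  expect_equal(adjusted_rand_index(labels[1:60], truth[1:60]), 1)
  # background proteins never share a label with the planted blocks
  expect_length(intersect(unique(labels[61:100]), unique(labels[1:60])), 0)
})

test_that("modules below the minimum size fall into the background", {
  tom <- block_tom(c(10, 30, 25))
  labels <- detect_modules(tom, min_size = 20)
  expect_true(all(labels[1:10] == "grey"))           # size-10 block rejected
  expect_identical(length(unique(labels[11:40])), 1L)
  expect_false(unique(labels[11:40]) == "grey")
  expect_error(detect_modules(tom, min_size = 1000), "min_size")
})

test_that("an all-equal TOM yields a single module", {
  tom <- matrix(0.5, 30, 30)
  diag(tom) <- 1
  dimnames(tom) <- list(paste0("P", 1:30), paste0("P", 1:30))
  labels <- detect_modules(tom, min_size = 20)
  expect_identical(unname(unique(labels)), "module1")
})

test_that("module eigengenes match the SVD oracle and orientation rule", {
  m <- toy_matrix(n_proteins = 12, seed = 11)
  labels <- setNames(c(rep("module1", 6), rep("module2", 4), "grey", "grey"),
                     rownames(m$values))
  me <- module_eigengenes(m, labels)
  expect_equal(colnames(me$eigengenes), c("module1", "module2"))
  # unit-normalized columns
  expect_equal(unname(colSums(me$eigengenes^2)), c(1, 1), tolerance = 1e-8)
  # SVD oracle for module1
  x <- m$values[1:6, ]
  xs <- t(scale(t(x)))
  v1 <- svd(xs)$v[, 1]
  if (mean(cor(v1, t(xs))) < 0) v1 <- -v1
  expect_equal(unname(me$eigengenes[, "module1"]), v1, tolerance = 1e-8)
  # positive mean correlation with members
  expect_gt(mean(cor(me$eigengenes[, "module1"], t(xs))), 0)
})

test_that("an identical-profile module explains all variance", {
  profile <- rnorm(16, 25, 2)
  v <- matrix(rep(profile, each = 4), 4, 16,
              dimnames = list(paste0("P", 1:4), NULL))
  m <- toy_matrix(n_proteins = 4, n_per_cell = 2, seed = 12)
  colnames(v) <- colnames(m$values)
  m <- intensity_matrix(v, m$annotations)
  labels <- setNames(rep("module1", 4), rownames(v))
  me <- module_eigengenes(m, labels)
  expect_equal(unname(me$explained_variance), 1, tolerance = 1e-8)
  expect_equal(abs(cor(me$eigengenes[, 1], profile)), 1, tolerance = 1e-8)
})

test_that("a two-protein anticorrelated module still gets an oriented eigengene", {
  m <- toy_matrix(n_proteins = 2, n_per_cell = 2, seed = 13)
  base <- rnorm(16)
  v <- rbind(P1 = base, P2 = -base)
  colnames(v) <- colnames(m$values)
  m <- intensity_matrix(v, m$annotations)
  me <- module_eigengenes(m, setNames(rep("module1", 2), c("P1", "P2")))
  expect_equal(unname(me$explained_variance), 1, tolerance = 1e-8)
  # the eigengene tracks both members perfectly (up to the forced geometry
  # of opposite signs, where the mean-correlation orientation is a tie)
  expect_equal(abs(as.numeric(cor(me$eigengenes[, 1], scale(t(v))))), c(1, 1),
               tolerance = 1e-8)
})

test_that("module-trait correlation flags only real associations", {
  m <- toy_matrix(n_proteins = 2, n_per_cell = 3, seed = 14)
  traits <- trait_indicators(m$annotations)
  # eigengene equal to the MB indicator: rho = 1
  me <- cbind(moduleA = as.numeric(traits[, "MB"]),
              moduleB = rnorm(nrow(traits)))
  tc <- module_trait_correlation(me, traits)
  rho_mb <- tc$rho[tc$module == "moduleA" & tc$trait == "MB"]
  expect_equal(rho_mb, 1, tolerance = 1e-12)
  expect_true(tc$significant[tc$module == "moduleA" & tc$trait == "MB"])
  expect_error(module_trait_correlation(me, cbind(flat = rep(1, 24))), "constant")
})

test_that("BH adjustment is monotone in the raw p-values", {
  set.seed(15)
  p <- runif(50)
  adj <- p.adjust(p, method = "BH")
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
})

test_that("modules are recovered on the default synthetic configuration", {
  gen <- generate_dataset(synthetic_config(seed = 1))
  mat <- normalize_intensities(gen$matrix)
  net <- suppressWarnings(build_network(mat))
  truth <- gen$truth
  planted <- truth$module != "grey"
  ari <- adjusted_rand_index(truth$module[planted],
                             net$labels[truth$protein_id[planted]])
  expect_gte(ari, 0.8)
  # only trait-driven structure is flagged against the traits
  tc <- net$trait_correlations
  flagged <- unique(tc$module[tc$significant])
  expect_gt(length(flagged), 0)
  for (mod in flagged) {
    members <- names(net$labels)[net$labels == mod]
    purity <- mean(truth$trait_driven[match(members, truth$protein_id)])
    expect_gt(purity, mean(truth$trait_driven))
  }
})
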