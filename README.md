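# csfpanel

Multi-stage biomarker discovery for multi-fraction cerebrospinal-fluid (CSF)
proteomics, built as a tested, reproducible R pipeline. The target setting is
a two-group clinical comparison (controls vs. medulloblastoma, "MB") profiled
by label-free LC-MS/MS in four biochemical fractions per patient: total CSF,
a peptide-ligand-library equalized preparation (CPLL), microvesicles (Mv) and
exosomes (Ex). The package is aimed at proteomics and systems-biology
analysts who need every stage of such a workflow — from protein-group tables
to a ranked candidate-biomarker panel with diagnostic statistics — in one
auditable place, with a synthetic-data generator that plants recoverable
ground truth so each stage can be verified at desk scale.

## What the pipeline computes

1. **Ingest & accounting** — MaxQuant-style protein-group TSVs are read with
   zeros treated as non-detections and intensities log2-transformed;
   per-sample median normalization; Venn-style detection/overlap accounting
   with an explicit truncate/round percentage policy.
2. **Sample screen** — Spearman dissimilarity `d = 1 − ρ`, Torgerson
   classical MDS (double-centered Gram eigendecomposition), k-means with
   restarts, and a 3-MAD median-correlation outlier rule.
3. **Co-expression network** — soft-threshold power `β` chosen by the
   scale-free topology fit (`R² ≥ 0.8`), unsigned adjacency
   `a_ij = |cor(x_i, x_j)|^β`, topological overlap

   `TOM_ij = (ℓ_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,
   with `ℓ_ij = Σ_u a_iu a_uj` and `k_i = Σ_u a_iu`,

   average-linkage clustering of `1 − TOM` with a minimum module size of 20,
   module eigengenes (first principal component of the standardized module),
   and Spearman module–trait correlation flagged at `|ρ| > 0.7` with BH
   `p ≤ 0.05`.
4. **Differential expression** — a compound five-part criterion per fraction:
   BH-adjusted Welch-t `p ≤ 0.05`, fold change ≥ 2 (`|log2 FC| ≥ 1`),
   detection in ≥ 70 % of samples of at least one group, per-protein ROC
   AUC > 0.7 (Mann–Whitney rank statistic), and post-hoc power ≥ 0.8
   (noncentral t at the observed effect). A hyperbolic volcano cutoff
   `y = c/(x − x₀)` is provided for visualization thresholds.
5. **Dual ranking** — PLS-DA (NIPALS, 2 components) with variable importance
   in projection, `VIP_j = sqrt( p · Σ_a SSY_a w_ja² / Σ_a SSY_a )`
   (so `Σ VIP² = p` exactly), and linear-SVM recursive feature elimination
   with a stratified 65/35 learning/validation split and fourfold CV; the
   consensus panel keeps proteins with `VIP > 1` and an SVM rank within the
   top `k`, ordered by mean rank, with Spearman concordance reported.
6. **Enrichment** — hypergeometric over-representation of GMT gene sets with
   BH adjustment, a bounded per-term rank value
   `s = clip(± sqrt(k/K)·(1 − q), −1, 1)` per group, and the signed distance
   `d = (s_MB − s_control)/√2` from the equal-enrichment diagonal.
7. **Diagnostic validation** — empirical ROC with trapezoid AUC (provably
   identical to the rank AUC), stratified-bootstrap or DeLong confidence
   intervals, the conventional AUC quality bins (0.9–1 "excellent"), the
   Youden-index cutoff with Clopper–Pearson CIs and likelihood ratio, and
   Kruskal–Wallis with Dunn post hoc z-tests for multi-group assay data.

## Worked example

The demonstration run generates the default synthetic design — 400 proteins,
2 groups × 4 fractions × 3 replicates (24 samples), three planted
co-expression modules (sizes 50/40/30, latent correlation 0.8, the first one
group-associated), 20 planted two-fold discriminant proteins, 32
cell-exclusive proteins, and intensity-dependent dropout — and pushes it
through every stage:

```r
library(csfpanel)
run <- run_demo(seed = 1)
print(run)
#> Pipeline run (seed 1 )
#>   samples: 24  proteins: 400
#>   network beta: 10 ; modules: 4
#>   significant proteins (any fraction): 1
#>   consensus panel size: 78
#>   top-marker AUC: 1.000 (excellent)

str(run$evaluation[c("module_ari", "panel_recovery")])
#> List of 2
#>  $ module_ari    : num 0.976
#>  $ panel_recovery: num 1
```

Reading the numbers: the network stage recovered the planted modules almost
exactly (adjusted Rand index 0.976 against the planted partition; the extra
fourth module is the block of planted discriminant proteins, which genuinely
co-express through their shared group shift). All 20 planted discriminant
proteins were recovered in the 78-protein consensus panel
(`panel_recovery = 1`), and the top-ranked marker separates the groups
perfectly (AUC 1.0, "excellent" bin). The per-fraction compound criterion is
deliberately strict at 3-vs-3 replicates, hence only one protein clears all
five tests — the operating characteristics of that criterion are verified
separately at 6-vs-6 in the test suite. The diagnostic stage prints the full
assay summary:

```r
print(run$validation)
#> AUC 1.000 (1.000-1.000), excellent
#> Youden cutoff 30.6: sensitivity 1.000 (0.735-1.000),
#>   specificity 1.000 (0.735-1.000), LR+ Inf
```

`run_demo(seed, out_dir = "...")` additionally writes every stage table as
TSV plus a JSON manifest with parameters and md5 checksums; reruns with the
same seed are byte-identical.

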