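---
title: "Methods: models, parameters and design choices in csfpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in csfpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfpanel)
```

# The analysis problem

The package implements a complete discovery workflow for two-group clinical
proteomics where each subject contributes several biochemical fractions of
the same biofluid. The motivating setting is cerebrospinal fluid collected
from extraventricular drainage in children, compared between a tumor group
(medulloblastoma, "MB") and non-tumor controls across four preparations:
total fluid, a combinatorial-peptide-ligand-library equalized fraction
("CPLL", which compresses the protein dynamic range and enriches faint
proteins), microvesicles ("Mv") and exosomes ("Ex"). Protein intensities
come from label-free quantification, so the data are log-scale, wide
dynamic range, and missing not at random: low-abundance proteins drop below
the detection limit preferentially.

The workflow answers three questions in sequence: *what co-expression
structure does the proteome have and which parts track the clinical
condition* (network stage); *which individual proteins separate the groups
under conservative compound evidence* (differential-expression stage); and
*which compact ranked panel best discriminates, and how would it perform as
an assay* (ranking and validation stages).

# The synthetic-data generator

Every stage is testable because the generator plants known structure. The
intensity model for protein $i$ in sample $j$ is, on the log2 scale,

$$x_{ij} = b_i + \lambda_m f_{mj} + \delta_i \cdot [\text{MB}, \text{affected fraction}] + \varepsilon_{ij},$$

with

* $b_i \sim U(20, 30)$ — a per-protein baseline over a 10-log2-unit dynamic
  range, shared across samples. The wide range makes intensity-dependent
  dropout bite realistically, which is what gives the 70 % presence filter
  its meaning.
* A one-factor Gaussian block per module: members of module $m$ share a
  latent sample factor $f_{mj} \sim N(0,1)$ with loading
  $\lambda_m = \sigma\sqrt{\rho/(1-\rho)}$, which makes the implied pairwise
  correlation exactly the configured `latent_correlation` $\rho$. A module
  can be *trait-driven*: its latent factor is shifted by `group_effect`
  latent standard deviations in MB samples (default 3 for the first module),
  which is what the module–trait correlation stage is supposed to find.
* $\delta_i$ — the planted effect for the configured discriminant proteins:
  `log2_fc = 2` adds +2 log2 units (a four-fold linear change) in MB
  samples of the affected fractions.
* $\varepsilon_{ij} \sim N(0, \sigma^2)$ with $\sigma = 0.5$ log2 units,
  homoscedastic across groups. Per-group variance structure is not
  identifiable from the motivating design, so equal variances are an
  explicit modelling assumption, not an inference.

Detection applies logistic missing-not-at-random dropout,
$P(\text{detect}) = \text{logit}^{-1}(s\,(x_{ij} - m))$ with midpoint
$m = 19$ and steepness $s = 1$ by default, and then forces the configured
exclusivity patterns: a protein exclusive to one group-fraction cell is
detected in all of that cell's samples and nowhere else, emulating the
Venn-style exclusive identifications seen in multi-fraction studies.

The default design is 2 groups × 4 fractions × 3 replicates (24 samples)
with 400 proteins: three modules of 50/40/30 at $\rho = 0.8$, 20
discriminant proteins affecting all fractions, and 4 exclusive proteins per
cell. What the generator does **not** emulate: peptide/spectrum-level
structure, retention time or m/z, batch effects, fraction-specific global
proteome shifts (fraction structure enters only through exclusivity), and
correlated (module-like) noise among null proteins beyond the planted
blocks. Passing tests therefore demonstrate algorithmic correctness and
recoverability under this model, not performance guarantees on real CSF
data.

# Stage-by-stage choices

## Normalization

The upstream convention for label-free tables is followed: a zero or empty
intensity is a non-detection, never a measured zero. Normalization is
per-sample median centering of detected log2 values onto the grand median —
the standard location alignment for LFQ-style tables; it is monotone,
mask-preserving and idempotent. Whether alignment should be global or
per-fraction is genuinely open in this design; global is the default and a
`per_fraction` flag provides the alternative.

## Sample screen

Classical (Torgerson) MDS was chosen over stress-minimizing variants because
it is a deterministic eigendecomposition, checkable against a
distance-preservation oracle. Axis signs are fixed by making the
largest-magnitude coordinate positive. The outlier rule — flag a sample
whose median Spearman correlation to the others falls more than 3 MADs below
the cohort median — is a deliberately conservative, scale-free screen; no
published rule exists for this step, so the package states one.

## Co-expression network

* **Correlation**: Pearson on pairwise-complete log2 values, the convention
  of weighted co-expression analysis; Spearman is reserved for the sample
  screen and the module–trait stage.
* **Detection filter**: proteins detected in fewer than half the samples do
  not enter the network (`min_detection = 0.5`). Sparsely detected proteins
  — exclusives above all — have pairwise-complete correlations computed on
  as few as 3 shared samples, which are degenerate (often exactly ±1) and
  produce artifactual tight clusters in the topological overlap. Filtered
  proteins remain in the output as background.
* **Unsigned network** (`|cor|^β`): the default of the underlying
  methodology; a `signed` flag is available.
* **Power selection**: smallest candidate power whose scale-free fit
  (R² of the log–log regression of binned connectivity frequency on
  connectivity) reaches 0.8, else the best-fitting power with a warning.
  On planted-module data the degree distribution is not scale-free, so the
  fallback is the common path there; the chosen power is recorded in the
  result and reproducible.
* **Tree cut**: average-linkage clustering of `1 − TOM` with a *static* cut,
  minimum module size 20. The cut height, when not supplied, is chosen by a
  deterministic scan: every merge height of the tree is tried and the lowest
  height that resolves the largest number of clusters of at least
  `min_size` members wins. A fixed default height cannot work here — where
  the background merges is a function of the power and the data, and a
  quantile of the merge heights sits above the point where the tree has
  already collapsed — while the scan is still a static cut (deterministic,
  oracle-testable) and degrades gracefully: an all-equal TOM yields a single
  module. Full dynamic tree cutting remains out of scope.
* **Eigengenes**: first right singular vector of the row-standardized module
  matrix, unit norm, oriented to correlate positively with members on
  average. Missing values are mean-imputed *inside the standardization
  only* (a standardized missing value becomes 0); the imputation is not
  propagated anywhere else.
* **Module–trait correlation**: Spearman of each eigengene against six 0/1
  indicators (MB, control, total, CPLL, Mv, Ex), BH-adjusted across all
  module–trait pairs, flagged at `|ρ| > 0.7` and adjusted `p ≤ 0.05`.

## Differential expression

The compound criterion requires all five of: BH-adjusted Welch-t
`p ≤ 0.05`; `|log2 FC| ≥ log2(2)`; detection in at least 70 % of samples of
one group; orientation-free per-protein AUC `> 0.7`; post-hoc power
`≥ 0.8`. Choices worth stating:

* Welch rather than pooled-variance t is the default (a `student` flag
  exists); variance equality is not assumed from the data.
* "70 % identity in one of two conditions" is read as detection frequency —
  the natural semantics for label-free missingness.
* Missing values are excluded from the t and AUC computations; detection
  evidence is consumed once, by the presence filter, and not double-counted
  through imputation.
* The power criterion is computed post hoc at the observed standardized
  effect via the noncentral t distribution (`power.t.test` agrees to
  numerical precision). Whether the original criterion was a design-stage
  or post-hoc power is ambiguous; the post-hoc value gates by default.
* The volcano cutoff `y = c/(x − x_0)` defaults to `x_0 = 1` (the two-fold
  bound) with `c` calibrated so the curve passes through
  `(2, −log10 0.05)`; a point exactly on the curve is *not* flagged.
* At the default 3-vs-3 per-fraction design this criterion is close to
  all-or-nothing: BH-adjusted p-values at $n = 3$ rarely clear 0.05, so few
  proteins are significant. That is a property of the criterion at small
  $n$, reported as-is; the criterion's operating characteristics (null
  significant fraction ≤ 1 %, recall ≥ 80 % and FDP ≤ 10 % at planted
  two-fold effects) are verified in the test suite at 6-vs-6.

## Dual ranking

PLS-DA is fit by NIPALS against the centered 0/1 class vector on
standardized features, two components by default (the conventional two-axis
view), with the sign of each weight vector fixed by its largest-magnitude
entry. VIP scores use the explained-class-variance weighting and satisfy
$\sum_j \mathrm{VIP}_j^2 = p$ exactly, which the tests assert as an
identity.

The SVM side uses a linear soft-margin machine (`C = 1`, standardized
features) inside recursive feature elimination: refit, drop the feature with
the smallest squared weight, repeat; the reversed elimination order is the
ranking. Accuracy is reported honestly from data the ranking never chose:
stratified fourfold cross-validation on the 65 % learning part and a
confusion matrix on the held-out 35 %.

Both prioritizations run on the **full quantified matrix**, pooling all
fractions' samples with the clinical group as the class; the
machine-learning stage *is* the feature reduction, and the per-fraction
differential-expression tables stand as an independent line of evidence.
(Per-fraction ranking is arithmetically impossible at the default design —
a 65 % learning split of 3 + 3 samples cannot hold 4 samples per class —
and conditioning the ranking on the small-sample significant set would make
the panel inherit that stage's instability.) Non-detections are imputed at
half the protein's minimum detected intensity (minus one log2 unit), the
standard low-abundance choice for classifier inputs.

The consensus panel keeps proteins with `VIP > 1` (greater-than-average
importance) and SVM rank within `top_k`, where `top_k` defaults to the
VIP-selected count so the two methods nominate panels of comparable size;
ordering is by the mean of the two rank positions and the Spearman
concordance between the rankings over the consensus is reported rather than
assumed. One behaviour deserves emphasis: L2-regularized linear SVMs share
weight across correlated features, so recursive elimination scatters the
individual ranks of a redundant block (for example a planted co-expressed
discriminant block) even when the block as a whole is informative. The VIP
side does not have this pathology, which is exactly why the panel is a
consensus of the two rather than either alone.

## Enrichment

Over-representation uses the one-sided hypergeometric tail against the
quantified universe with BH adjustment across terms — a term-level test
matching the term-level rank statistic reported, rather than a running-sum
enrichment walk. The bounded per-term score,

$$s = \mathrm{clip}\left(\pm\sqrt{k/K}\,(1 - q),\ -1,\ 1\right),$$

with $k$ significant members, $K$ members in the universe, $q$ the
FDR-adjusted p, and the sign set by whether the term's mean fold change
favors the scored group, is one concrete instantiation of a score that is
bounded in $[-1, 1]$, increasing in coverage, shrunk by weak evidence, and
group-oriented — the published description constrains the ingredients but
not the formula, so the function is isolated behind a single interface to
be swappable. The scatter geometry places each term at
$(s_{MB}, s_{control})$; the signed perpendicular distance from the $x = y$
diagonal, $d = (s_{MB} - s_{control})/\sqrt{2}$, is antisymmetric under
group exchange (a tested property).

## Diagnostic validation

The empirical ROC sweeps every observed threshold; the trapezoid area
equals the Mann–Whitney rank AUC on every instance (tested as an identity,
and cross-checked against an independent ROC implementation). The AUC
confidence interval is a stratified bootstrap percentile interval by
default — distribution-free and honest at small n — with the DeLong
asymptotic interval behind a flag. Qualitative AUC bins are upper-inclusive
(0.9 grades "excellent", exactly 0.5 "not discriminant"). The Youden cutoff
maximizes sensitivity + specificity − 1 with ties broken toward the lower
cutoff; sensitivity and specificity carry Clopper–Pearson intervals, and
LR+ is reported as `Inf` at specificity 1. Multi-group assay comparisons
use the tie-corrected Kruskal–Wallis test with Dunn z post hoc tests under
BH adjustment; quantiles are type-7 (linear interpolation).

# Reproducibility machinery

Every stochastic stage draws its seed from a substream of the master seed,
so partial reruns reproduce regardless of stage order. `run_pipeline()`
writes self-describing TSVs plus a JSON manifest (package version, seed,
all operating thresholds, md5 checksum per file); reruns with an identical
configuration are byte-identical, which the test suite asserts.

# Problem sizes used in verification

The test suite and the acceptance script verify the stages at deliberately
desk-scale sizes: the default 400 × 24 design for network and end-to-end
checks; 1000 proteins × 6-vs-6 for differential-expression operating
characteristics (50 null replicates); 200 random matrices up to 12 × 12 for
the topological-overlap brute-force identity; 100 random instances for the
SVM-RFE pick property and 50 label permutations for the chance-level check;
500 random instances for the AUC identity. These sizes were chosen as the
smallest at which the corresponding statistical statements are stable.

# Known limitations

* The static-cut module detection does not implement dynamic tree cutting;
  deeply nested module structure will be under-resolved.
* The compound DE criterion has essentially no power below ~5 replicates
  per group per fraction; this is inherent to BH-adjusted t-tests at that
  size, not a tuning issue.
* SVM-RFE ranks of individual members of highly correlated blocks are
  unstable by construction; interpret the consensus panel, not raw SVM
  ranks, for redundant features.
* The enrichment rank-value formula is a stated convention, not an
  identified quantity; comparisons across tools should use $k$, $K$, $q$
  and the fold-change direction, which are conventional.
* No peptide-level inference, no identification FDR, no batch correction:
  the pipeline starts from a quantified protein-group table.
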