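Package: csfpanel
Title: Co-Expression Network and Machine-Learning Biomarker Discovery for
    Multi-Fraction CSF Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reproducible implementation of a multi-stage
    biomarker-discovery workflow for label-free proteomic profiling of
    cerebrospinal fluid analyzed in several biochemical fractions (total,
    peptide-library equalized, microvesicle and exosome preparations).
    Stages cover detection/overlap accounting of protein-group intensity
    tables, median normalization, multidimensional-scaling sample screens,
    weighted co-expression network construction (soft thresholding,
    topological overlap, module detection, module eigengenes and
    module-trait correlation), a compound differential-expression
    criterion (moderated by presence, fold change, per-protein ROC AUC
    and post-hoc power), dual feature prioritization by PLS-DA variable
    importance and linear-SVM recursive feature elimination, a bounded
    two-group gene-set enrichment score, and diagnostic-performance
    statistics (ROC with bootstrap confidence intervals, Youden cutoff,
    likelihood ratios, Kruskal-Wallis with Dunn post hoc tests). A
    synthetic-data generator with planted co-expression modules,
    discriminant proteins, exclusivity patterns and intensity-dependent
    dropout provides recoverable ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    mclust,
    yaml
Config/testthat/edition: 3
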