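Package: dyneqtl
Title: Dynamic eQTL Mapping for Single-Cell Differentiation Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lineage-aware dynamic expression quantitative trait locus (eQTL)
    mapping for single-cell differentiation time courses. Provides pseudotime
    quantile binning and pseudobulk aggregation with TMM normalization,
    cell-line-collapsed principal-component covariates, genotype-by-time and
    genotype-by-cell-type-proportion interaction models with gene-level
    Bonferroni and Storey q-value correction, permutation and
    genotype-correlation calibration controls, a linear-mixed-model simulation
    study of selective-inference type I error, non-negative least squares
    cell-type deconvolution, and a synthetic-data generator emulating a
    bifurcating iPSC-to-cardiomyocyte/cardiac-fibroblast design with a
    complete truth ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    edgeR,
    lme4,
    pracma,
    vcfR,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
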