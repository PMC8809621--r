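---
title: "Methods: lineage-aware dynamic eQTL mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage-aware dynamic eQTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the statistical methods it
implements: the models and their assumptions, the tunable parameters and
why their defaults are what they are, what the synthetic-data generator
emulates (and deliberately does not), and the numerical and design choices
made where more than one reasonable option existed.

## The problem

In a differentiation time course run across many genotyped cell lines, a
cis-regulatory variant's effect on a gene need not be constant: an eQTL may
act only in pluripotent cells, only in a terminal cell type, or grow and
fade as cells mature. Bulk RNA-seq of such a course confounds three things:
regulatory dynamics, differences in how fast lines differentiate, and
differences in which lineage their cells prefer. Single-cell data lets us
unbundle them — pseudotime replaces wall-clock day as the maturation axis,
and lineage assignment isolates each branch of a bifurcating landscape
(here cardiomyocyte, CM, versus cardiac fibroblast, CF, with iPSC,
mesoderm, cardiac mesoderm and progenitor stages shared by both branches).

The pipeline's units of analysis are *pseudobulk samples*: sums of UMI
counts over all cells of one cell line within one pseudotime quantile bin
of one lineage. Working at this level trades single-cell resolution for
stable expression estimates and a tractable linear-model framework.

## Pseudobulk construction and normalization

Cells pass QC first (gene detected in ≥ 10 cells; doublet probability
≤ 0.3; unambiguous line assignment; mitochondrial fraction ≤ 0.25; ≥ 300
genes detected, recomputed after the gene filter; removal of cells whose
feature or read counts sit more than 4 SD from the median). "Maximum" and
"minimum" thresholds are read inclusively; the outlier rule is strict.
The SD in the outlier rule is the ordinary standard deviation with the
distance measured from the median; a MAD variant is available
(`robust = TRUE`). The outlier step re-estimates its scale on whatever
population it is given, so re-running the full QC pass can trim a handful
of additional boundary cells — the metadata-threshold filters themselves
are exactly idempotent.

Three aggregation schemes are supported: by collection day; by day within
each lineage; and by pseudotime quantile bins within each lineage (the
default analysis scheme, 16 bins). Bins are computed on the lineage's cells
pooled across lines — so a fast line contributes more cells to late bins —
with ties broken by stable input order against a rank-and-split oracle.
The time covariate `t` is the day for day schemes and the member cells'
median pseudotime (lower median, for determinism) for the binned scheme.
Pseudobulk samples with library size below 10,000 are dropped.

Aggregation sums raw UMI counts. Between-sample normalization is TMM with
singleton pairing (`TMMwsp`), suited to sparse pseudobulk columns, followed
by a library-size-adapted log2 CPM: with effective library
`L*_s = lib_s × factor_s` and sample-scaled pseudocount
`p_s = prior · L*_s / mean(L*)`,

    expr_gs = log2( (x_gs + p_s) / (L*_s + 2 p_s) · 1e6 ),  prior = 2.

The factor computation delegates to edgeR — the canonical implementation —
and the logCPM formula is implemented directly and cross-checked against
`edgeR::cpm()` in the test suite. Bulk read counts enter the same path
after division by gene length in kb (RPK), which makes the output logTPM.

## Covariates: cell-line collapsed PCA

Broad line-level differences — differentiation speed, lineage preference,
line-specific expression — can masquerade as dynamic eQTLs, because
genotype is constant within a line. To absorb them, the normalized
expression is rearranged into a matrix with one row per cell line and one
column per (gene, time unit) pair, each column standardized to mean 0 /
variance 1, and decomposed by PCA. Each line receives one score vector
(default: 5 PCs) that is broadcast to all of its samples and entered into
every model both as a main effect and interacted with time.

A line can be missing some (line, bin) samples (depth filtering removes
late fibroblast bins for some lines). Those entries are zero-filled *after*
standardization — equivalent to column-mean imputation — which keeps every
line in the decomposition without inventing signal.

## The dynamic eQTL model

For each cis pair (variant within 50 kb of the TSS, inclusive; sample MAF
≥ 0.1; no missing dosages; gene with ≥ 0.1 CPM in ≥ 10 samples and ≥ 6
counts in ≥ 10 samples), the linear dynamic model is the OLS fit

    E_ct ~ mu + b1 G_c + b2 t + b3..b7 PC_c + b8..b12 PC_c t + b13 G_c t

with expression standardized per gene across the lineage's samples and
genotype left on the dosage scale (0–2). The genotype-by-time coefficient
b13 is tested two-sided against a t distribution on N − 14 degrees of
freedom. The quadratic model adds t², PC t² and G t² (21 coefficients) and
tests the G t² term only; the G t term is controlled but not tested. The
interaction p-value is invariant to affine maps of t and of E (verified as
a property test), so pseudotime is used raw.

Cell-type interaction eQTLs replace t with a deconvolved cell-type
proportion K. Three variants: the base model (t ↦ K); a model additionally
adjusting for *all* cell-type proportions as main effects (the unknown-type
column must be excluded — proportions sum to one and the design would be
singular); and a model using m sample-level expression PCs in place of the
proportion main effect. In every variant the tested term is the final G·K
interaction. Static per-context eQTLs (one day or one cell type at a time)
are plain `E ~ G + 5 sample PCs` fits whose effect and SE are exported for
downstream cross-context sharing analyses, which are out of scope here.

Multiple testing is gene-level: per gene, the strongest variant's p-value
is Bonferroni-adjusted by the number of variants tested for that gene;
Storey q-values are then computed across genes. The π0 estimator uses the
λ grid 0.05–0.95 (step 0.05) with a 3-df cubic smoothing spline evaluated
at the largest λ, clipped to (0, 1]; below 20 genes, π0 is fixed at 1
(conservative). π1 = 1 − π0 of a replication p-value set measures
replication.

Singular designs (constant dosage within the tested samples, collinear
proportions) are flagged and excluded from multiplicity rather than
reported as p = NA discoveries.

## Calibration controls

Three controls probe the test's null behavior:

- *Interaction-term permutation*: per test, an independent permutation of
  t inside the G·t column only (a switch also permutes the PC·t columns);
  the base t column keeps the true ordering. This isolates the interaction
  term's contribution.
- *Cell-level pseudotime permutation*: pseudotime is permuted across the
  lineage's cells, cells are re-binned and re-aggregated, and the scan is
  re-run B times; the per-gene empirical p is `(1 + #{|t_b| ≥ |t_obs|}) /
  (B + 1)` (add-one estimator — never zero, floor exactly 1/(B+1)).
- *Genotype-correlation check*: if line clusters with shared behavior drove
  the hits, lines would correlate in genotype across the top hits. The mean
  absolute off-diagonal of the line-by-line dosage correlation matrix over
  the top 200 hits is compared with 500 resampled variant sets matched on
  MAF (bins of 0.05) and distance to the nearest TSS (bins of 10 kb); thin
  matching bins fall back to MAF-only matching with a warning.

A t-test on terminal-type composition differences between within-batch and
cross-batch day-11/day-15 sample pairs checks that batch does not drive
cell-type assignment.

### Why the dynamic eQTL t-test is conservative on realistic data

On null data from the realistic generator (no genetic effects), the
interaction p-values are *not* uniform: they are right-shifted
(conservative), with roughly 1–3% of tests below 0.05. The mechanism is
residual-variance inflation: marker-gene bumps, terminal-branch offsets and
the log/count transforms make each gene's expression a nonlinear function
of pseudotime shared across lines, and a linear-in-t model leaves that
lack-of-fit in σ̂² while the genotype-by-time contrast — orthogonal to any
line-shared trend — gains no corresponding variance. Replacing the linear
time main effect with pseudotime-bin fixed effects restores uniformity in
our diagnostics, and under a model-faithful null (flat expression surface,
homogeneous lines) the end-to-end pipeline is calibrated. Unabsorbed
per-line expression offsets (beyond what 5 line PCs capture) act the same
way. The practical consequence is that t-based p-values *understate*
significance on data with strong nonlinear trajectories — type-I error is
controlled, power is given up — which is the same direction reported by the
permutation-based empirical nulls in this analysis style. The package's
uniformity property tests therefore use the model-faithful null
configuration; the conservative behavior under realistic trends is asserted
(and bounded) rather than hidden.

## The selective-inference simulation

Inferring pseudotime from the same expression matrix that is subsequently
tested ("double dipping") could inflate type-I error. The study simulates

    Y_ijk = beta_k G_ik + alpha_k M_ij + a_ik + eps_ijk

for individuals i = 1..n (10 or 20), cells j = 1..100 and genes
k = 1..1000, with MAF_k ~ U(0.1, 0.5), G_ik ~ Binomial(2, MAF_k),
beta_k ~ N(0, sigma_beta²) (0.1 or 0.4 — about 0.4% and 6.3% of expression
variance on average), maturity M_ij ~ N(0, 1) with effect
alpha_k ~ N(0, sigma_alpha²), individual effects a_i· ~ N(0, sigma² Σ) and
errors eps_ij· ~ N(0, D Σ D). The constraint sigma_alpha² + sigma² = 0.3
makes maturity plus individual effect explain 30% of variance, with the
ratio sigma_alpha²/sigma² varied over {0, 0.1, 0.5, 1, 2, 10}.

One stated property of the model — scalar error variance — cannot coexist
with another — unit variance for every gene — because beta_k and alpha_k
vary by gene. We resolve this in favor of exact unit variance: the error
scale is per-gene, `sigma_e,k² = 1 − beta_k² 2 p_k (1 − p_k) − alpha_k² −
sigma²`, with error covariance D Σ D (D diagonal of sigma_e,k); genes whose
residual variance would fall below 0.01 have beta_k and alpha_k re-drawn,
and the number of re-draws is recorded in the truth ledger. The re-draw
truncation pulls the realized maturity-plus-individual share slightly below
30% (typically 28–29%); it is reported as realized, not corrected. Σ
defaults to a 10-factor low-rank correlation matrix standardized to unit
diagonal — a stand-in for the empirical expression correlation the original
study took from its own pseudobulk, which is not available; identity and
user-supplied matrices are accepted.

Pseudotime is then defined as PC1 of the pooled, gene-centered cell
matrix; cells are cut at the global PC1 tertiles (per-individual tertiles
are available); expression and pseudotime are averaged per (individual,
bin); and each gene is tested for the G·t interaction with (1) OLS and (2)
a random-intercept-per-individual mixed model. All genes are null for the
interaction by construction, so the fraction of p < α is the type-I error.
The fixed-effect model is conservative on this design; the mixed model
shows moderate inflation — both directions are asserted in the tests.

Mixed-model inference was left open by the source material. We use a Wald
t-test on n − p residual degrees of freedom rather than a Wald z, so the
mixed model degenerates *exactly* to the OLS t-test when the REML variance
estimate hits the zero boundary (where lme4 fits are singular and the
package substitutes the OLS fit, flagged `boundary`). A likelihood-ratio
test is available via `test = "lrt"`. Note that even with a true grouping
variance of zero, REML estimates a positive variance for a sizable minority
of genes — chance structure in 30 samples — so LM and LMM p-values track
each other closely but do not match gene-for-gene.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions used throughout the test suite.

Per cell: pseudotime ~ Beta with mean `clamp(speed_line × day / max(day),
0.02, 0.98)` and concentration 8 (`pt_concentration`); cells past the
bifurcation pseudotime 0.35 commit to CM with per-line probability
`lineage_pref` (default drawn U(0.25, 0.75); speed drawn log-normal with
sdlog 0.15). Cell types follow fixed pseudotime thresholds (IPSC < 0.15 <
MES < 0.30 < CMES < 0.45 < PROG < 0.60 < terminal CM/CF by branch). Log
expression is `a_g + b_g t` (baseline N(0,1), slopes N(0, 0.8²)) plus a
Gaussian marker bump for 30% of genes (amplitude 1.5, width 0.12, centered
on a random type's pseudotime midpoint; terminal-type bumps respect the
branch), terminal-branch offsets N(0, 0.6²), gene-specific per-line offsets
N(0, 0.2²), and the planted genetic effects `(γ1 + γ2 t + γ3 t²) G`,
applied to all cells for lineage `"all"` or to terminal cells of the stated
branch — confining a "CM dynamic eQTL" to the branch where that regulatory
program runs. Counts are negative binomial (shared dispersion 0.5 — typical
droplet-data overdispersion) around depth-scaled softmax rates with
per-cell depth log-normal(log 2500, 0.4). A 5% fraction of cells is planted
to fail exactly one QC filter, and 2% are labelled `UNK`. These magnitudes
were chosen once as representative of iPSC-panel droplet data; they are
configuration, not constants.

What the generator does *not* emulate: realistic transcriptome-wide
co-expression, read-level sequencing artifacts, ambient RNA, doublet
transcriptome mixing (`doublet_prob` is metadata only), or cell-cycle
structure. Consequently, passing tests demonstrate the pipeline's
statistical behavior under controlled truth — calibration, power, lineage
specificity, recovery — not robustness to every artifact of real droplet
data.

Bulk samples are synthesized by summing all of a (line, day) sample's cells
across lineages and scaling each gene by its length in kb, mimicking
read-based (length-biased) quantification; true cell-type proportions are
recorded for deconvolution assessment.

## Deconvolution

Cells are split 60/40 by type; markers are chosen per type by one-vs-rest
Wilcoxon rank-sum on log1p-CPM (top 25 per type by BH-adjusted p, ties by
log fold change), intersected with the bulk gene set. The signature matrix
is the per-type sum of training counts, TMMwsp-normalized and converted to
CPM, restricted to markers. Proportions solve non-negative least squares
`min ‖S f − m‖², f ≥ 0` per sample, renormalized to the simplex — the
solution is invariant to positive rescaling of the mixture. NNLS here is a
transparent, self-contained stand-in for heavier machine-learning
deconvolution services; it is assessed on synthetic held-out pseudobulk
(mean absolute error ≤ 0.05 with well-separated types) and is not claimed
to match those services on real bulk data. The solver is
`pracma::lsqnonneg` with an internal Lawson–Hanson fallback for
nearly-collinear signatures on which pracma's fixed iteration cap can
trip.

## Numerical choices and degenerate inputs

- OLS fits use QR; rank-deficient designs are flagged `singular`, not
  silently pseudo-inverted.
- Quantile binning breaks pseudotime ties by stable input order; all
  pseudotimes equal puts every cell in bin 0 with a warning.
- Zero-SD features in the outlier rule remove nothing; zero-variance
  covariates report R² = 0 with a warning.
- Empirical p-values use add-one estimators everywhere (floor 1/(B+1)).
- Identical seeds give bit-identical generator output; permutation and
  resampling routines record their seeds.
- Positions are 1-based throughout (VCF convention); the cis window
  |pos − TSS| ≤ 50 kb is inclusive at the boundary.

## Problem sizes

The shipped tests and simulations run at deliberately reduced sizes chosen
to exercise every code path at desk scale: 19 lines × 7 days × 30–60 cells
per sample, 120–250 genes with 5–20 cis variants each for pipeline tests;
1000 genes × 10 individuals × 100 cells for the selective-inference
generator (500 genes for the type-I grid); 10 seeds for calibration
replicates; B ≈ 20 for nested permutation checks. All statistical claims
scale with these sizes through the stated Monte-Carlo standard errors.

## Known limitations

- Aggregation sums raw UMI counts; variance-stabilized ("corrected") counts
  from single-cell normalization models are out of scope, and TMM + logCPM
  carries the depth normalization instead.
- The dynamic model is linear (or quadratic) in pseudotime; strongly
  nonlinear trajectories make the t-test conservative (see above) rather
  than invalid.
- Storey's π1 on small or highly dependent replication sets is noisy; the
  estimator warns below 50 p-values.
- Pseudotime and lineage labels are *inputs*: trajectory inference itself
  (diffusion maps, graph abstraction) is upstream and out of scope.
- Cross-context empirical-Bayes sharing of static eQTLs is exported-for,
  not implemented.
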