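---
title: "Coupled methylation-expression analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled methylation-expression analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Tumor subtypes that lack targetable receptors (the motivating case is
triple-negative vs triple-positive breast cancer) need subtype-specific
markers. Single-omics screens are noisy: a methylation change with no
expression consequence, or an expression change with no regulatory
signature, is a weak candidate. `methex` couples the two: a gene counts
only when a promoter-proximal or gene-body methylation shift *and* an
expression shift co-occur, each passing its own significance and magnitude
cutoff. The coupled unit (a DMEG — differentially methylated and expressed
gene) is then stress-tested as a classifier feature set, and upregulated
DMEGs are cross-referenced against a drug-target table.

# Scales and statistics

**β and M.** β = M/(M+U+100) estimates the methylated fraction of alleles;
the offset of 100 guards low-intensity probes and keeps β < 1. Group
testing runs on the logit2 scale m = log2(β/(1−β)), where variance is far
more homogeneous across the (0,1) range; effect-size filtering stays on
the β scale, where a difference of 0.2 means "20 percentage points of
methylation". This dual-scale contract is deliberate and is asserted in
the tests: the t statistic comes from M-values, the Δβ filter from β.

**Region aggregation.** A gene's per-region summary is the *geometric*
mean 2^((Σ log2 βᵢ)/k) of its k CpG βs. Note this is not the arithmetic
mean, although the two agree when CpGs in a region are homogeneous; the
geometric form is the formula this pipeline is contracted to, and the
AM-GM inequality (geometric ≤ arithmetic, equality iff constant) is kept
as a property test. Region membership comes exclusively from the
annotation file (the Illumina-manifest dialect: ";"-joined gene and region
columns, positionally paired); nothing is recomputed from coordinates, and
one probe may legitimately feed several (gene, region) units.

**Moderated testing.** Per feature, the pooled two-group variance s²_g
with d_g = n₁+n₂−2 df is shrunk towards a prior (d₀, s₀²) estimated by
moments matching on log s²_g: the excess of var(log s²_g) over the
expected trigamma(d_g/2) scatter identifies d₀ through a trigamma
inversion (Newton iteration), and the mean identifies s₀². The posterior
variance (d₀s₀² + d_g s²_g)/(d₀+d_g) gives t with d₀+d_g df. Two limits are
exposed for verification: d₀ = 0 reproduces the ordinary pooled t exactly,
and d₀ = ∞ gives a z-like statistic with fixed s₀². The test suite checks
the default path against limma's `lmFit`/`eBayes` (a Suggests-only oracle;
the package never calls limma at run time). Features with fewer than 2
non-missing values in a group are reported as untestable (NA) rather than
dropped; zero-variance features are excluded from the moment matching, and
below 10 testable features the prior falls back to d₀ = 0 with a warning.

**Multiplicity.** Benjamini-Hochberg step-up with cumulative-min
enforcement, NA passed through without counting towards m. Families follow
the analysis design: all sites form one family, each region label is its
own family at region level, expression is one family. The implementation
uses the ratio form (m/i)·p(i) so that adjusted ≥ raw holds also in
floating point (and is bit-identical to `stats::p.adjust(..., "BH")`).

**Calls and quadrants.** All thresholds are strict inequalities: adj
p < 0.05 with Δβ > 0.2 (hyper) or < −0.2 (hypo); adj p < 0.05 with
log2FC > 2 (up) or < −2 (down). Boundary values (Δβ = 0.2, logFC = 2, adj
p = 0.05 exactly) therefore produce no call — asserted explicitly. A DMEG
record exists per (gene, region) and carries one of four patterns (HypoUp,
HypoDown, HyperUp, HyperDown) from the sign pair; a gene may carry
different patterns in different regions and all records are kept (no
filtering of conflicting regions — the conservative choice where the
analysis design is silent).

# Classifier evaluation

Separability of the two groups is measured on two feature sets: the β
values of called DMSs inside DMEGs restricted to TSS1500+TSS200 (the
promoter-proximal sites most plausibly regulatory), and the log2
expression of DMEG genes. Scores are leave-one-out: sample i is scored by
a forest trained on everything except i.

The random forest is implemented in the package (compiled code): CART
trees, gini splits, mtry = ⌊√p⌋ features per split, 500 trees by default
(the conventional default), majority-vote leaves, vote fraction as the
continuous score. One deviation from the textbook recipe is deliberate:
each tree trains on a *balanced* bootstrap (min(n₁, n₀) draws with
replacement per class) rather than a plain bootstrap. In leave-one-out
folds the training classes always differ by one, and with plain bootstrap
that asymmetry biases every vote fraction against the held-out sample's
class — under permuted labels the LOOCV AUC then sits visibly below 0.5
(we measured ≈ 0.28 on 80 samples) instead of at chance. Balanced
per-class sampling removes the bias at its source; under permutation the
AUC returns to the chance band. A dependency-free nearest-centroid
classifier is available as a fallback (`classifier = "nearest_centroid"`).

ROC curves come from a threshold sweep with tied scores grouped (midrank
convention), so the trapezoid AUC equals the Mann-Whitney pairwise
statistic exactly — the test suite brute-forces this equality. The AUC
p-value is the one-sided Mann-Whitney normal approximation with tie
correction; a Monte-Carlo permutation alternative is available for small
cohorts and the two agree within Monte-Carlo error in the tests.
Stratified evaluation re-runs LOOCV within covariate levels (age
dichotomized at >50 years, stages III and IV pooled, other covariates by
level), skipping strata with fewer than 3 samples in a class.

# The synthetic cohort: what it emulates, what it does not

The generator states one world and the tests measure it; none of its
parameters were adjusted to make a test pass.

- **Baseline methylation**: each CpG's baseline β is drawn from the
  classic bimodal 450K mixture — Beta(2,10) (unmethylated mode) or
  Beta(10,2) (methylated mode), 50/50.
- **Planted effects**: default 20 genes of 200, planted in both TSS1500
  and TSS200, |Δβ| = 0.4, |log2FC| = 4, pattern mix dominated by HypoUp
  (12/20) with HyperDown the runner-up — the mix the quadrant analysis
  expects to be typical. For planted CpGs the baseline is drawn from the
  mixture component compatible with the direction (a hypomethylation
  effect needs a methylated baseline, a hypermethylation effect an
  unmethylated one), rejection-sampled so the shifted target stays inside
  (ε, 1−ε); an infeasible target errors naming the gene. The truth table
  records the *realized* noiseless region-level Δβ, not the nominal
  target, so recovery tests compare like with like.
- **Noise**: Gaussian with sd 0.5 on the M scale per cell (a typical
  between-sample spread for 450K data), mapped back to β — values can
  never leave (0,1). Expression: gene baseline ~ N(8, 2) log2 units, group
  effect added to cases, per-cell Gaussian noise sd 1.
- **Covariates**: age ~ N(58, 10) (clamped 30-85), menopause linked to age
  but not group, race 75/25, stage 25/50/25 — all independent of the
  case/control label, which is exactly the property the stratified
  analysis is meant to confirm.

Not emulated: probe-type (I/II) chemistry bias, batch effects, copy-number
confounding, cross-reactive probes, missingness patterns. A green test on
this world therefore establishes algorithmic correctness (the pipeline
finds what is there, at the stated effect sizes, and nothing in null
data) — not robustness to the artifacts of real arrays, which upstream
preprocessing is expected to handle (IDAT parsing and normalization are
explicitly out of scope).

# Numerical choices and degenerate inputs

- β clamping into [1e-6, 1−1e-6] before any logit, with a count of clamped
  cells reported; file-supplied 0/1 values would otherwise produce
  infinite M-values.
- NA β cells are excluded pairwise from means/variances; a feature is
  untestable (NA statistics, call "none") if any group has < 2 non-missing
  values.
- Zero-variance features with zero effect are defined as t = 0, p = 1.
- Ties in scores are handled by the midrank convention throughout
  (ROC steps, U statistic, tie-corrected variance); all-tied scores give
  p = 0.5 (no information).
- Forest determinism: the fold-i forest is seeded with seed + i from a
  dedicated Mersenne Twister, so results are reproducible and independent
  of R's global RNG state; the generator and pipeline save and restore
  `.Random.seed`.

# Known limitations

- The moderated test supports only the two-group contrast; covariates
  enter via stratified evaluation, not via the linear model.
- Drug mapping is an exact join on upper-cased symbols against a local
  snapshot; no alias expansion, no live database access. The shipped table
  is fictitious (named `synthetic_drug_targets.tsv` accordingly) and
  exists so the join logic is testable.
- Gene-category allocation requires a user-supplied map; none is bundled.
- External validation on independent cohorts, and docking or
  molecular-dynamics follow-up of drug-target pairs, are out of scope by
  design.
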