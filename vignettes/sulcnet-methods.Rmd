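---
title: "Sulcal phenotype networks: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sulcal phenotype networks: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sulcnet)
```

# The analysis chain

`sulcnet` analyses the shape of cortical folds (sulci) as a network problem.
For each subject, five shape phenotypes are measured on each of 40 sulci:
average depth (AD), depth variability (DV), longest branch (LB), branch
span (BS) and fractal dimension (FD). The pipeline proceeds:

1. **SPN construction.** Each phenotype is Z-scored across the 40 sulci
   within a subject, and the sulcal phenotype network (SPN) is the 40 x 40
   Pearson correlation matrix of the resulting 5-element shape profiles.
   Sulci with similar shape profiles (e.g. two deep, unbranched, "linear"
   sulci) correlate positively.
2. **Eigen-fold index.** The first principal component of the element-wise
   mean SPN of control subjects (column-centered, unstandardized) orders
   sulci along the linear-to-complex axis — the dominant, bimodal mode of
   sulcal shape organization.
3. **Complexity scores.** A subject's complexity for sulcus *i* is the
   correlation of their SPN row *i* with the eigen-fold index, Fisher-Z
   transformed. High scores mark sulci sitting at the complex pole of the
   subject's own shape organization.
4. **Syndrome effect maps.** Per sulcus, an OLS model
   `z(score) ~ group + age + TTV + EN + sex + site` yields a standardized
   case-control effect (the group beta), with Bonferroni (p < 0.05/40) and
   nominal flags. TTV is total tissue volume; EN (Euler number) indexes
   scan quality.
5. **Contraction test.** After residualizing scores for all covariates
   except group, a random-intercept mixed model `resid ~ group + (1 |
   subject)` is fitted separately for the linear and complex sulcal
   classes. Contraction — de-differentiation of the axis — is declared when
   the linear class shifts up (one-sided beta > 0) *and* the complex class
   shifts down (one-sided beta < 0).
6. **Spatial statistics.** Correlations between per-sulcus maps are tested
   against spin permutation nulls (random 3-D rotations of a spherical
   parcellation, mirrored across hemispheres). Cross-syndrome effect-map
   collections are summarized by column-centered PCA whose components are
   validated by permuting each map across sulci.
7. **GWAS phenotype preparation.** Fisher-Z complexity scores are filtered
   (single-pass outlier exclusion at mean +/- 5 SD), rank-inverse-normal
   transformed (Blom offset 3/8), and residualized on age, age^2, sex,
   age x sex, age^2 x sex, site and EN. Nyholt's effective-test count from
   the phenotype correlation eigenvalues sets experiment-wide thresholds
   (5e-8 / meff for SNPs; 0.05 / n_genes / meff for genes). A minimal
   additive-dosage OLS scan, greedy clumping at r^2 < 0.1 and positional
   gene mapping with a symmetric 10 kb window complete the arm.
8. **Fetal expression modules.** Candidate genes are clustered on their
   fetal spatiotemporal expression (20 cortical regions x 5 tissue layers
   x 2 timepoints, Z-scored within timepoint) by a k-means sweep over
   k in [2, n_genes/2] with an elbow rule on the within/between
   sum-of-squares ratio; degree-weighted module prototypes rank the
   transcriptome by co-expression and feed preranked GSEA with
   sign-stratified permutation p-values and ratio-of-tails FDR.

# The synthetic world

Restricted inputs (clinical MRI cohorts, biobank genotypes, fetal
microdissection expression) are replaced by seeded generators with known
ground truth. Their defaults are fixed once and document the conditions the
tests probe.

**Cohorts.** Each subject carries a latent "complex folding tendency"
`b = axis * (1 + covariate modulation) + case shift + jitter` per sulcus.
The annotation's axis spans [-1, 1] with half the sulci on each side
(bimodal, homologous left/right pairs sharing positions). AD and DV load
-1 on the complex direction, LB/BS/FD +1, so linear sulci are deep with
variable depth and complex sulci are shallow, branched and fractal —
reproducing the two poles the SPN is built to detect. Both noise channels
(folding jitter shared across the five phenotypes, and per-phenotype
measurement noise) default to SD 0.7 on the axis scale, chosen a priori as
a signal-to-noise ratio typical of sulcal morphometrics: strong enough that
the eigen-fold index reproduces across split halves (r > 0.95 at n = 150),
weak enough that individual coherence scores stay mid-range rather than
saturating at |r| = 1.

Two planting subtleties deserve emphasis, because complexity is a
*relative*, within-subject measure:

* **Moment matching.** A planted effect map is applied after rescaling
  `axis + effect_map` to the axis's mean and SD. Without this, any map
  inflates cases' across-sulcus variance, and within-subject Z-scoring
  reads the inflation as spurious axis contraction.
* **Alignment matching.** A systematic displacement also decorrelates
  cases' patterns from the control-derived template, which again reads as a
  global coherence loss. Cases' random jitter is therefore shrunk so that
  their expected pattern-template correlation matches controls
  (`vj_case = rho^2 (va + vj) - va`). Together these make `effect_map` and
  `contraction` orthogonal planted channels: contraction alone shrinks the
  deterministic axis (`-contraction * axis`), which transmits as the
  simultaneous two-class shift the contraction test targets.

A related estimation-side choice: controls are scored against the
eigen-fold index of the mean SPN *excluding themselves* (leave-one-out,
`loo_controls = TRUE`). Scoring controls against a template they helped
build inflates their coherence relative to cases and mimics contraction;
with leave-one-out scoring the contraction test's type-I error is at the
nominal 5% in simulation.

**Parcellations and maps.** Spin-test substrates place 20 left-hemisphere
centroids uniformly on the unit sphere and mirror them (-x) to the right.
Synthetic "smooth maps" mix a bilaterally shared random linear field, a
hemisphere-specific field (SD 0.4 — real cortical maps are strongly but not
perfectly symmetric) and parcel noise (SD 1.0). At 40 parcels the
centroid-level spin test is only approximately calibrated: the smoother the
map, the more anti-conservative it becomes (rejection ~0.14 for nearly
pure low-frequency fields, ~0.055-0.06 at the default mixture). This is a
known limitation of coarse-parcellation spins, not of the rotation
machinery, whose matrices are exactly orthonormal and Haar-uniform
(verified against the closed-form mean |trace|). Nearest-centroid donor
assignment (duplicates permitted) is the default; an exclusive one-to-one
greedy matching is available but empirically degrades the spun map's
smooth structure more at 20 points per hemisphere.

**Cross-syndrome maps.** Shared-axis collections draw per-syndrome weights
around 0.7 (SD 0.5). The weights must vary: column-centered PCA removes the
column means, so a shared axis with *constant* weight is mathematically
invisible to it. Likewise, a shared component parallel to the axis is, by
the generator's own logic, a contraction — the workflow generator therefore
plants its shared component orthogonal to the axis.

**Genotypes.** Haplotypes threshold a latent Gaussian with exchangeable
within-block correlation (default 0.8, blocks of 10), giving {0,1,2}
dosages with Hardy-Weinberg structure and within-block LD exceeding
between-block LD. Causal SNPs contribute standardized-dosage effects to a
phenotype with unit-variance residual noise. No coalescent realism is
attempted; the structure is exactly what greedy clumping needs to be
tested against.

**Expression.** Three modules of ~13 genes (of 40) peak in the cortical
plate (16 pcw), subventricular zone (21 pcw) and intermediate zone
(16 pcw), the last carrying 85% of its structure as an anterior-posterior
regional gradient. The regional gradient is orthogonal to every layer bump
after centering; this matters because any two Gaussian layer bumps over
only five layers are substantially anti-correlated once profiles are
centered, which would make one module's gene set appear significantly
*depleted* in another module's co-expression ranking. Amplitude 2 against
cell noise 0.5 reflects clearly separable microarray modules. Off-peak
timepoints are attenuated to 30%, though within-timepoint Z-scoring
deliberately removes most amplitude information — as in the real
normalization, which targets *relative* spatial patterns.

# Numerical and inferential choices

* Pearson correlation throughout; SDs use the n-1 denominator.
* Fisher-Z clips |r| at 1 - 1e-12 instead of returning infinity.
* `complexity_scores` excludes the self-correlation (diagonal) entry by
  default: a constant 1 carries no subject information and biases the
  coherence toward the sulcus's own eigen-fold score. A flag restores the
  all-40 variant.
* The eigen-fold sign is fixed by an anchor sulcus that must score
  positive. The package anchors the most *complex* sulcus of the
  annotation, so complexity reads high = complex and the contraction
  directions (linear class up, complex class down) carry their intended
  signs. A reference axis can override the anchor.
* Mixed-model inference uses the Wald z approximation; degrees-of-freedom
  corrections are not attempted and small-sample p-values are
  correspondingly approximate. Singular random-intercept fits fall back to
  variance 0 with a warning; a single observation per subject degenerates
  exactly to OLS.
* All permutation p-values use the add-one estimator
  `(1 + #exceedances) / (1 + n)`, which can never return zero.
* Two-sided spin tests compare absolute correlations; the delta-PCA null
  permutes each syndrome's map across sulci independently (the alternative
  common-shuffle null is not implemented).
* Nyholt's meff rounds half-to-even and is clipped to [1, M]; eigenvalues
  of non-positive-definite correlation matrices are clipped at 0 with a
  warning.
* Outlier exclusion is a single pass on the pre-exclusion mean/SD.
* RINT uses the Blom offset (3/8), average ranks for ties, configurable.
* k-means uses kmeans++-style careful seeding, 50 restarts per k by
  default, deterministic under a seed; empty clusters trigger a re-seeded
  run. The elbow is the maximal discrete second difference of the
  within/between SS ratio, ties toward smaller k, and an exactly linear
  curve returns k_min with a warning.
* GSEA permutes gene labels (preranked setting), uses the
  weighted-KS statistic (weight 1 default), sign-matched permutation
  p-values, NES = ES / mean |same-sign null ES| and sign-stratified
  ratio-of-tails FDR. Module degrees use positively clipped within-module
  co-expression (a flag restores raw correlations).
* Genomic coordinates are 1-based inclusive internally; BED input is
  converted on read. The SNP-to-gene window is inclusive at exactly
  10,000 bp.

# What a green test does and does not establish

The synthetic world has matched covariate distributions between groups,
exactly linear covariate action on the axis, Gaussian noise, and planted
effects that respect the relative nature of complexity. Recovery and
calibration results under this world validate the *machinery* — they do
not certify performance on real cohorts with site confounding, non-Gaussian
artifacts, unmodeled within-subject correlation structure (the random
intercept is a first-order account only), or LD patterns beyond
exchangeable blocks. The spin test's residual anti-conservatism at 40
parcels (about one percentage point at the default smoothness) is inherent
to coarse centroid spins and should be kept in mind when p-values sit near
the threshold.

# Known limitations

* No computation of phenotypes from MRI; inputs begin at the phenotype
  table.
* The association scan is plain OLS — no mixed-model association,
  imputation dosages beyond [0, 2], or X-chromosome dosage compensation
  (X variants are analyzed identically with a warning).
* Gene mapping is positional only; no LD-aware multi-SNP gene statistic.
* Heritability, genetic correlation and over-representation analyses are
  out of scope.
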