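Package: sulcnet
Title: Sulcal Phenotype Networks, Syndromic Effect Maps and Folding Genetics
Version: 0.1.0
Authors@R: person("Sulcnet", "Developers", role = c("aut", "cre"),
    email = "maintainers@sulcnet.dev")
Description: Tools for network-based analysis of cortical sulcal shape.
    Builds per-subject sulcal phenotype networks (SPNs) from five standard
    shape phenotypes, derives the eigen-fold (linear-to-complex) axis and
    per-sulcus complexity scores, estimates standardized case-control effect
    maps with an axis-contraction mixed-model test, provides spin-based
    spatial permutation nulls and permutation-validated PCA of effect maps,
    prepares GWAS phenotypes (outlier filtering, rank-based inverse normal
    transformation, residualisation) with Nyholt effective-test thresholds,
    a minimal additive-allele association scan with greedy LD clumping and
    positional gene mapping, and a fetal-expression module pipeline
    (k-means with elbow selection, degree-weighted prototypes, preranked
    GSEA). Seeded synthetic-data generators with known ground truth stand in
    for restricted imaging and biobank inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
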