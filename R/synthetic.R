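#' @title Synthetic data generators
#' @description Seeded generators for every input the pipeline consumes:
#'   cohort phenotype tables with a planted linear-to-complex axis, group
#'   effect maps and axis contraction; spherical sulcal parcellations;
#'   LD-blocked genotype matrices with planted causal SNPs; and fetal
#'   expression cubes with planted layer/timepoint modules. All generators
#'   return the planted ground truth alongside the data.
#' @name synthetic_data
NULL

#' Cohort specification
#'
#' @param n_cases,n_controls group sizes (each >= 2).
#' @param annotation sulcus annotation (sulcus, class, axis) as from
#'   [default_sulcus_annotation()]; `axis` is the planted linear-to-complex
#'   position in \[-1, 1\] (+1 = complex pole).
#' @param effect_map named per-sulcus planted case-control complexity shift
#'   (standardized units, positive = cases more complex). Default all zero.
#' @param contraction shrinkage factor >= 0: cases receive an additional
#'   complexity shift of `-contraction * axis`, moving linear sulci up and
#'   complex sulci down the axis.
#' @param covariate_effects named coefficients (age, TTV, EN, sex) scaling
#'   how each (standardized) covariate modulates a subject's axis expression.
#' @param noise_sd SD of the latent per-(subject, sulcus) folding jitter and
#'   of per-phenotype measurement noise, on the axis scale (default 0.7).
#' @param jitter_sd,measurement_sd optionally set the two noise channels
#'   separately (folding jitter shared across the five phenotypes vs
#'   independent per-phenotype measurement noise); both default to
#'   `noise_sd`.
#' @param age_range,n_sites covariate distribution settings.
#' @param seed integer RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 100L, n_controls = 100L,
                        annotation = default_sulcus_annotation(),
                        effect_map = NULL, contraction = 0,
                        covariate_effects = c(age = 0.1, TTV = 0.1,
                                              EN = 0.05, sex = 0),
                        noise_sd = 0.7, jitter_sd = NULL,
                        measurement_sd = NULL, age_range = c(10, 30),
                        n_sites = 2L, seed = 1L) {
  if (n_cases < 2 || n_controls < 2) stop("need >= 2 subjects per group")
  if (noise_sd < 0) stop("non-positive noise_sd")
  if (is.null(jitter_sd)) jitter_sd <- noise_sd
  if (is.null(measurement_sd)) measurement_sd <- noise_sd
  sulci <- annotation$sulcus
  if (is.null(effect_map)) {
    effect_map <- stats::setNames(rep(0, length(sulci)), sulci)
  }
  if (length(effect_map) != length(sulci)) {
    stop("effect_map must have one entry per sulcus")
  }
  if (is.null(names(effect_map))) names(effect_map) <- sulci
  if (contraction < 0) stop("contraction must be >= 0")
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    annotation = annotation, effect_map = effect_map,
    contraction = contraction, covariate_effects = covariate_effects,
    noise_sd = noise_sd, jitter_sd = jitter_sd,
    measurement_sd = measurement_sd, age_range = age_range,
    n_sites = as.integer(n_sites), seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Simulate a case-control cohort of sulcal phenotypes
#'
#' Each subject carries a latent per-sulcus "complex folding tendency"
#' `b = axis * (1 + covariate modulation) + case shift + jitter`, where the
#' case shift is `effect_map - contraction * axis`. The five core phenotypes
#' load on `b` with signs reproducing the linear (deep, variable-depth) vs
#' complex (shallow, branched, fractal) poles: average depth and depth
#' variability load negatively on the complex direction; longest branch,
#' branch span and fractal dimension positively. Sulcal thickness (no axis
#' coupling) and a length column (for surface area derivation) are also
#' emitted.
#'
#' @param spec a [cohort_spec()].
#' @return list with `phenotypes` (long data.frame: subject, group, sulcus,
#'   phenotype, value), `covariates` (one row per subject: subject, group,
#'   age, sex, site, TTV, EN) and `truth` (planted quantities).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  ann <- spec$annotation
  sulci <- ann$sulcus
  n_sulci <- length(sulci)
  n <- spec$n_cases + spec$n_controls
  subj <- sprintf("S%04d", seq_len(n))
  group <- rep(c("case", "control"), c(spec$n_cases, spec$n_controls))

  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  sex <- stats::rbinom(n, 1L, 0.5)
  site <- sample(sprintf("site%d", seq_len(spec$n_sites)), n, replace = TRUE)
  ttv <- stats::rnorm(n, 1.2e6, 1e5)
  en <- round(stats::rnorm(n, -80, 30))

  ce <- spec$covariate_effects
  covmod <- ce["age"] * as.numeric(scale(age)) +
    ce["TTV"] * as.numeric(scale(ttv)) +
    ce["EN"] * as.numeric(scale(en)) +
    (if (!is.na(ce["sex"])) ce["sex"] * (sex - 0.5) else 0)
  covmod[!is.finite(covmod)] <- 0

  # complexity is a within-subject relative measure, so the planted map is
  # moment-matched to the axis: without this, any effect map inflates cases'
  # across-sulcus variance and within-subject z-scoring reads the inflation
  # as a spurious axis contraction. Contraction itself is planted afterwards
  # as the deliberate variance shrink -contraction * axis.
  v <- ann$axis + spec$effect_map
  if (stats::sd(v) > 0 && stats::sd(ann$axis) > 0) {
    v <- (v - mean(v)) * stats::sd(ann$axis) / stats::sd(v) + mean(ann$axis)
  }
  e_shift <- v - ann$axis
  case_shift <- e_shift - spec$contraction * ann$axis
  is_case <- as.numeric(group == "case")

  # hold each case's alignment with the normative axis template constant:
  # a systematic displacement e_shift decorrelates cases' patterns from the
  # control-derived eigen-fold template, which downstream reads as a global
  # coherence loss (a spurious contraction). Shrinking cases' random jitter
  # so that corr(pattern, axis) matches controls keeps effect_map and
  # contraction orthogonal planted channels:
  #   vj_case = rho^2 (va + vj) - va,  rho = cor(axis + effect_map, axis)
  va <- stats::var(ann$axis)
  vj <- spec$jitter_sd^2
  rho <- if (stats::sd(v) > 0 && va > 0) stats::cor(v, ann$axis) else 1
  vj_case <- rho^2 * (va + vj) - va
  if (vj_case < -1e-12 && any(is_case == 1)) {
    warning("planted effect map variance exceeds jitter variance; ",
            "case pattern alignment cannot be fully matched", call. = FALSE)
  }
  vj_case <- max(vj_case, 0)
  jitter_by_subject <- ifelse(is_case == 1, sqrt(vj_case), spec$jitter_sd)

  # latent complex-direction tendency, subjects x sulci
  b <- outer(1 + covmod, ann$axis) +
    outer(is_case, case_shift) +
    matrix(stats::rnorm(n * n_sulci), n, n_sulci) * jitter_by_subject

  loadings <- c(average_depth = -1, depth_variability = -1,
                longest_branch = 1, branch_span = 1, fractal_dimension = 1)
  mu <- c(average_depth = 12, depth_variability = 2, longest_branch = 40,
          branch_span = 15, fractal_dimension = 1.2)
  sigma <- c(average_depth = 2, depth_variability = 0.5, longest_branch = 8,
             branch_span = 4, fractal_dimension = 0.08)

  rows <- vector("list", length(loadings) + 2L)
  k <- 1L
  for (p in names(loadings)) {
    val <- mu[p] + sigma[p] *
      (loadings[p] * b +
         matrix(stats::rnorm(n * n_sulci, 0, spec$measurement_sd),
                n, n_sulci))
    rows[[k]] <- data.frame(
      subject = rep(subj, times = n_sulci),
      sulcus = rep(sulci, each = n),
      phenotype = p, value = as.vector(val), stringsAsFactors = FALSE)
    k <- k + 1L
  }
  # thickness: deliberately uncoupled from the axis
  thick <- 2.5 + matrix(stats::rnorm(n * n_sulci, 0, 0.3), n, n_sulci)
  rows[[k]] <- data.frame(subject = rep(subj, times = n_sulci),
                          sulcus = rep(sulci, each = n),
                          phenotype = "thickness",
                          value = as.vector(thick), stringsAsFactors = FALSE)
  k <- k + 1L
  # per-sulcus characteristic length + subject noise (for surface area)
  base_len <- stats::runif(n_sulci, 30, 80)
  len <- matrix(rep(base_len, each = n), n, n_sulci) +
    matrix(stats::rnorm(n * n_sulci, 0, 2), n, n_sulci)
  rows[[k]] <- data.frame(subject = rep(subj, times = n_sulci),
                          sulcus = rep(sulci, each = n),
                          phenotype = "length",
                          value = as.vector(len), stringsAsFactors = FALSE)

  phen <- do.call(rbind, rows)
  covs <- data.frame(subject = subj, group = group, age = age, sex = sex,
                     site = site, TTV = ttv, EN = en,
                     stringsAsFactors = FALSE)
  list(
    phenotypes = phen,
    covariates = covs,
    truth = list(axis = stats::setNames(ann$axis, sulci),
                 effect_map = spec$effect_map,
                 contraction = spec$contraction,
                 case_shift = stats::setNames(case_shift, sulci),
                 class = stats::setNames(ann$class, sulci),
                 covariate_effects = spec$covariate_effects,
                 noise_sd = spec$noise_sd, seed = spec$seed)
  )
}

#' Extract one subject's sulci x phenotypes matrix from a long table
#'
#' @param phenotypes long phenotype table.
#' @param subject subject id.
#' @param phenotypes_used phenotype names (default the five core phenotypes).
#' @param sulci sulcus ordering (default canonical order restricted to table).
#' @return numeric matrix, sulci x phenotypes.
#' @export
subject_matrix <- function(phenotypes, subject,
                           phenotypes_used = core_phenotypes(),
                           sulci = NULL) {
  d <- phenotypes[phenotypes$subject == subject &
                    phenotypes$phenotype %in% phenotypes_used, , drop = FALSE]
  if (is.null(sulci)) sulci <- unique(phenotypes$sulcus)
  m <- matrix(NA_real_, length(sulci), length(phenotypes_used),
              dimnames = list(sulci, phenotypes_used))
  idx <- cbind(match(d$sulcus, sulci), match(d$phenotype, phenotypes_used))
  m[idx] <- d$value
  if (anyNA(m)) {
    stop("subject ", subject, " is missing phenotype values", call. = FALSE)
  }
  m
}

#' Build one SPN per subject from a long phenotype table
#'
#' @inheritParams subject_matrix
#' @param subjects subject ids (default all).
#' @return named list of SPN matrices.
#' @export
cohort_spns <- function(phenotypes, subjects = NULL,
                        phenotypes_used = core_phenotypes(), sulci = NULL) {
  if (is.null(subjects)) subjects <- unique(phenotypes$subject)
  if (is.null(sulci)) sulci <- unique(phenotypes$sulcus)
  out <- lapply(subjects, function(s) {
    build_spn(zscore_within_subject(
      subject_matrix(phenotypes, s, phenotypes_used, sulci), s))
  })
  names(out) <- subjects
  out
}

#' Simulate a spherical sulcal parcellation
#'
#' Left-hemisphere parcel centroids are drawn uniformly on the unit sphere;
#' right-hemisphere centroids are their x-mirrors, emulating a bilaterally
#' symmetric parcellation with borders about gyral peaks.
#'
#' @param n_sulci total parcel count (even unless `unilateral`).
#' @param seed RNG seed.
#' @param unilateral if TRUE all parcels go to one hemisphere.
#' @return data.frame (sulcus, hemisphere, x, y, z) with unit-norm centroids.
#' @export
simulate_parcellation <- function(n_sulci = 40L, seed = 1L,
                                  unilateral = FALSE) {
  if (n_sulci < 3) stop("n_sulci must be >= 3")
  if (!unilateral && n_sulci %% 2L != 0L) {
    stop("n_sulci must be even for a paired left/right parcellation")
  }
  set.seed(seed)
  n_left <- if (unilateral) n_sulci else n_sulci %/% 2L
  pts <- matrix(stats::rnorm(3L * n_left), n_left, 3L)
  pts <- pts / sqrt(rowSums(pts^2))
  sulci <- canonical_sulci(n_left)
  if (unilateral) {
    data.frame(sulcus = sulci[seq_len(n_left)], hemisphere = "L",
               x = pts[, 1], y = pts[, 2], z = pts[, 3],
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      sulcus = sulci,
      hemisphere = rep(c("L", "R"), each = n_left),
      x = c(pts[, 1], -pts[, 1]),
      y = c(pts[, 2], pts[, 2]),
      z = c(pts[, 3], pts[, 3]),
      stringsAsFactors = FALSE)
  }
}

#' Genotype specification
#'
#' @param n_subjects,n_snps dimensions.
#' @param maf_range minor-allele-frequency interval within (0, 0.5].
#' @param block_size SNPs per LD block.
#' @param within_block_r latent exchangeable correlation within a block,
#'   in \[0, 1).
#' @param causal data.frame with columns `snp` (index) and `effect`
#'   (per-allele effect), or NULL.
#' @param seed RNG seed.
#' @return list of class `genotype_spec`.
#' @export
genotype_spec <- function(n_subjects = 1000L, n_snps = 100L,
                          maf_range = c(0.05, 0.5), block_size = 10L,
                          within_block_r = 0.8, causal = NULL, seed = 1L) {
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must lie in (0, 0.5]")
  }
  if (within_block_r < 0 || within_block_r >= 1) {
    stop("within_block_r must be in [0, 1)")
  }
  if (!is.null(causal)) {
    stopifnot(all(causal$snp >= 1), all(causal$snp <= n_snps))
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_snps = as.integer(n_snps),
    maf_range = maf_range, block_size = as.integer(block_size),
    within_block_r = within_block_r, causal = causal, seed = as.integer(seed)
  ), class = "genotype_spec")
}

#' Simulate LD-blocked genotype dosages with planted causal SNPs
#'
#' Haplotypes are generated by thresholding a latent Gaussian with
#' exchangeable within-block correlation; dosage = sum of two haplotypes,
#' giving values in \{0, 1, 2\} with approximate Hardy-Weinberg structure and
#' within-block linkage disequilibrium exceeding between-block LD.
#'
#' @param spec a [genotype_spec()].
#' @return list with `dosages` (subjects x SNPs matrix), `variants`
#'   (data.frame: id, chr, pos, ref, alt, maf, block), `phenotype`
#'   (genetic value + N(0,1) noise), `genetic_value`, and `truth`.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "genotype_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects; m <- spec$n_snps
  block <- ((seq_len(m) - 1L) %/% spec$block_size) + 1L
  maf <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
  thr <- stats::qnorm(maf)
  r <- spec$within_block_r
  dos <- matrix(0L, n, m)
  for (h in 1:2) {
    z <- matrix(stats::rnorm(n * m), n, m)
    for (bk in unique(block)) {
      idx <- which(block == bk)
      shared <- stats::rnorm(n)
      z[, idx] <- sqrt(r) * shared + sqrt(1 - r) * z[, idx]
    }
    dos <- dos + (sweep(z, 2, thr, `<`)) * 1L
  }
  storage.mode(dos) <- "integer"
  ids <- sprintf("snp_%05d", seq_len(m))
  colnames(dos) <- ids
  rownames(dos) <- sprintf("S%05d", seq_len(n))
  variants <- data.frame(
    id = ids, chr = 1L, pos = seq_len(m) * 10000L,
    ref = "A", alt = "G", maf = maf, block = block,
    stringsAsFactors = FALSE)
  gv <- rep(0, n)
  if (!is.null(spec$causal) && nrow(spec$causal)) {
    for (i in seq_len(nrow(spec$causal))) {
      j <- spec$causal$snp[i]
      g <- dos[, j]
      s <- stats::sd(g)
      if (s > 0) gv <- gv + spec$causal$effect[i] * (g - mean(g)) / s
    }
  }
  phen <- gv + stats::rnorm(n)
  list(dosages = dos, variants = variants, genetic_value = gv,
       phenotype = phen,
       truth = list(causal = spec$causal, maf = maf, block = block,
                    seed = spec$seed))
}

#' Expression specification
#'
#' @param n_genes number of genes.
#' @param regions,layers,timepoints labels; defaults follow a fetal cortical
#'   sampling scheme of 20 regions x 5 tissue layers x 2 timepoints.
#' @param modules data.frame with columns `n_genes`, `peak_layer`,
#'   `peak_timepoint`, `amplitude` and optionally `region_gradient` (fraction
#'   in \[0, 1\] of the module's structure carried by an anterior-posterior
#'   regional gradient rather than the layer bump; regional gradients are
#'   orthogonal to layer bumps, giving near-null cross-module co-expression).
#'   Gene counts must sum to <= n_genes.
#' @param noise_sd per-cell expression noise SD.
#' @param gene_sets data.frame with columns `name`, `module` (index into
#'   `modules`), `overlap` (fraction of the set drawn from that module's
#'   genes) and `size`; or NULL.
#' @param seed RNG seed.
#' @return list of class `expression_spec`.
#' @export
expression_spec <- function(n_genes = 40L,
                            regions = sprintf("region_%02d", 1:20),
                            layers = c("cortical_plate", "subplate",
                                       "intermediate_zone",
                                       "subventricular_zone",
                                       "ventricular_zone"),
                            timepoints = c("16pcw", "21pcw"),
                            modules = data.frame(
                              n_genes = c(13L, 13L, 14L),
                              peak_layer = c("cortical_plate",
                                             "subventricular_zone",
                                             "intermediate_zone"),
                              peak_timepoint = c("16pcw", "21pcw", "16pcw"),
                              amplitude = 2,
                              region_gradient = c(0, 0, 0.85)),
                            noise_sd = 0.5, gene_sets = NULL, seed = 1L) {
  if (!is.null(modules) && sum(modules$n_genes) > n_genes) {
    stop("module gene counts exceed n_genes")
  }
  if (!is.null(gene_sets) && any(gene_sets$overlap < 0 | gene_sets$overlap > 1)) {
    stop("overlap fraction outside [0,1]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(
    n_genes = as.integer(n_genes), regions = regions, layers = layers,
    timepoints = timepoints, modules = modules, noise_sd = noise_sd,
    gene_sets = gene_sets, seed = as.integer(seed)
  ), class = "expression_spec")
}

#' Simulate a fetal expression cube with planted spatiotemporal modules
#'
#' Module genes express as a Gaussian bump over tissue layers centered on the
#' module's peak layer, strongest at the peak timepoint (attenuated to 30%
#' at the other), uniform over regions; background genes are pure noise.
#'
#' @param spec an [expression_spec()].
#' @return list with `cube` (long data.frame: gene, region, layer, timepoint,
#'   value), `truth` (per-gene module labels, `"background"` for fillers)
#'   and `gene_sets` (named list of gene ids, or NULL).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_spec"))
  set.seed(spec$seed)
  genes <- sprintf("gene_%04d", seq_len(spec$n_genes))
  lab <- rep("background", spec$n_genes)
  if (!is.null(spec$modules) && nrow(spec$modules)) {
    at <- 1L
    for (i in seq_len(nrow(spec$modules))) {
      k <- spec$modules$n_genes[i]
      lab[at:(at + k - 1L)] <- sprintf("module_%d", i)
      at <- at + k
    }
  }
  grid <- expand.grid(region = spec$regions, layer = spec$layers,
                      timepoint = spec$timepoints,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  layer_idx <- match(grid$layer, spec$layers)
  region_idx <- match(grid$region, spec$regions)
  # anterior-posterior gradient, centered and unit-scaled across regions
  grad <- as.numeric(scale(region_idx))
  n_cells <- nrow(grid)
  out <- vector("list", spec$n_genes)
  for (g in seq_len(spec$n_genes)) {
    base <- rep(0, n_cells)
    if (lab[g] != "background") {
      i <- as.integer(sub("module_", "", lab[g]))
      peak <- match(spec$modules$peak_layer[i], spec$layers)
      amp <- spec$modules$amplitude[i]
      rg <- if ("region_gradient" %in% names(spec$modules)) {
        spec$modules$region_gradient[i]
      } else 0
      tw <- ifelse(grid$timepoint == spec$modules$peak_timepoint[i], 1, 0.3)
      shape <- (1 - rg) * exp(-((layer_idx - peak)^2) / 2) + rg * grad
      base <- amp * tw * shape
    }
    out[[g]] <- data.frame(
      gene = genes[g], region = grid$region, layer = grid$layer,
      timepoint = grid$timepoint,
      value = base + stats::rnorm(n_cells, 0, spec$noise_sd),
      stringsAsFactors = FALSE)
  }
  cube <- do.call(rbind, out)
  sets <- NULL
  if (!is.null(spec$gene_sets) && nrow(spec$gene_sets)) {
    sets <- list()
    for (i in seq_len(nrow(spec$gene_sets))) {
      gs <- spec$gene_sets[i, ]
      mod_genes <- genes[lab == sprintf("module_%d", gs$module)]
      other <- setdiff(genes, mod_genes)
      n_in <- round(gs$overlap * gs$size)
      n_in <- min(n_in, length(mod_genes))
      picked <- c(sample(mod_genes, n_in),
                  sample(other, min(gs$size - n_in, length(other))))
      sets[[gs$name]] <- picked
    }
  }
  list(cube = cube, truth = stats::setNames(lab, genes), gene_sets = sets)
}

#' Simulate effect-map collections sharing a planted spatial axis
#'
#' Each of `n_maps` syndromic maps is `w_i * shared + noise`, with the
#' shared axis a smooth map on the parcellation and per-map weights drawn
#' around `weight`. Weights must vary across maps for the shared axis to be
#' identifiable by column-centered PCA (a constant weight is removed with
#' the column means).
#'
#' @param parcellation from [simulate_parcellation()].
#' @param n_maps number of maps (default 9 syndromes).
#' @param weight mean shared-axis weight (default 0.7).
#' @param weight_sd SD of per-map weights (default 0.5).
#' @param noise_sd per-parcel noise SD (default 0.3).
#' @param seed RNG seed.
#' @return list: `maps` (n_maps x sulci matrix), `shared` (the planted
#'   axis), `weights`.
#' @export
simulate_shared_axis_maps <- function(parcellation, n_maps = 9L,
                                      weight = 0.7, weight_sd = 0.5,
                                      noise_sd = 0.3, seed = 1L) {
  shared <- simulate_smooth_maps(parcellation, 1L, seed = seed)[, 1]
  set.seed(seed + 1L)
  w <- stats::rnorm(n_maps, weight, weight_sd)
  maps <- t(sapply(seq_len(n_maps), function(i) {
    w[i] * shared + stats::rnorm(length(shared), 0, noise_sd)
  }))
  rownames(maps) <- sprintf("syndrome_%d", seq_len(n_maps))
  colnames(maps) <- parcellation$sulcus
  list(maps = maps, shared = shared, weights = w)
}

#' Simulate spatially smooth sulcus maps on a parcellation
#'
#' Each map mixes a bilaterally shared random linear field over the centroid
#' coordinates with hemisphere-specific fields (real cortical maps are
#' strongly but not perfectly symmetric) plus independent parcel noise.
#' Maps are mutually independent. Used for spin-test calibration and as
#' building blocks for shared-axis collections.
#'
#' @param parcellation from [simulate_parcellation()].
#' @param n_maps number of maps.
#' @param noise_sd SD of the white-noise component (default 1).
#' @param hemi_sd SD of the hemisphere-specific field component
#'   (default 0.4).
#' @param seed RNG seed.
#' @return matrix, sulci x maps, rownames = sulcus labels.
#' @export
simulate_smooth_maps <- function(parcellation, n_maps = 2L, noise_sd = 1,
                                 hemi_sd = 0.4, seed = 1L) {
  # force the argument before seeding: a lazily evaluated parcellation
  # expression may consume (or reset) the RNG
  xyz <- as.matrix(parcellation[, c("x", "y", "z")])
  hemi <- parcellation$hemisphere
  set.seed(seed)
  runit <- function() {
    u <- stats::rnorm(3)
    u / sqrt(sum(u^2))
  }
  out <- sapply(seq_len(n_maps), function(i) {
    shared <- as.vector(xyz %*% runit())
    v <- shared
    for (h in unique(hemi)) {
      idx <- hemi == h
      v[idx] <- v[idx] + hemi_sd *
        as.vector(xyz[idx, , drop = FALSE] %*% runit())
    }
    v + stats::rnorm(nrow(xyz), 0, noise_sd)
  })
  rownames(out) <- parcellation$sulcus
  colnames(out) <- sprintf("map_%02d", seq_len(n_maps))
  out
}
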