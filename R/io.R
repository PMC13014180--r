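#' @title Readers, writers, configuration and workflows
#' @description TSV/GMT/BED readers and writers for the pipeline's tables,
#'   a validated run configuration, and the three end-to-end workflows
#'   (cohort, gwas, modules) with provenance logging and deterministic
#'   replay.
#' @name workflow_io
NULL

.pheno_header <- c("subject", "sulcus", "phenotype", "value")

#' Write / read a long-format phenotype table (TSV)
#'
#' @param x data.frame with columns subject, sulcus, phenotype, value (extra
#'   columns preserved).
#' @param path file path.
#' @param header_comment optional `# key: value` provenance lines.
#' @return `read_phenotype_table` returns the validated data.frame.
#' @export
write_phenotype_table <- function(x, path, header_comment = NULL) {
  stopifnot(all(.pheno_header %in% names(x)))
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_comment) writeLines(paste0("# ", h), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_table
#' @export
read_phenotype_table <- function(path) {
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(.pheno_header, names(x))
  if (length(missing)) {
    stop("phenotype table missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  key <- paste(x$subject, x$sulcus, x$phenotype)
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (subject, sulcus, phenotype) rows at lines ",
         paste(utils::head(which(dup) + 1L, 5), collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(x$value)) stop("value column is not numeric", call. = FALSE)
  # every (subject, phenotype) must cover the same sulcus set
  tab <- table(x$subject, x$phenotype)
  if (length(unique(as.vector(tab))) > 1) {
    bad <- which(tab != max(tab), arr.ind = TRUE)[1, ]
    stop("incomplete sulcus coverage: subject ", rownames(tab)[bad[1]],
         ", phenotype ", colnames(tab)[bad[2]], call. = FALSE)
  }
  x
}

#' Write / read a square labeled matrix (SPN, similarity) as TSV
#'
#' @param m matrix with dimnames.
#' @param path file path.
#' @param header_comment provenance lines.
#' @export
write_matrix_tsv <- function(m, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_comment) writeLines(paste0("# ", h), con)
  utils::write.table(data.frame(sulcus = rownames(m), m,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  x <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  m
}

#' Write / read a two-column sulcus map TSV
#'
#' @param map named numeric vector.
#' @param path file path.
#' @param header_comment provenance lines.
#' @export
write_sulcus_map <- function(map, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_comment) writeLines(paste0("# ", h), con)
  utils::write.table(data.frame(sulcus = names(map), value = unname(map)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sulcus_map
#' @export
read_sulcus_map <- function(path) {
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(x$value, x$sulcus)
}

#' Read / write gene sets in GMT format
#'
#' Tab-separated: set name, description, then member genes, one set per line.
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  out
}

#' Read dosages from a biallelic VCF (GT field only)
#'
#' Minimal text-VCF reader: biallelic records only, dosage = count of ALT
#' alleles in the GT field (`.` yields NA). Multiallelic records are
#' dropped with a warning.
#'
#' @param path uncompressed VCF file.
#' @return list: `dosages` (subjects x variants matrix), `variants`
#'   (data.frame: id, chr, pos, ref, alt).
#' @export
read_vcf_dosages <- function(path) {
  lines <- readLines(path)
  header <- grep("^#CHROM", lines, value = TRUE)
  if (!length(header)) stop("missing #CHROM header line", call. = FALSE)
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  subjects <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  rows <- strsplit(body, "\t", fixed = TRUE)
  multi <- vapply(rows, function(r) grepl(",", r[5], fixed = TRUE),
                  logical(1))
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) dropped", call. = FALSE)
    rows <- rows[!multi]
  }
  variants <- data.frame(
    id = vapply(rows, `[`, "", 3), chr = vapply(rows, `[`, "", 1),
    pos = as.integer(vapply(rows, `[`, "", 2)),
    ref = vapply(rows, `[`, "", 4), alt = vapply(rows, `[`, "", 5),
    stringsAsFactors = FALSE)
  gt_to_dosage <- function(gt) {
    gt <- sub(":.*", "", gt)
    if (grepl("\\.", gt)) return(NA_integer_)
    sum(as.integer(strsplit(gt, "[/|]")[[1]]))
  }
  dos <- vapply(rows, function(r) {
    vapply(r[-(1:9)], gt_to_dosage, integer(1), USE.NAMES = FALSE)
  }, integer(length(subjects)))
  dos <- matrix(dos, nrow = length(subjects),
                dimnames = list(subjects, variants$id))
  list(dosages = dos, variants = variants)
}

#' Read gene intervals from BED or native 1-based TSV
#'
#' BED input (0-based half-open) is converted to 1-based inclusive
#' coordinates on read; the native TSV (columns gene, chr, start, end) is
#' taken as already 1-based inclusive.
#'
#' @param path file path.
#' @param format `"bed"` or `"tsv"`.
#' @return data.frame: gene, chr, start, end (1-based inclusive).
#' @export
read_gene_intervals <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (format == "bed") {
    x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    data.frame(gene = x[[4]], chr = x[[1]], start = x[[2]] + 1L,
               end = x[[3]], stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
}

#' Derive sulcal surface area as mean depth x length
#'
#' Adds a `surface_area` phenotype (mm^2) to a long table that carries
#' `average_depth` and `length` rows per (subject, sulcus).
#'
#' @param phenotypes long phenotype table.
#' @return the table with appended surface_area rows.
#' @export
derive_surface_area <- function(phenotypes) {
  d <- phenotypes[phenotypes$phenotype == "average_depth", , drop = FALSE]
  l <- phenotypes[phenotypes$phenotype == "length", , drop = FALSE]
  if (!nrow(d) || !nrow(l)) {
    stop("average_depth and length columns required", call. = FALSE)
  }
  if (any(d$value < 0) || any(l$value < 0)) {
    stop("negative depth or length", call. = FALSE)
  }
  key_d <- paste(d$subject, d$sulcus)
  key_l <- paste(l$subject, l$sulcus)
  m <- match(key_d, key_l)
  if (anyNA(m)) stop("depth/length rows not aligned", call. = FALSE)
  sa <- d
  sa$phenotype <- "surface_area"
  sa$value <- d$value * l$value[m]
  rbind(phenotypes, sa)
}

.default_config <- function() {
  list(
    n_spins = 10000L, n_perm = 1000L, outlier_sd = 5, rint_offset = 3 / 8,
    include_diagonal = FALSE, clump_r2 = 0.1, gene_window = 10000L,
    base_snp = 5e-8, base_gene_alpha = 0.05, alpha = 0.05, seed = 1L
  )
}

#' Load and validate a run configuration (JSON)
#'
#' Defaults follow the reference analysis settings (10,000 spins, r^2 < 0.1
#' clumping, 10 kb gene window, +/- 5 SD outlier exclusion, 5e-8 base SNP
#' threshold). Unknown keys are errors.
#'
#' @param path JSON file, or NULL for pure defaults.
#' @param overrides named list applied on top of the file.
#' @return validated named list of class `run_config`.
#' @export
run_config <- function(path = NULL, overrides = NULL) {
  cfg <- .default_config()
  user <- list()
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(overrides)) user[names(overrides)] <- overrides
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(user)] <- user
  stopifnot(cfg$n_spins >= 100, cfg$n_perm >= 100, cfg$outlier_sd > 0,
            cfg$clump_r2 > 0, cfg$clump_r2 <= 1, cfg$gene_window >= 0,
            cfg$base_snp > 0, cfg$alpha > 0, cfg$alpha < 1)
  structure(cfg, class = "run_config")
}

.config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","),
                                character(1)),
             sep = "=", collapse = ";")
  # tiny polynomial rolling hash (double-safe), enough for a provenance tag
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.provenance <- function(cfg, stage) {
  c(sprintf("run_id: %s-%s", stage, .config_hash(cfg)),
    sprintf("config_hash: %s", .config_hash(cfg)),
    sprintf("seed: %d", cfg$seed),
    sprintf("package: sulcnet %s",
            as.character(utils::packageVersion("sulcnet"))))
}

#' Run an end-to-end workflow on synthetic inputs
#'
#' `"cohort"`: simulates 9 syndromic cohorts, computes complexity effect
#' maps, the cross-syndrome similarity matrix and the permutation-validated
#' PCA. `"gwas"`: simulates genotypes with a planted causal SNP, prepares
#' the phenotype, runs the association scan, clumping and gene mapping.
#' `"modules"`: simulates a 3-module expression cube and runs clustering,
#' prototypes, ranking and GSEA. All outputs are written under `out_dir`
#' with provenance headers; identical config + seed reproduces outputs
#' byte-identically.
#'
#' @param config a [run_config()].
#' @param workflow one of `"cohort"`, `"gwas"`, `"modules"`.
#' @param out_dir output directory (created).
#' @param scale integer >= 1 shrinking simulated sizes for smoke runs
#'   (default 1 = reference sizes).
#' @return invisible list of in-memory results.
#' @export
run_workflow <- function(config, workflow = c("cohort", "gwas", "modules"),
                         out_dir, scale = 1) {
  workflow <- match.arg(workflow)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- .provenance(config, workflow)
  log <- c(prov, sprintf("stage_order: %s", workflow))
  res <- switch(workflow,
    cohort = .wf_cohort(config, out_dir, prov, scale),
    gwas = .wf_gwas(config, out_dir, prov, scale),
    modules = .wf_modules(config, out_dir, prov, scale))
  writeLines(c(log, res$log), file.path(out_dir, "run.log"))
  invisible(res)
}


# write a TSV with provenance comment lines
.write_tsv_prov <- function(x, path, prov) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in prov) writeLines(paste0("# ", h), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.wf_cohort <- function(cfg, out_dir, prov, scale) {
  n_grp <- max(20L, as.integer(100 / scale))
  syndromes <- sprintf("syndrome_%d", 1:9)
  ann <- default_sulcus_annotation()
  # shared off-axis spatial component with syndrome-varying weight; a shared
  # component parallel to the axis would be a contraction, which is planted
  # through the contraction parameter instead
  set.seed(cfg$seed)
  shared <- stats::rnorm(nrow(ann), 0, 0.5)
  shared <- stats::residuals(stats::lm(shared ~ ann$axis))
  maps <- list()
  planted <- list()
  log <- c()
  for (i in seq_along(syndromes)) {
    seed_i <- cfg$seed * 1000L + i
    set.seed(seed_i)
    w <- stats::rnorm(1, 0.7, 0.3)
    emap <- stats::setNames(w * shared + stats::rnorm(nrow(ann), 0, 0.25),
                            ann$sulcus)
    planted[[syndromes[i]]] <- emap
    spec <- cohort_spec(n_cases = n_grp, n_controls = n_grp,
                        effect_map = emap, seed = seed_i)
    sim <- simulate_cohort(spec)
    cc <- cohort_complexity(sim)
    vl <- data.frame(subject = cc$scores$subject, sulcus = cc$scores$sulcus,
                     value = cc$scores$fisher_z)
    em <- effect_map(vl, sim$covariates, cohort = syndromes[i])
    maps[[syndromes[i]]] <- stats::setNames(em$beta1, em$sulcus)
    .write_tsv_prov(em, file.path(out_dir,
                                  paste0(syndromes[i], "_effects.tsv")),
                    prov)
    log <- c(log, sprintf("stage: effect_map %s seed=%d n=%d/group",
                          syndromes[i], seed_i, n_grp))
  }
  css <- cross_syndrome_similarity(maps, n_perm = cfg$n_perm,
                                   seed = cfg$seed)
  write_matrix_tsv(css$similarity, file.path(out_dir, "similarity.tsv"),
                   prov)
  .write_tsv_prov(
    data.frame(component = seq_along(css$pca$explained),
               explained = css$pca$explained, p_perm = css$pca$p_perm),
    file.path(out_dir, "delta_pca.tsv"), prov)
  list(maps = maps, similarity = css, truth = planted, log = log)
}

.wf_gwas <- function(cfg, out_dir, prov, scale) {
  n_subj <- max(200L, as.integer(2000 / scale))
  spec <- genotype_spec(n_subjects = n_subj, n_snps = 50L, block_size = 5L,
                        causal = data.frame(snp = 12L, effect = 0.3),
                        seed = cfg$seed)
  sim <- simulate_genotypes(spec)
  set.seed(cfg$seed + 1L)
  covs <- data.frame(subject = rownames(sim$dosages),
                     age = stats::runif(n_subj, 45, 80),
                     sex = stats::rbinom(n_subj, 1, 0.5),
                     site = "site1",
                     EN = round(stats::rnorm(n_subj, -80, 30)))
  prep <- prepare_phenotype(fisher_z(tanh(sim$phenotype / 3)), covs,
                            outlier_sd = cfg$outlier_sd,
                            offset = cfg$rint_offset)
  assoc <- assoc_scan(sim$dosages, prep$value, variants = sim$variants)
  leads <- clump_leads(assoc, sim$dosages, p_threshold = 1e-4,
                       r2_threshold = cfg$clump_r2)
  genes <- data.frame(gene = sprintf("GENE%d", 1:5), chr = 1L,
                      start = c(100000L, 150000L, 240000L, 300000L, 420000L),
                      end = c(120000L, 170000L, 260000L, 320000L, 440000L))
  hits <- map_snps_to_genes(assoc[assoc$id %in% leads, ], genes,
                            window = cfg$gene_window)
  .write_tsv_prov(assoc, file.path(out_dir, "assoc.tsv"), prov)
  writeLines(c(prov, leads), file.path(out_dir, "leads.txt"))
  .write_tsv_prov(hits, file.path(out_dir, "gene_hits.tsv"), prov)
  list(assoc = assoc, leads = leads, hits = hits,
       log = sprintf("stage: gwas seed=%d n=%d", cfg$seed, n_subj))
}

.wf_modules <- function(cfg, out_dir, prov, scale) {
  spec <- expression_spec(
    gene_sets = data.frame(name = c("set_module1", "set_random"),
                           module = c(1L, 2L), overlap = c(0.8, 0),
                           size = 10L),
    seed = cfg$seed)
  sim <- simulate_expression(spec)
  norm <- zscore_by_timepoint(sim$cube)
  prof <- flatten_profiles(norm)
  sweep <- kmeans_sweep(prof, k_max = min(10L, nrow(prof) %/% 2L),
                        seed = cfg$seed)
  k <- elbow_select(sweep)
  assign <- sweep$assignments[[match(k, sweep$k)]]
  proto <- module_prototypes(prof, assign)
  ranking <- coexpression_ranking(proto$prototypes[1, ], prof)
  gsea <- gsea_preranked(ranking, sim$gene_sets, n_perm = cfg$n_perm,
                         seed = cfg$seed)
  .write_tsv_prov(gsea, file.path(out_dir, "gsea.tsv"), prov)
  .write_tsv_prov(
    data.frame(gene = names(assign), module = assign,
               truth = sim$truth[names(assign)]),
    file.path(out_dir, "modules.tsv"), prov)
  list(k = k, assignments = assign, gsea = gsea,
       log = sprintf("stage: modules seed=%d k=%d", cfg$seed, k))
}
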