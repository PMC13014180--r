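#' @title GWAS phenotype preparation, thresholds, association and clumping
#' @description The common-variant arm: phenotype preparation (outlier
#'   exclusion at mean +/- 5 SD, rank-based inverse normal transformation,
#'   covariate residualization), Nyholt effective-test arithmetic with the
#'   derived significance thresholds, a minimal additive-allele OLS
#'   association scan with ancestry-PC covariates, greedy LD clumping at
#'   r^2 < 0.1, and positional SNP-to-gene mapping with a 10 kb window.
#' @name gwas_phenotypes
NULL

#' Rank-based inverse normal transformation
#'
#' Blom variant by default: `qnorm((rank - c) / (n + 1 - 2c))` with
#' `c = 3/8`, average ranks for ties.
#'
#' @param x numeric vector.
#' @param offset Blom constant c (default 3/8).
#' @return transformed vector.
#' @export
rint <- function(x, offset = 3 / 8) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  stats::qnorm((rank(x, ties.method = "average") - offset) /
                 (n - 2 * offset + 1))
}

#' Prepare one sulcus' complexity phenotype for association testing
#'
#' Steps, in order: (1) values are expected already Fisher-Z transformed
#' (set `fisher_z_input = FALSE` to apply the transform here); (2) single-pass
#' outlier exclusion at mean +/- `outlier_sd` SD, mean/SD computed on the
#' pre-exclusion sample; (3) rank-based inverse normal transformation of the
#' retained values; (4) OLS residualization on age, age^2, sex, age x sex,
#' age^2 x sex, site and Euler number.
#'
#' @param values per-subject Fisher-Z complexity values.
#' @param covariates data.frame with columns subject, age, sex, site, EN,
#'   rows aligned with `values`.
#' @param outlier_sd exclusion threshold in SD units (default 5).
#' @param offset RINT offset (default 3/8).
#' @param fisher_z_input declare whether values are already Fisher-Z; if
#'   FALSE, [fisher_z()] is applied first.
#' @param min_n minimum retained sample size (default 30).
#' @return data.frame: subject, value (residualized normal score, NA for
#'   excluded), excluded flag, reason.
#' @export
prepare_phenotype <- function(values, covariates, outlier_sd = 5,
                              offset = 3 / 8, fisher_z_input = TRUE,
                              min_n = 30L) {
  stopifnot(length(values) == nrow(covariates))
  if (!fisher_z_input) values <- fisher_z(values)
  mu <- mean(values)
  s <- .sd_checked(values, "phenotype")
  excluded <- abs(values - mu) > outlier_sd * s
  keep <- which(!excluded)
  if (length(keep) < min_n) {
    stop("fewer than ", min_n, " subjects after outlier exclusion",
         call. = FALSE)
  }
  y <- rint(values[keep], offset)
  cv <- covariates[keep, , drop = FALSE]
  age <- as.numeric(cv$age)
  sex <- as.numeric(cv$sex)
  df <- data.frame(.y = y, age = age, age2 = age^2, sex = sex,
                   age_sex = age * sex, age2_sex = age^2 * sex,
                   EN = as.numeric(cv$EN))
  if (length(unique(cv$site)) > 1) df$site <- factor(cv$site)
  fit <- stats::lm(.y ~ ., data = df)
  if (anyNA(stats::coef(fit))) stop("rank-deficient covariates", call. = FALSE)
  out <- data.frame(subject = covariates$subject, value = NA_real_,
                    excluded = excluded,
                    reason = ifelse(excluded, "outlier_5sd", ""),
                    stringsAsFactors = FALSE)
  out$value[keep] <- stats::residuals(fit)
  out
}

#' Nyholt effective number of independent tests
#'
#' `meff_raw = 1 + (M - 1) * (1 - Var(lambda) / M)` where lambda are the
#' eigenvalues of the phenotype correlation matrix and Var uses the sample
#' (M - 1) denominator; `meff` rounds half-to-even and is bounded to
#' \[1, M\].
#'
#' @param x either a subjects x phenotypes matrix of prepared phenotypes, or
#'   a phenotype correlation matrix (square, unit diagonal).
#' @return list of class `meff_result`: M, eigenvalues, meff_raw, meff.
#' @export
nyholt_meff <- function(x) {
  stopifnot(is.matrix(x))
  is_cor <- nrow(x) == ncol(x) && max(abs(diag(x) - 1)) < 1e-8 &&
    max(abs(x - t(x))) < 1e-8
  cm <- if (is_cor) x else stats::cor(x, use = "complete.obs")
  m <- ncol(cm)
  if (m < 3) stop("need >= 3 phenotypes", call. = FALSE)
  ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) {
    warning("correlation matrix not positive semi-definite; ",
            "negative eigenvalues clipped at 0", call. = FALSE)
  }
  ev <- pmax(ev, 0)
  meff_raw <- 1 + (m - 1) * (1 - stats::var(ev) / m)
  meff <- as.integer(min(max(round(meff_raw), 1), m))
  structure(list(M = m, eigenvalues = ev, meff_raw = meff_raw, meff = meff),
            class = "meff_result")
}

#' SNP- and gene-level significance thresholds
#'
#' Experiment-wide thresholds divide the genome-wide base levels by the
#' effective number of independent phenotypes (Nyholt meff); gene thresholds
#' additionally divide the base alpha by the number of genes tested.
#'
#' @param meff effective number of tests (>= 1).
#' @param n_genes number of genes (>= 1).
#' @param base_snp genome-wide SNP threshold (default 5e-8).
#' @param base_gene_alpha base gene-level alpha (default 0.05).
#' @return list: snp_genome, snp_experiment, gene_genome, gene_experiment.
#' @export
significance_thresholds <- function(meff, n_genes = 19299L,
                                    base_snp = 5e-8,
                                    base_gene_alpha = 0.05) {
  stopifnot(meff >= 1, n_genes >= 1)
  list(snp_genome = base_snp,
       snp_experiment = base_snp / meff,
       gene_genome = base_gene_alpha / n_genes,
       gene_experiment = base_gene_alpha / n_genes / meff)
}

#' Additive-allele association scan
#'
#' Per variant, OLS of the prepared phenotype on dosage plus covariates
#' (typically ancestry principal components), with a two-sided t-test on the
#' dosage coefficient. Implemented by projecting phenotype and dosages onto
#' the orthogonal complement of the covariate space (Frisch-Waugh-Lovell),
#' which is exact OLS. Monomorphic variants are flagged and carry NA
#' statistics.
#'
#' @param dosages subjects x variants matrix with values in \[0, 2\].
#' @param phenotype numeric vector aligned with dosage rows (NA allowed;
#'   such subjects are dropped).
#' @param covariates optional subjects x k numeric matrix of covariates
#'   (ancestry PCs); an intercept is always included.
#' @param variants optional variant table (id, chr, pos) merged into output.
#' @return data.frame: id, beta, se, t, p, n, monomorphic.
#' @export
assoc_scan <- function(dosages, phenotype, covariates = NULL,
                       variants = NULL) {
  stopifnot(nrow(dosages) == length(phenotype))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == length(phenotype))
  }
  keep <- is.finite(phenotype)
  y <- phenotype[keep]
  g <- dosages[keep, , drop = FALSE]
  n <- length(y)
  x <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(covariates)) covariates[keep, , drop = FALSE])
  k <- ncol(x)
  qx <- qr(x)
  if (qx$rank < k) stop("rank-deficient covariate matrix", call. = FALSE)
  y_r <- stats::residuals(stats::lm.fit(x, y))
  g_r <- g - x %*% qr.coef(qx, g)
  gg <- colSums(g_r^2)
  mono <- apply(g, 2, function(col) stats::var(col) == 0) | gg < 1e-12
  beta <- colSums(g_r * y_r) / gg
  rss <- sum(y_r^2) - beta^2 * gg
  df <- n - k - 1L
  se <- sqrt(pmax(rss, 0) / df / gg)
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  if (!is.null(variants) && "chr" %in% names(variants) &&
      any(variants$chr %in% c("X", "x", "23", 23L))) {
    warning("X-chromosome variants analyzed with the autosomal model; ",
            "no dosage-compensation adjustment is applied", call. = FALSE)
  }
  out <- data.frame(
    id = colnames(dosages) %||% sprintf("v%d", seq_len(ncol(dosages))),
    beta = beta, se = se, t = tval, p = p, n = n, monomorphic = mono,
    stringsAsFactors = FALSE)
  out[mono, c("beta", "se", "t", "p")] <- NA_real_
  if (!is.null(variants)) {
    out <- merge(variants, out, by = "id", sort = FALSE)
    out <- out[match(colnames(dosages), out$id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Greedy LD clumping of significant associations
#'
#' Repeatedly takes the smallest-p significant variant as a lead (ties broken
#' by chromosome then position) and removes every remaining significant
#' variant whose sample dosage r^2 with that lead is at or above
#' `r2_threshold`.
#'
#' @param assoc association results from [assoc_scan()] (needs id, p and, if
#'   available, chr and pos for tie-breaking).
#' @param dosages the dosage matrix used for the scan (columns named by id).
#' @param p_threshold significance threshold defining the clumping universe.
#' @param r2_threshold LD pruning threshold (default 0.1).
#' @return character vector of lead variant ids (possibly empty).
#' @export
clump_leads <- function(assoc, dosages, p_threshold, r2_threshold = 0.1) {
  sig <- assoc[!is.na(assoc$p) & assoc$p < p_threshold, , drop = FALSE]
  if (!nrow(sig)) return(character(0))
  chr <- if ("chr" %in% names(sig)) sig$chr else rep(0L, nrow(sig))
  pos <- if ("pos" %in% names(sig)) sig$pos else seq_len(nrow(sig))
  ord <- order(sig$p, chr, pos)
  sig <- sig[ord, , drop = FALSE]
  remaining <- sig$id
  leads <- character(0)
  while (length(remaining)) {
    lead <- remaining[1]
    leads <- c(leads, lead)
    g_lead <- dosages[, lead]
    others <- remaining[-1]
    if (!length(others)) break
    r2 <- vapply(others, function(v) {
      g <- dosages[, v]
      if (stats::sd(g) == 0 || stats::sd(g_lead) == 0) return(1)
      stats::cor(g_lead, g)^2
    }, numeric(1))
    remaining <- others[r2 < r2_threshold]
  }
  leads
}

#' Positional SNP-to-gene mapping with a symmetric window
#'
#' A gene is reported for a variant iff the variant position lies in
#' `[start - window, end + window]` (1-based inclusive, same chromosome).
#' Intragenic hits carry distance 0; flanking hits carry the distance to the
#' nearer gene boundary.
#'
#' @param leads data.frame of variants: id, chr, pos.
#' @param genes data.frame of gene intervals: gene, chr, start, end (1-based
#'   inclusive).
#' @param window symmetric window in bp (default 10,000).
#' @return data.frame: id, gene, chr, pos, distance.
#' @export
map_snps_to_genes <- function(leads, genes, window = 10000L) {
  stopifnot(all(c("id", "chr", "pos") %in% names(leads)),
            all(c("gene", "chr", "start", "end") %in% names(genes)))
  if (any(genes$end < genes$start)) stop("malformed gene intervals")
  rows <- list()
  for (i in seq_len(nrow(leads))) {
    v <- leads[i, ]
    hit <- genes[genes$chr == v$chr &
                   v$pos >= genes$start - window &
                   v$pos <= genes$end + window, , drop = FALSE]
    if (nrow(hit)) {
      dist <- ifelse(v$pos >= hit$start & v$pos <= hit$end, 0L,
                     pmin(abs(v$pos - hit$start), abs(v$pos - hit$end)))
      rows[[length(rows) + 1L]] <- data.frame(
        id = v$id, gene = hit$gene, chr = v$chr, pos = v$pos,
        distance = as.integer(dist), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(id = character(0), gene = character(0),
                      chr = integer(0), pos = integer(0),
                      distance = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Ancestry principal components from centered dosages
#'
#' Thin convenience: PCs of the column-centered dosage matrix via SVD. Not a
#' substitute for LD-pruned population-structure PCA on real data.
#'
#' @param dosages subjects x variants matrix.
#' @param k number of components (default 10).
#' @return subjects x k matrix of PC scores.
#' @export
ancestry_pcs <- function(dosages, k = 10L) {
  centered <- scale(dosages, center = TRUE, scale = FALSE)
  sv <- svd(centered, nu = k, nv = 0)
  pcs <- sv$u %*% diag(sv$d[seq_len(k)], k)
  colnames(pcs) <- sprintf("PC%d", seq_len(k))
  pcs
}
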