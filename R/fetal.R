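#' @title Fetal expression modules and preranked GSEA
#' @description Clusters candidate genes by fetal spatiotemporal expression
#'   (within-timepoint Z-scoring, k-means sweep with elbow selection),
#'   builds degree-weighted module prototypes, ranks the transcriptome by
#'   co-expression with each prototype, and runs preranked GSEA with
#'   sign-stratified permutation p-values and FDR.
#' @name fetal_modules
NULL

#' Z-score expression within each (gene, timepoint) slice
#'
#' Standardizes each gene's values across the region x layer cells of one
#' timepoint to mean 0 / SD 1, capturing relative (localized) expression and
#' its change across timepoints.
#'
#' @param cube long data.frame: gene, region, layer, timepoint, value, with a
#'   complete crossing per gene.
#' @return the cube with `value` standardized per (gene, timepoint).
#' @export
zscore_by_timepoint <- function(cube) {
  stopifnot(all(c("gene", "region", "layer", "timepoint", "value") %in%
                  names(cube)))
  key <- interaction(cube$gene, cube$timepoint, drop = TRUE)
  mu <- tapply(cube$value, key, mean)
  s <- tapply(cube$value, key, stats::sd)
  if (any(s == 0 | !is.finite(s))) {
    bad <- names(s)[s == 0 | !is.finite(s)][1]
    stop("constant expression slice: ", bad, call. = FALSE)
  }
  out <- cube
  out$value <- as.numeric((cube$value - mu[key]) / s[key])
  out
}

#' Flatten a normalized cube to a genes x cells profile matrix
#'
#' Column order is timepoint-major, then layer, then region, with
#' self-describing column names `<timepoint>|<layer>|<region>`.
#'
#' @param cube normalized long cube.
#' @param regions,layers,timepoints label orderings (default: order of first
#'   appearance in the cube).
#' @return numeric matrix, genes x (timepoints * layers * regions).
#' @export
flatten_profiles <- function(cube, regions = NULL, layers = NULL,
                             timepoints = NULL) {
  if (is.null(regions)) regions <- unique(cube$region)
  if (is.null(layers)) layers <- unique(cube$layer)
  if (is.null(timepoints)) timepoints <- unique(cube$timepoint)
  genes <- unique(cube$gene)
  cols <- expand.grid(region = regions, layer = layers,
                      timepoint = timepoints,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # timepoint-major, then layer, then region
  cols <- cols[order(match(cols$timepoint, timepoints),
                     match(cols$layer, layers),
                     match(cols$region, regions)), , drop = FALSE]
  cname <- paste(cols$timepoint, cols$layer, cols$region, sep = "|")
  m <- matrix(NA_real_, length(genes), nrow(cols),
              dimnames = list(genes, cname))
  col_key <- paste(cube$timepoint, cube$layer, cube$region, sep = "|")
  idx <- cbind(match(cube$gene, genes), match(col_key, cname))
  m[idx] <- cube$value
  if (anyNA(m)) stop("incomplete (region, layer, timepoint) crossing")
  m
}

#' Reconstruct a long cube from a flattened profile matrix
#'
#' Inverse of [flatten_profiles()]; column names are parsed back into
#' (timepoint, layer, region) triples.
#'
#' @param m genes x cells matrix with `<timepoint>|<layer>|<region>` columns.
#' @return long data.frame: gene, region, layer, timepoint, value.
#' @export
unflatten_profiles <- function(m) {
  parts <- strsplit(colnames(m), "|", fixed = TRUE)
  stopifnot(all(lengths(parts) == 3))
  tp <- vapply(parts, `[`, "", 1)
  ly <- vapply(parts, `[`, "", 2)
  rg <- vapply(parts, `[`, "", 3)
  data.frame(
    gene = rep(rownames(m), times = ncol(m)),
    region = rep(rg, each = nrow(m)),
    layer = rep(ly, each = nrow(m)),
    timepoint = rep(tp, each = nrow(m)),
    value = as.vector(m), stringsAsFactors = FALSE)
}

# kmeans++ style careful seeding: spread initial centers
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1, prob = prob)
    centers[j + 1, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(x[idx, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

#' K-means sweep over k with within/between SS ratio
#'
#' For each k in `[k_min, k_max]` runs `restarts` k-means fits with careful
#' (kmeans++-style) seeding and keeps the best (lowest within-SS) solution.
#' The reported criterion is total within-cluster SS divided by
#' between-cluster SS.
#'
#' @param profiles genes x cells numeric matrix.
#' @param k_min smallest k (default 2).
#' @param k_max largest k (default `floor(n_genes / 2)`).
#' @param restarts restarts per k (default 50).
#' @param seed RNG seed; the sweep is deterministic given the seed.
#' @return list of class `kmeans_sweep`: `k`, `ratio`, `assignments` (list of
#'   per-k label vectors).
#' @export
kmeans_sweep <- function(profiles, k_min = 2L,
                         k_max = max(2L, nrow(profiles) %/% 2L),
                         restarts = 50L, seed = 1L) {
  stopifnot(nrow(profiles) >= 4, k_min >= 2, k_max >= k_min,
            k_max < nrow(profiles))
  set.seed(seed)
  ks <- seq.int(k_min, k_max)
  ratio <- numeric(length(ks))
  assignments <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    best <- NULL
    for (r in seq_len(restarts)) {
      km <- tryCatch(
        stats::kmeans(profiles, centers = .kmeanspp_centers(profiles, k),
                      iter.max = 50L),
        error = function(e) NULL)
      if (is.null(km) || length(unique(km$cluster)) < k) next # re-seed run
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) stop("k-means failed for k = ", k, call. = FALSE)
    ratio[i] <- best$tot.withinss / best$betweenss
    assignments[[i]] <- stats::setNames(best$cluster, rownames(profiles))
  }
  structure(list(k = ks, ratio = ratio, assignments = assignments),
            class = "kmeans_sweep")
}

#' Elbow selection of k
#'
#' Picks the k maximizing the discrete second difference
#' `ratio(k-1) - 2 ratio(k) + ratio(k+1)` (greatest curvature of the
#' within/between SS ratio curve), with ties broken toward the smallest k.
#' Exactly linear (zero-curvature) curves return `k_min` with a warning.
#'
#' @param sweep a [kmeans_sweep()] result, or a list with `k` and `ratio`.
#' @return selected k (integer).
#' @export
elbow_select <- function(sweep) {
  k <- sweep$k
  r <- sweep$ratio
  stopifnot(length(k) >= 3)
  d2 <- r[-c(length(r) - 1, length(r))] - 2 * r[-c(1, length(r))] +
    r[-c(1, 2)]
  if (max(abs(d2)) < 1e-12) {
    warning("zero curvature everywhere; returning k_min", call. = FALSE)
    return(k[1])
  }
  k[-c(1, length(k))][which.max(d2)]
}

#' Degree-weighted module prototypes
#'
#' Degree of gene g = sum over same-module co-members m of
#' `max(0, cor(profile_g, profile_m))` (positively clipped co-expression;
#' set `clip_negative = FALSE` for raw correlations). The module prototype is
#' the degree-weighted mean of member profiles; singleton modules get
#' degree 1.
#'
#' @param profiles genes x cells matrix.
#' @param assignments named integer/character module labels per gene.
#' @param clip_negative clip negative co-expression to 0 (default TRUE).
#' @return list: `degrees` (named numeric), `prototypes` (modules x cells
#'   matrix).
#' @export
module_prototypes <- function(profiles, assignments, clip_negative = TRUE) {
  stopifnot(nrow(profiles) == length(assignments))
  if (is.null(names(assignments))) names(assignments) <- rownames(profiles)
  mods <- sort(unique(assignments))
  degrees <- stats::setNames(numeric(length(assignments)),
                             names(assignments))
  prototypes <- matrix(NA_real_, length(mods), ncol(profiles),
                       dimnames = list(as.character(mods),
                                       colnames(profiles)))
  for (mod in mods) {
    members <- names(assignments)[assignments == mod]
    pm <- profiles[members, , drop = FALSE]
    if (any(apply(pm, 1, stats::sd) == 0)) {
      stop("constant profile in module ", mod, call. = FALSE)
    }
    if (length(members) == 1) {
      degrees[members] <- 1
      prototypes[as.character(mod), ] <- pm[1, ]
      next
    }
    cc <- stats::cor(t(pm))
    diag(cc) <- 0
    if (clip_negative) cc <- pmax(cc, 0)
    deg <- rowSums(cc)
    degrees[members] <- deg
    w <- if (sum(deg) > 0) deg / sum(deg) else rep(1 / length(deg),
                                                   length(deg))
    prototypes[as.character(mod), ] <- colSums(pm * w)
  }
  list(degrees = degrees, prototypes = prototypes)
}

#' Rank genes by co-expression with a prototype
#'
#' Scores every gene by the Pearson correlation of its profile with the
#' prototype, sorted descending; ties break by gene id, and constant-profile
#' genes score NA and are placed last.
#'
#' @param prototype numeric profile vector.
#' @param profiles genes x cells matrix (all genes to rank).
#' @return data.frame: gene, score, sorted by descending score.
#' @export
coexpression_ranking <- function(prototype, profiles) {
  if (stats::sd(prototype) == 0) stop("constant prototype", call. = FALSE)
  score <- apply(profiles, 1, function(g) {
    if (stats::sd(g) == 0) NA_real_ else stats::cor(g, prototype)
  })
  out <- data.frame(gene = rownames(profiles), score = score,
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$gene, na.last = TRUE), , drop = FALSE]
}

# weighted KS enrichment score for hit indicator along a ranked score vector
.gsea_es <- function(scores, is_hit, weight) {
  n <- length(scores)
  nh <- sum(is_hit)
  w <- abs(scores)^weight
  w[is_hit & w == 0] <- 0 # zero-score hits contribute nothing at weight > 0
  denom_hit <- sum(w[is_hit])
  inc <- numeric(n)
  if (denom_hit > 0) inc[is_hit] <- w[is_hit] / denom_hit
  inc[!is_hit] <- -1 / (n - nh)
  running <- cumsum(inc)
  running[which.max(abs(running))]
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic (hit increments
#' proportional to |score|^weight, miss decrements 1/(N - set size)), with
#' gene-label permutation nulls. P-values are sign-matched (positive ES
#' against positive null ES, negative against negative), NES divides ES by
#' the mean |same-sign null ES|, and FDR q uses the sign-stratified
#' ratio-of-tails procedure over all sets in the run.
#'
#' @param ranking data.frame from [coexpression_ranking()] (gene, score) or
#'   a named numeric vector of scores, no duplicate gene ids; NA scores are
#'   dropped.
#' @param gene_sets named list of character vectors of gene ids.
#' @param weight exponent on |score| (default 1).
#' @param n_perm number of gene-label permutations (>= 100; default 1000).
#' @param seed RNG seed.
#' @param min_size,max_size set-size bounds after intersecting with the
#'   ranking (defaults 2 and Inf).
#' @return data.frame: set, size, es, nes, p, q.
#' @export
gsea_preranked <- function(ranking, gene_sets, weight = 1, n_perm = 1000L,
                           seed = 1L, min_size = 2L, max_size = Inf) {
  if (is.data.frame(ranking)) {
    scores <- stats::setNames(ranking$score, ranking$gene)
  } else {
    scores <- ranking
  }
  scores <- scores[!is.na(scores)]
  if (anyDuplicated(names(scores))) stop("duplicate gene ids", call. = FALSE)
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  scores <- sort(scores, decreasing = TRUE)
  genes <- names(scores)
  n <- length(genes)
  sizes <- vapply(gene_sets, function(s) sum(genes %in% s), integer(1))
  keep <- sizes >= min_size & sizes <= max_size & sizes < n
  if (!any(keep)) stop("no gene set within size bounds", call. = FALSE)
  gene_sets <- gene_sets[keep]
  sizes <- sizes[keep]
  es <- vapply(seq_along(gene_sets), function(i) {
    .gsea_es(scores, genes %in% gene_sets[[i]], weight)
  }, numeric(1))
  set.seed(seed)
  usizes <- sort(unique(sizes))
  null_by_size <- lapply(usizes, function(sz) {
    vapply(seq_len(n_perm), function(i) {
      hit <- logical(n)
      hit[sample.int(n, sz)] <- TRUE
      .gsea_es(scores, hit, weight)
    }, numeric(1))
  })
  names(null_by_size) <- as.character(usizes)
  p <- numeric(length(es))
  nes <- numeric(length(es))
  null_nes_all <- c()
  for (i in seq_along(es)) {
    null <- null_by_size[[as.character(sizes[i])]]
    same <- if (es[i] >= 0) null[null >= 0] else null[null < 0]
    if (!length(same)) same <- 0
    p[i] <- .perm_p(sum(abs(same) >= abs(es[i])), length(same))
    denom <- mean(abs(same))
    nes[i] <- if (denom > 0) es[i] / denom else 0
  }
  # sign-stratified ratio-of-tails FDR over null NES pooled across sizes
  null_nes <- unlist(lapply(seq_along(es), function(i) {
    null <- null_by_size[[as.character(sizes[i])]]
    pos <- null[null >= 0]; neg <- null[null < 0]
    c(if (length(pos)) pos / mean(abs(pos)) else NULL,
      if (length(neg)) neg / mean(abs(neg)) else NULL)
  }))
  q <- vapply(seq_along(es), function(i) {
    if (nes[i] >= 0) {
      num_pool <- null_nes[null_nes >= 0]
      obs_pool <- nes[nes >= 0]
      num <- mean(num_pool >= nes[i])
      den <- mean(obs_pool >= nes[i])
    } else {
      num_pool <- null_nes[null_nes < 0]
      obs_pool <- nes[nes < 0]
      num <- mean(num_pool <= nes[i])
      den <- mean(obs_pool <= nes[i])
    }
    if (!is.finite(num) || den == 0) return(1)
    min(1, num / den)
  }, numeric(1))
  data.frame(set = names(gene_sets), size = sizes, es = es, nes = nes,
             p = p, q = q, row.names = NULL, stringsAsFactors = FALSE)
}
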