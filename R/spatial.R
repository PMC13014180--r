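#' @title Spin-based spatial statistics and cross-syndrome modes
#' @description Spatial correlations between per-sulcus maps with
#'   rotation-based ("spin") permutation nulls respecting hemisphere mirror
#'   symmetry, cross-syndrome similarity matrices, and permutation-validated
#'   PCA of effect maps.
#' @name spatial_modes
NULL

#' Pearson correlation between two sulcus maps
#'
#' @param a,b numeric vectors, one value per sulcus in the same order.
#' @return correlation coefficient.
#' @export
spatial_correlation <- function(a, b) {
  stopifnot(length(a) == length(b), all(is.finite(a)), all(is.finite(b)))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant map", call. = FALSE)
  }
  stats::cor(a, b)
}

# one spin: rotate left centroids by R and right centroids by the x-mirrored
# rotation; return, per original parcel, the index of the donor parcel.
# method "nearest": nearest rotated centroid, duplicates permitted.
# method "exclusive": greedy one-to-one matching by descending similarity
# (the Vasa-style parcel variant), preserving the spun map's value
# distribution at the cost of larger angular matching error.
.spin_assignment <- function(xyz, hemi, rot, method = "nearest") {
  mirror <- diag(c(-1, 1, 1))
  assign <- integer(nrow(xyz))
  for (h in unique(hemi)) {
    idx <- which(hemi == h)
    r_h <- if (h == "L") rot else mirror %*% rot %*% mirror
    rotated <- xyz[idx, , drop = FALSE] %*% t(r_h)
    sim <- xyz[idx, , drop = FALSE] %*% t(rotated)  # cosine similarity
    if (method == "nearest") {
      assign[idx] <- idx[max.col(sim, ties.method = "first")]
    } else {
      n_h <- length(idx)
      local <- integer(n_h)
      free_row <- rep(TRUE, n_h)
      free_col <- rep(TRUE, n_h)
      for (step in seq_len(n_h)) {
        sub <- sim
        sub[!free_row, ] <- -Inf
        sub[, !free_col] <- -Inf
        best <- arrayInd(which.max(sub), dim(sub))
        local[best[1]] <- best[2]
        free_row[best[1]] <- FALSE
        free_col[best[2]] <- FALSE
      }
      assign[idx] <- idx[local]
    }
  }
  assign
}

#' Spin permutation test for the correlation of two sulcus maps
#'
#' Each spin applies one uniform random 3-D rotation to the left-hemisphere
#' centroids and its x-mirrored twin to the right-hemisphere centroids; every
#' parcel then receives map `a`'s value at the nearest rotated centroid
#' within its hemisphere (donors may repeat), and the correlation with map
#' `b` is recomputed. The p-value uses the add-one estimator; two-sided tests
#' compare absolute values.
#'
#' @param parcellation data.frame (sulcus, hemisphere, x, y, z) covering both
#'   maps' sulci, e.g. from [simulate_parcellation()].
#' @param a,b named numeric maps (names = sulcus labels) or plain vectors in
#'   parcellation order.
#' @param n_spins number of spins (>= 100; the reference setting is 10,000).
#' @param seed RNG seed.
#' @param sidedness `"two-sided"` (default) or `"one-sided"` (upper tail of
#'   signed r).
#' @param method donor assignment: `"nearest"` (default; nearest rotated
#'   centroid, duplicate donors permitted) or `"exclusive"` (greedy
#'   one-to-one rotation matching, which keeps the spun map's value
#'   distribution intact).
#' @param .identity_rotation test hook: force every spin to the identity.
#' @return list: `r_obs`, `null` (numeric vector of spun correlations),
#'   `p_spin`, `n_spins`.
#' @export
spin_null <- function(parcellation, a, b, n_spins = 10000L, seed = 1L,
                      sidedness = c("two-sided", "one-sided"),
                      method = c("nearest", "exclusive"),
                      .identity_rotation = FALSE) {
  sidedness <- match.arg(sidedness)
  method <- match.arg(method)
  if (n_spins < 100) stop("n_spins must be >= 100", call. = FALSE)
  if (!is.null(names(a))) a <- a[parcellation$sulcus]
  if (!is.null(names(b))) b <- b[parcellation$sulcus]
  stopifnot(length(a) == nrow(parcellation), length(b) == nrow(parcellation))
  xyz <- as.matrix(parcellation[, c("x", "y", "z")])
  nrm <- sqrt(rowSums(xyz^2))
  if (max(abs(nrm - 1)) > 1e-6) stop("centroids must be unit-norm")
  r_obs <- spatial_correlation(a, b)
  set.seed(seed)
  null <- vapply(seq_len(n_spins), function(i) {
    rot <- if (.identity_rotation) diag(3) else random_rotation()
    idx <- .spin_assignment(xyz, parcellation$hemisphere, rot, method)
    stats::cor(a[idx], b)
  }, numeric(1))
  exceed <- if (sidedness == "two-sided") {
    sum(abs(null) >= abs(r_obs))
  } else {
    sum(null >= r_obs)
  }
  list(r_obs = r_obs, null = null, p_spin = .perm_p(exceed, n_spins),
       n_spins = n_spins)
}

#' Phenotype-congruence profile against a complexity effect map
#'
#' Spatially correlates each phenotype's effect map with the syndrome's
#' complexity effect map, with spin-test significance and Bonferroni
#' correction over syndromes (the reference analysis tests 9 syndromes, so
#' the corrected threshold is alpha / n_syndromes).
#'
#' @param phenotype_maps named list of per-sulcus effect vectors (one per
#'   phenotype).
#' @param delta_map the syndrome's complexity (delta) effect map.
#' @param parcellation spin substrate.
#' @param syndrome syndrome id recorded in the output.
#' @param n_syndromes Bonferroni denominator (default 9).
#' @param n_spins,seed,alpha spin-test settings.
#' @return data.frame: syndrome, phenotype, r, p_spin, bonferroni, nominal.
#' @export
congruence_profile <- function(phenotype_maps, delta_map, parcellation,
                               syndrome = "syndrome", n_syndromes = 9L,
                               n_spins = 1000L, seed = 1L, alpha = 0.05) {
  rows <- lapply(names(phenotype_maps), function(p) {
    sp <- spin_null(parcellation, phenotype_maps[[p]], delta_map,
                    n_spins = n_spins, seed = seed)
    data.frame(syndrome = syndrome, phenotype = p, r = sp$r_obs,
               p_spin = sp$p_spin, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bonferroni <- out$p_spin < alpha / n_syndromes
  out$nominal <- out$p_spin < alpha
  out
}

#' PCA of cross-syndrome complexity effect maps with permutation validation
#'
#' PCA of the column-centered syndromes x sulci matrix. Per-sulcus PC scores
#' come from the right singular vectors; per-syndrome loadings are the
#' projections, scaled to \[-1, 1\] by their maximum absolute value. The
#' permutation null independently permutes each syndrome's map across sulci
#' and recomputes each component's variance-explained fraction; p-values use
#' the add-one estimator. PC signs are set so the top-loading syndrome loads
#' positively.
#'
#' @param maps syndromes x sulci numeric matrix (rownames = syndromes).
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed RNG seed.
#' @return list of class `delta_pca`: `scores` (sulci x PCs), `loadings`
#'   (syndromes x PCs, scaled), `explained`, `p_perm`.
#' @export
delta_pca <- function(maps, n_perm = 1000L, seed = 1L) {
  stopifnot(is.matrix(maps), nrow(maps) >= 2, ncol(maps) >= 3)
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  ve_of <- function(m) {
    d <- svd(scale(m, center = TRUE, scale = FALSE))$d
    d^2 / sum(d^2)
  }
  centered <- scale(maps, center = TRUE, scale = FALSE)
  sv <- svd(centered)
  n_pc <- sum(sv$d > 1e-12)
  if (n_pc == 0) stop("degenerate: no variance across maps", call. = FALSE)
  explained <- (sv$d^2 / sum(sv$d^2))[seq_len(n_pc)]
  scores <- sv$v[, seq_len(n_pc), drop = FALSE] # per-sulcus
  load_raw <- sv$u[, seq_len(n_pc), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pc)], n_pc)             # per-syndrome projections
  for (k in seq_len(n_pc)) {
    top <- which.max(abs(load_raw[, k]))
    if (load_raw[top, k] < 0) {
      load_raw[, k] <- -load_raw[, k]
      scores[, k] <- -scores[, k]
    }
  }
  loadings <- sweep(load_raw, 2, apply(abs(load_raw), 2, max), `/`)
  rownames(scores) <- colnames(maps)
  rownames(loadings) <- rownames(maps)
  colnames(scores) <- colnames(loadings) <- sprintf("PC%d", seq_len(n_pc))
  set.seed(seed)
  exceed <- numeric(n_pc)
  for (i in seq_len(n_perm)) {
    perm <- t(apply(maps, 1, sample))
    ve_p <- ve_of(perm)[seq_len(n_pc)]
    exceed <- exceed + (ve_p >= explained)
  }
  structure(list(scores = scores, loadings = loadings,
                 explained = explained,
                 p_perm = .perm_p(exceed, n_perm)),
            class = "delta_pca")
}

#' Cross-syndrome similarity matrix of complexity effect maps
#'
#' Symmetric matrix of pairwise spatial correlations, with rows/columns
#' ordered by descending PC1 loading from [delta_pca()].
#'
#' @param maps named list of per-sulcus effect vectors, or a syndromes x
#'   sulci matrix.
#' @param n_perm,seed passed to [delta_pca()] for the ordering.
#' @return list: `similarity` (ordered matrix), `order`, `pca`.
#' @export
cross_syndrome_similarity <- function(maps, n_perm = 1000L, seed = 1L) {
  if (is.list(maps)) maps <- do.call(rbind, maps)
  stopifnot(nrow(maps) >= 2)
  n <- nrow(maps)
  sim <- diag(1, n)
  dimnames(sim) <- list(rownames(maps), rownames(maps))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      sim[i, j] <- sim[j, i] <- spatial_correlation(maps[i, ], maps[j, ])
    }
  }
  # duplicate (zero-variance) collections have no PC ordering; keep input
  # order rather than erroring, since the similarity matrix is still valid
  pca <- tryCatch(delta_pca(maps, n_perm = n_perm, seed = seed),
                  error = function(e) NULL)
  ord <- if (is.null(pca)) seq_len(n) else {
    order(pca$loadings[, 1], decreasing = TRUE)
  }
  list(similarity = sim[ord, ord, drop = FALSE],
       order = rownames(maps)[ord], pca = pca)
}
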