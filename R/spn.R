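#' @title Sulcal phenotype networks (SPNs)
#' @description Core machinery: within-subject standardization of the five
#'   shape phenotypes, per-subject SPN construction, group-mean SPNs, the
#'   eigen-fold (linear-to-complex) index, and per-sulcus complexity scores.
#' @name spn_core
NULL

#' Five core sulcal shape phenotypes
#' @export
core_phenotypes <- function() {
  c("average_depth", "depth_variability", "longest_branch",
    "branch_span", "fractal_dimension")
}

#' Z-score a subject's phenotype matrix across sulci
#'
#' Each phenotype column is standardized to mean 0 / SD 1 (denominator n-1)
#' across the sulci of one subject, so that the SPN captures shape profile
#' similarity rather than differences in phenotype units.
#'
#' @param x numeric matrix, sulci x phenotypes, rownames = sulcus labels.
#' @param subject subject id used in error messages.
#' @return matrix of the same shape with standardized columns.
#' @export
zscore_within_subject <- function(x, subject = "subject") {
  stopifnot(is.matrix(x), is.numeric(x))
  if (!all(is.finite(x))) stop("non-finite phenotype values for ", subject)
  out <- x
  for (j in seq_len(ncol(x))) {
    s <- stats::sd(x[, j])
    if (!is.finite(s) || s == 0) {
      stop("constant phenotype '", colnames(x)[j] %||% j,
           "' for subject ", subject, call. = FALSE)
    }
    out[, j] <- (x[, j] - mean(x[, j])) / s
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a subject's sulcal phenotype network
#'
#' The SPN is the sulcus x sulcus Pearson correlation matrix of standardized
#' phenotype profiles: entry (i, j) is the correlation between sulcus i's and
#' sulcus j's phenotype vectors. The diagonal is set exactly to 1.
#'
#' @param z standardized sulci x phenotypes matrix
#'   (from [zscore_within_subject()]).
#' @return symmetric matrix with unit diagonal, class `spn`.
#' @export
build_spn <- function(z) {
  stopifnot(is.matrix(z), ncol(z) >= 2)
  if (!all(is.finite(z))) stop("non-finite standardized values")
  p <- ncol(z)
  row_sd <- sqrt(pmax(rowSums(z^2) - rowSums(z)^2 / p, 0) / (p - 1))
  if (any(row_sd == 0)) {
    stop("constant phenotype profile for sulcus ",
         paste(rownames(z)[row_sd == 0], collapse = ", "), call. = FALSE)
  }
  m <- stats::cor(t(z))
  diag(m) <- 1
  m <- (m + t(m)) / 2
  dimnames(m) <- list(rownames(z), rownames(z))
  .assert_spn(m)
  structure(m, class = c("spn", "matrix", "array"))
}

#' Element-wise mean SPN
#'
#' @param spns list of SPN matrices with identical sulcus ordering.
#' @return SPN matrix of element-wise means.
#' @export
mean_spn <- function(spns) {
  stopifnot(is.list(spns), length(spns) >= 1)
  ref <- rownames(spns[[1]])
  for (s in spns) {
    if (!identical(rownames(s), ref)) {
      stop("sulcus ordering mismatch between SPNs", call. = FALSE)
    }
  }
  m <- Reduce(`+`, lapply(spns, unclass)) / length(spns)
  diag(m) <- 1
  .assert_spn(m, "mean SPN")
  structure(m, class = c("spn", "matrix", "array"))
}

#' Eigen-fold index of a mean SPN
#'
#' First principal component of the (column-centered, unstandardized) mean
#' SPN, treating rows as observations. Scores order sulci along the
#' linear-to-complex axis. The sign is fixed either so that the `anchor`
#' sulcus scores positive, or (if `reference_axis` is supplied) so that the
#' correlation with the reference axis is non-negative. The package
#' convention anchors the most-complex sulcus of the annotation positive, so
#' that downstream complexity scores read high = complex.
#'
#' @param spn mean SPN matrix.
#' @param anchor sulcus label whose score is forced positive. Default: the
#'   most complex sulcus of [default_sulcus_annotation()] present in the SPN.
#' @param reference_axis optional numeric vector (one value per sulcus); if
#'   given, overrides `anchor` and orients scores to correlate positively.
#' @return list with `scores` (named numeric), `explained` (variance fraction
#'   of PC1) and `anchor`.
#' @export
eigen_fold_index <- function(spn, anchor = NULL, reference_axis = NULL) {
  .assert_spn(unclass(spn))
  m <- unclass(spn)
  centered <- scale(m, center = TRUE, scale = FALSE)
  sv <- svd(centered)
  if (sv$d[1] < 1e-12) stop("degenerate SPN: all rows equal", call. = FALSE)
  scores <- sv$u[, 1] * sv$d[1]
  names(scores) <- rownames(m)
  explained <- sv$d[1]^2 / sum(sv$d^2)
  if (!is.null(reference_axis)) {
    stopifnot(length(reference_axis) == length(scores))
    if (stats::cor(scores, reference_axis) < 0) scores <- -scores
    anchor <- NULL
  } else {
    if (is.null(anchor)) {
      ann <- default_sulcus_annotation()
      ann <- ann[ann$sulcus %in% rownames(m), , drop = FALSE]
      anchor <- if (nrow(ann)) most_complex_sulcus(ann) else rownames(m)[1]
    }
    if (!anchor %in% names(scores)) {
      stop("anchor sulcus '", anchor, "' not in SPN", call. = FALSE)
    }
    if (scores[anchor] < 0) scores <- -scores
  }
  structure(list(scores = scores, explained = explained, anchor = anchor),
            class = "eigen_fold_index")
}

#' Per-sulcus complexity scores for one subject
#'
#' For each sulcus i, the raw complexity r_i is the Pearson correlation of
#' the subject's SPN row i with the eigen-fold scores. By default the
#' self-correlation position i (a constant 1) is excluded from both vectors;
#' set `include_diagonal = TRUE` to correlate all positions. Scores are
#' Fisher-Z transformed with clipping at |r| = 1 - 1e-12.
#'
#' @param spn the subject's SPN.
#' @param efi an [eigen_fold_index()] result (or a bare named numeric of
#'   scores in matching order).
#' @param include_diagonal include position i in the correlation
#'   (default FALSE).
#' @return data.frame with columns `sulcus`, `r`, `fisher_z`.
#' @export
complexity_scores <- function(spn, efi, include_diagonal = FALSE) {
  m <- unclass(spn)
  scores <- if (inherits(efi, "eigen_fold_index")) efi$scores else efi
  stopifnot(length(scores) == nrow(m))
  if (!is.null(names(scores)) && !is.null(rownames(m)) &&
      !identical(names(scores), rownames(m))) {
    stop("sulcus order mismatch between SPN and eigen-fold index",
         call. = FALSE)
  }
  n <- nrow(m)
  if (include_diagonal) {
    row_sd <- apply(m, 1, stats::sd)
    if (any(row_sd == 0)) {
      stop("constant SPN row for sulcus ",
           rownames(m)[which(row_sd == 0)[1]] %||% which(row_sd == 0)[1],
           call. = FALSE)
    }
    r <- as.vector(stats::cor(t(m), scores))
  } else {
    # vectorized leave-one-out correlation: for sulcus i, correlate row i
    # with the eigen-fold scores over the other n-1 positions, via sum
    # adjustments of the full-row moments
    np <- n - 1
    e <- as.numeric(scores)
    sx <- rowSums(m) - diag(m)
    sxx <- rowSums(m^2) - diag(m)^2
    sxy <- as.vector(m %*% e) - diag(m) * e
    sy <- sum(e) - e
    syy <- sum(e^2) - e^2
    vx <- np * sxx - sx^2
    vy <- np * syy - sy^2
    if (any(vx <= 1e-20)) {
      stop("constant SPN row for sulcus ",
           rownames(m)[which(vx <= 1e-20)[1]] %||% which(vx <= 1e-20)[1],
           call. = FALSE)
    }
    r <- (np * sxy - sx * sy) / sqrt(vx * vy)
  }
  r <- pmax(pmin(r, 1), -1)
  data.frame(
    sulcus = rownames(m) %||% as.character(seq_len(n)),
    r = r,
    fisher_z = fisher_z(r),
    stringsAsFactors = FALSE
  )
}

#' Complexity scores against multiple reference eigen-fold indices
#'
#' Sensitivity analysis: each subject's SPN is scored against the eigen-fold
#' index derived from every supplied reference cohort, and a per-sulcus
#' between-reference agreement (correlation of subject scores across
#' references) is reported.
#'
#' @param spns list of subject SPNs.
#' @param references list of [eigen_fold_index()] results (or score vectors).
#' @param include_diagonal passed to [complexity_scores()].
#' @return list with `scores` (list over references of subjects x sulci
#'   Fisher-Z matrices) and `agreement` (per-sulcus matrix of pairwise
#'   between-reference correlations averaged over pairs).
#' @export
cross_reference_complexity <- function(spns, references,
                                       include_diagonal = FALSE) {
  stopifnot(length(references) >= 1, length(spns) >= 2)
  per_ref <- lapply(references, function(ref) {
    do.call(rbind, lapply(spns, function(s) {
      complexity_scores(s, ref, include_diagonal)$fisher_z
    }))
  })
  n_sulci <- ncol(per_ref[[1]])
  sulci <- rownames(unclass(spns[[1]]))
  n_ref <- length(references)
  agree <- rep(NA_real_, n_sulci)
  if (n_ref >= 2) {
    for (j in seq_len(n_sulci)) {
      rs <- c()
      for (a in seq_len(n_ref - 1)) {
        for (b in seq(a + 1, n_ref)) {
          rs <- c(rs, stats::cor(per_ref[[a]][, j], per_ref[[b]][, j]))
        }
      }
      agree[j] <- mean(rs)
    }
  }
  names(agree) <- sulci
  list(scores = per_ref, agreement = agree)
}

#' Edge-wise similarity of two SPNs
#'
#' Pearson correlation over strictly upper-triangular entries.
#'
#' @param a,b SPN matrices with identical sulcus ordering.
#' @return correlation coefficient.
#' @export
spn_similarity <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  stopifnot(identical(dim(a), dim(b)))
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    stop("sulcus ordering mismatch", call. = FALSE)
  }
  ua <- a[upper.tri(a)]
  ub <- b[upper.tri(b)]
  if (stats::sd(ua) == 0 || stats::sd(ub) == 0) {
    stop("constant upper triangle", call. = FALSE)
  }
  stats::cor(ua, ub)
}

#' Bipartite (linear/complex) classes from a mean SPN
#'
#' Two-group k-means clustering of SPN rows, with labels oriented so that the
#' anchor sulcus's cluster is called `"linear"` (anchor defaults to the most
#' linear sulcus of the annotation).
#'
#' @param spn mean SPN.
#' @param anchor sulcus whose cluster is labeled `"linear"`.
#' @param seed RNG seed for the k-means restarts.
#' @param nstart number of k-means restarts.
#' @return named character vector of `"linear"`/`"complex"` labels.
#' @export
bipartite_classes <- function(spn, anchor = NULL, seed = 1L, nstart = 25L) {
  m <- unclass(spn)
  .assert_spn(m)
  if (is.null(anchor)) {
    ann <- default_sulcus_annotation()
    ann <- ann[ann$sulcus %in% rownames(m), , drop = FALSE]
    anchor <- if (nrow(ann)) most_linear_sulcus(ann) else rownames(m)[1]
  }
  if (!anchor %in% rownames(m)) stop("anchor not in SPN", call. = FALSE)
  km <- withr_seed(seed, stats::kmeans(m, centers = 2L, nstart = nstart))
  cl <- km$cluster
  labels <- ifelse(cl == cl[anchor], "linear", "complex")
  names(labels) <- rownames(m)
  labels
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
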