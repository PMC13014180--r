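# small shared helpers

#' Fisher Z transform with clipping
#'
#' atanh of a correlation, with |r| clipped to 1 - 1e-12 so perfect
#' correlations map to a large finite value rather than Inf.
#'
#' @param r numeric vector of correlations in \[-1, 1\].
#' @param clip clipping bound (default `1 - 1e-12`).
#' @return numeric vector of Fisher-Z values.
#' @export
fisher_z <- function(r, clip = 1 - 1e-12) {
  stopifnot(is.numeric(r), all(is.na(r) | abs(r) <= 1 + 1e-8))
  atanh(pmax(pmin(r, clip), -clip))
}

# sample SD with n-1 denominator, erroring on degenerate input
.sd_checked <- function(x, what = "input") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("zero or undefined standard deviation for ", what, call. = FALSE)
  }
  s
}

# adjusted Rand index between two label vectors (Hubert & Arabie)
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  maxidx <- (sum_i + sum_j) / 2
  if (maxidx == expected) return(0)
  (sum_ij - expected) / (maxidx - expected)
}

# uniform random rotation in SO(3) via QR of a Gaussian matrix
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qrd)
  d <- sign(diag(qr.R(qrd)))
  d[d == 0] <- 1
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# validated symmetric unit-diagonal correlation-like matrix
.assert_spn <- function(m, label = "SPN") {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (!all(is.finite(m))) stop(label, " has non-finite entries", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8) stop(label, " is not symmetric", call. = FALSE)
  if (max(abs(diag(m) - 1)) > 1e-8) {
    stop(label, " diagonal is not 1", call. = FALSE)
  }
  if (max(abs(m)) > 1 + 1e-8) stop(label, " entries outside [-1,1]", call. = FALSE)
  invisible(m)
}

# add-one permutation p-value
.perm_p <- function(n_exceed, n_perm) (1 + n_exceed) / (1 + n_perm)
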