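test_that("rint matches the Blom closed form, with average ranks for ties", {
  set.seed(101)
  x <- rnorm(57)
  n <- length(x)
  oracle <- qnorm((rank(x) - 3 / 8) / (n + 1 / 4))
  expect_equal(rint(x), oracle, tolerance = 1e-12)
  # ties share the average-rank normal score
  y <- c(1, 2, 2, 3)
  ry <- rint(y)
  expect_equal(ry[2], ry[3])
})

test_that("prepare_phenotype runs the printed steps in order", {
  set.seed(103)
  n <- 1000
  covs <- data.frame(subject = sprintf("s%04d", 1:n),
                     age = runif(n, 45, 80), sex = rbinom(n, 1, 0.5),
                     site = sample(c("a", "b"), n, TRUE),
                     EN = round(rnorm(n, -80, 30)))
  values <- rnorm(n)
  # plant one value at mean + 6 SD: exactly that subject is excluded
  values[17] <- mean(values) + 6 * sd(values)
  prep <- prepare_phenotype(values, covs)
  expect_true(prep$excluded[17])
  expect_equal(sum(prep$excluded), 1L)
  expect_equal(prep$reason[17], "outlier_5sd")
  expect_true(is.na(prep$value[17]))
  # post-RINT, pre-residualization values follow the Blom closed form:
  # residualization preserves orthogonality to covariates instead
  keep <- !prep$excluded
  for (cv in c("age", "EN")) {
    expect_lt(abs(cor(prep$value[keep], covs[[cv]][keep])), 1e-8)
  }
  expect_lt(abs(cor(prep$value[keep],
                    covs$age[keep]^2 * covs$sex[keep])), 1e-8)
  expect_lt(abs(mean(prep$value[keep])), 1e-10)
})

test_that("prepare_phenotype is invariant to monotone pre-transforms", {
  set.seed(107)
  n <- 400
  covs <- data.frame(subject = 1:n, age = runif(n, 45, 80),
                     sex = rbinom(n, 1, 0.5), site = "x",
                     EN = rnorm(n))
  x <- rnorm(n)
  p1 <- prepare_phenotype(x, covs)
  # strictly monotone map applied upstream of RINT: same ranks, same output
  # (bounded transform so the 5-SD outlier step stays inert for both)
  p2 <- prepare_phenotype(tanh(x / 10), covs)
  expect_equal(p1$value, p2$value, tolerance = 1e-10)
  expect_error(prepare_phenotype(rnorm(20), covs[1:20, ]), "fewer than 30")
})

test_that("nyholt_meff matches the eigenvalue-variance formula", {
  # independent phenotypes: Var(lambda) = 0 so meff = M
  expect_equal(nyholt_meff(diag(10))$meff, 10L)
  # rank-1 (all correlations 1): lambda = (M, 0, ..., 0), meff = 1
  ones <- matrix(1, 6, 6)
  expect_equal(nyholt_meff(ones)$meff, 1L)
  expect_equal(nyholt_meff(ones)$meff_raw, 1, tolerance = 1e-10)
  # random data: independent brute-force evaluation of the formula
  set.seed(109)
  x <- matrix(rnorm(200 * 10), 200, 10)
  x[, 2] <- x[, 1] + rnorm(200, 0, 0.4)
  res <- nyholt_meff(x)
  ev <- eigen(cor(x))$values
  oracle <- 1 + (10 - 1) * (1 - var(ev) / 10)
  expect_equal(res$meff_raw, oracle, tolerance = 1e-10)
  expect_equal(res$meff, as.integer(round(oracle)))
})

test_that("meff decreases as exchangeable correlation rises", {
  m <- 8
  prev <- Inf
  for (rho in c(0, 0.2, 0.4, 0.6, 0.8)) {
    cm <- matrix(rho, m, m)
    diag(cm) <- 1
    cur <- nyholt_meff(cm)$meff_raw
    expect_lte(cur, prev + 1e-10)
    prev <- cur
  }
})

test_that("significance thresholds reproduce the published arithmetic", {
  thr <- significance_thresholds(meff = 34, n_genes = 19299)
  expect_equal(signif(thr$snp_experiment, 3), 1.47e-9)
  expect_equal(signif(thr$gene_experiment, 3), 7.62e-8)
  expect_equal(signif(thr$gene_genome, 3), 2.59e-6)
  expect_equal(thr$snp_genome, 5e-8)
  thr1 <- significance_thresholds(meff = 1, n_genes = 19299)
  expect_equal(thr1$snp_experiment, thr1$snp_genome)
  expect_equal(thr1$gene_experiment, thr1$gene_genome)
})

test_that("assoc_scan equals per-variant lm fits", {
  set.seed(113)
  sim <- simulate_genotypes(genotype_spec(n_subjects = 300, n_snps = 12,
                                          seed = 113))
  pcs <- matrix(rnorm(300 * 3), 300, 3)
  y <- sim$phenotype + pcs %*% c(0.2, -0.1, 0.3)
  res <- assoc_scan(sim$dosages, as.vector(y), covariates = pcs)
  for (j in c(1, 5, 12)) {
    fit <- summary(lm(y ~ sim$dosages[, j] + pcs))$coefficients
    expect_equal(res$beta[j], fit[2, 1], tolerance = 1e-10)
    expect_equal(res$se[j], fit[2, 2], tolerance = 1e-10)
    expect_equal(res$p[j], fit[2, 4], tolerance = 1e-10)
  }
})

test_that("assoc_scan with no covariates equals textbook OLS formulas", {
  set.seed(127)
  g <- matrix(rbinom(400, 2, 0.3), 200, 2,
              dimnames = list(NULL, c("v1", "v2")))
  y <- 0.3 * g[, 1] + rnorm(200)
  res <- assoc_scan(g, y)
  gc <- g[, 1] - mean(g[, 1])
  beta <- sum(gc * (y - mean(y))) / sum(gc^2)
  resid <- y - mean(y) - beta * gc
  se <- sqrt(sum(resid^2) / 198 / sum(gc^2))
  expect_equal(res$beta[1], beta, tolerance = 1e-10)
  expect_equal(res$se[1], se, tolerance = 1e-10)
  # monomorphic variants are flagged, not numeric
  g2 <- cbind(g, v3 = rep(1L, 200))
  res2 <- assoc_scan(g2, y)
  expect_true(res2$monomorphic[3])
  expect_true(is.na(res2$p[3]))
})

test_that("assoc_scan p-values are uniform under a permuted phenotype", {
  set.seed(131)
  sim <- simulate_genotypes(genotype_spec(n_subjects = 500, n_snps = 2000,
                                          block_size = 1,
                                          within_block_r = 0, seed = 131))
  res <- assoc_scan(sim$dosages, sample(sim$phenotype))
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("clump_leads matches an exhaustive greedy oracle", {
  set.seed(137)
  sim <- simulate_genotypes(genotype_spec(
    n_subjects = 500, n_snps = 20, block_size = 4, within_block_r = 0.9,
    causal = data.frame(snp = c(2, 10, 18), effect = c(0.5, 0.4, 0.3)),
    seed = 137))
  assoc <- assoc_scan(sim$dosages, sim$phenotype, variants = sim$variants)
  leads <- clump_leads(assoc, sim$dosages, p_threshold = 1e-3)
  # independent oracle: plain greedy loop over the significant set
  sig <- assoc[!is.na(assoc$p) & assoc$p < 1e-3, ]
  sig <- sig[order(sig$p, sig$chr, sig$pos), ]
  oracle <- character(0)
  ids <- sig$id
  while (length(ids)) {
    oracle <- c(oracle, ids[1])
    keep <- vapply(ids[-1], function(v) {
      cor(sim$dosages[, ids[1]], sim$dosages[, v])^2 < 0.1
    }, logical(1))
    ids <- ids[-1][keep]
  }
  expect_identical(leads, oracle)
  # no pair of retained leads shares r^2 >= 0.1
  if (length(leads) > 1) {
    r2 <- cor(sim$dosages[, leads])^2
    expect_lt(max(r2[upper.tri(r2)]), 0.1)
  }
})

test_that("clump_leads handles no-LD, perfect-LD and empty inputs", {
  set.seed(139)
  g <- matrix(rbinom(600, 2, 0.4), 100, 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  assoc <- data.frame(id = colnames(g), chr = 1, pos = 1:6 * 100,
                      p = c(1e-6, 1e-5, 1e-4, 0.5, 1e-3, 0.2))
  # orthogonal dosages: every significant variant is a lead
  leads <- clump_leads(assoc, g, p_threshold = 0.01, r2_threshold = 1)
  expect_setequal(leads, c("v1", "v2", "v3", "v5"))
  # duplicated variant: one lead, smaller p wins
  g2 <- cbind(a = g[, 1], b = g[, 1])
  assoc2 <- data.frame(id = c("a", "b"), chr = 1, pos = c(100, 200),
                       p = c(1e-4, 1e-6))
  expect_identical(clump_leads(assoc2, g2, 0.01), "b")
  # tie in p: earlier position wins
  assoc2$p <- c(1e-6, 1e-6)
  expect_identical(clump_leads(assoc2, g2, 0.01), "a")
  expect_identical(clump_leads(assoc2, g2, 1e-10), character(0))
})

test_that("map_snps_to_genes applies the inclusive 10 kb window", {
  genes <- data.frame(gene = c("G1", "G2"), chr = c(1L, 1L),
                      start = c(50000L, 200000L), end = c(60000L, 210000L))
  leads <- data.frame(id = c("in", "edge", "out", "wrongchr"),
                      chr = c(1L, 1L, 1L, 2L),
                      pos = c(55000L, 40000L, 39999L, 55000L))
  hits <- map_snps_to_genes(leads, genes, window = 10000L)
  expect_setequal(hits$id, c("in", "edge"))
  expect_equal(hits$distance[hits$id == "in"], 0L)
  expect_equal(hits$distance[hits$id == "edge"], 10000L)
  expect_error(map_snps_to_genes(leads,
                                 data.frame(gene = "g", chr = 1,
                                            start = 10, end = 5)),
               "malformed")
})

test_that("block_size 1 keeps every significant SNP as a lead", {
  sim <- simulate_genotypes(genotype_spec(
    n_subjects = 800, n_snps = 15, block_size = 1, within_block_r = 0,
    causal = data.frame(snp = c(3, 9), effect = c(0.5, 0.5)), seed = 149))
  assoc <- assoc_scan(sim$dosages, sim$phenotype, variants = sim$variants)
  sig <- assoc$id[!is.na(assoc$p) & assoc$p < 1e-4]
  leads <- clump_leads(assoc, sim$dosages, p_threshold = 1e-4)
  expect_setequal(leads, sig)
})
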