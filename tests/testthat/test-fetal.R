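test_that("zscore_by_timepoint standardizes each (gene, timepoint) slice", {
  sim <- simulate_expression(expression_spec(n_genes = 6L, modules = NULL,
                                             seed = 151L))
  norm <- zscore_by_timepoint(sim$cube)
  key <- interaction(norm$gene, norm$timepoint)
  mus <- tapply(norm$value, key, mean)
  sds <- tapply(norm$value, key, sd)
  expect_equal(max(abs(mus)), 0, tolerance = 1e-10)
  expect_equal(max(abs(sds - 1)), 0, tolerance = 1e-10)
  # brute-force slice oracle
  g <- sim$cube[sim$cube$gene == "gene_0001" &
                  sim$cube$timepoint == "16pcw", ]
  oracle <- (g$value - mean(g$value)) / sd(g$value)
  got <- norm[norm$gene == "gene_0001" & norm$timepoint == "16pcw", ]
  expect_equal(got$value, oracle, tolerance = 1e-12)
  # per-(gene, timepoint) constants vanish
  shifted <- sim$cube
  shifted$value <- shifted$value +
    ifelse(shifted$timepoint == "16pcw", 5, -2) *
    as.integer(factor(shifted$gene))
  expect_equal(zscore_by_timepoint(shifted)$value, norm$value,
               tolerance = 1e-10)
  const <- sim$cube
  const$value[const$gene == "gene_0002" & const$timepoint == "21pcw"] <- 3
  expect_error(zscore_by_timepoint(const), "constant expression slice")
})

test_that("flatten_profiles enumerates cells timepoint-major", {
  cube <- expand.grid(region = c("r1", "r2"), layer = c("l1", "l2"),
                      timepoint = c("t1", "t2"), gene = c("g1", "g2"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cube$value <- seq_len(nrow(cube))
  m <- flatten_profiles(cube, regions = c("r1", "r2"),
                        layers = c("l1", "l2"), timepoints = c("t1", "t2"))
  expect_equal(colnames(m),
               c("t1|l1|r1", "t1|l1|r2", "t1|l2|r1", "t1|l2|r2",
                 "t2|l1|r1", "t2|l1|r2", "t2|l2|r1", "t2|l2|r2"))
  for (i in seq_len(nrow(cube))) {
    expect_equal(m[cube$gene[i],
                   paste(cube$timepoint[i], cube$layer[i], cube$region[i],
                         sep = "|")],
                 cube$value[i], ignore_attr = TRUE)
  }
  # round trip and header parse-back
  back <- unflatten_profiles(m)
  m2 <- flatten_profiles(back, regions = c("r1", "r2"),
                         layers = c("l1", "l2"), timepoints = c("t1", "t2"))
  expect_identical(m, m2)
  parsed <- strsplit(colnames(m), "|", fixed = TRUE)
  expect_true(all(vapply(parsed, `[`, "", 1) %in% c("t1", "t2")))
  expect_true(all(vapply(parsed, `[`, "", 2) %in% c("l1", "l2")))
})

test_that("kmeans_sweep is deterministic with non-increasing ratio", {
  sim <- simulate_expression(expression_spec(seed = 157L))
  prof <- flatten_profiles(zscore_by_timepoint(sim$cube))
  s1 <- kmeans_sweep(prof, k_max = 8L, restarts = 50L, seed = 157L)
  s2 <- kmeans_sweep(prof, k_max = 8L, restarts = 50L, seed = 157L)
  expect_identical(s1, s2)
  # at a high restart count the best-of-restarts ratio curve is monotone
  expect_true(all(diff(s1$ratio) <= 1e-8))
  # two far-separated clouds: k = 2 ratio is tiny
  set.seed(157)
  clouds <- rbind(matrix(rnorm(100, 0, 0.1), 10, 10),
                  matrix(rnorm(100, 50, 0.1), 10, 10))
  rownames(clouds) <- paste0("p", 1:20)
  sw <- kmeans_sweep(clouds, k_max = 4L, restarts = 10L, seed = 1L)
  expect_lt(sw$ratio[sw$k == 2], 0.01)
})

test_that("elbow_select maximizes discrete curvature", {
  expect_equal(elbow_select(list(k = 2:5, ratio = c(1.0, 0.2, 0.18, 0.17))),
               3)
  # by hand: d2(3) = 1.0 - 0.4 + 0.18 = 0.78; d2(4) = 0.2 - 0.36 + 0.17
  expect_warning(k <- elbow_select(list(k = 2:6,
                                        ratio = c(1, 0.8, 0.6, 0.4, 0.2))),
                 "zero curvature")
  expect_equal(k, 2)
  # ties break toward the smallest k
  expect_equal(elbow_select(list(k = 2:6, ratio = c(1, 0.5, 0.25, 0, 0))), 3)
})

test_that("module_prototypes weights members by positive co-expression", {
  set.seed(163)
  prof <- matrix(rnorm(10 * 16), 10, 16,
                 dimnames = list(paste0("g", 1:10), NULL))
  assign <- stats::setNames(rep(c(1, 2), each = 5), rownames(prof))
  out <- module_prototypes(prof, assign)
  # brute-force oracle for module 1
  pm <- prof[1:5, ]
  cc <- cor(t(pm)); diag(cc) <- 0; cc <- pmax(cc, 0)
  deg <- rowSums(cc)
  oracle <- colSums(pm * (deg / sum(deg)))
  expect_equal(out$prototypes["1", ], oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(out$degrees[1:5], deg, tolerance = 1e-12,
               ignore_attr = TRUE)
  # identical profiles: prototype equals the profile, equal degrees
  prof2 <- prof
  prof2[6:10, ] <- rep(prof[6, ], each = 5)
  out2 <- module_prototypes(prof2, assign)
  expect_equal(out2$prototypes["2", ], prof2[6, ], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(length(unique(round(out2$degrees[6:10], 8))), 1L)
  # two-gene module: symmetry makes the prototype a plain average
  assign3 <- stats::setNames(c(1, 1, rep(2, 8)), rownames(prof))
  out3 <- module_prototypes(prof, assign3)
  expect_equal(out3$prototypes["1", ], colMeans(prof[1:2, ]),
               tolerance = 1e-10, ignore_attr = TRUE)
  # permuting gene order within a module leaves prototypes unchanged
  perm <- c(5:1, 6:10)
  out4 <- module_prototypes(prof[perm, ], assign[perm])
  expect_equal(out4$prototypes, out$prototypes, tolerance = 1e-12)
})

test_that("coexpression_ranking orders genes by prototype similarity", {
  set.seed(167)
  prof <- matrix(rnorm(8 * 20), 8, 20,
                 dimnames = list(paste0("g", 1:8), NULL))
  proto <- prof[1, ] * 2 + 1   # affine copy of g1
  prof <- rbind(prof, anti = -proto)
  rk <- coexpression_ranking(proto, prof)
  expect_equal(rk$gene[1], "g1")
  expect_equal(rk$score[1], 1, tolerance = 1e-12)
  expect_equal(rk$gene[nrow(rk)], "anti")
  expect_equal(rk$score[nrow(rk)], -1, tolerance = 1e-12)
  # constant profiles are scored NA and placed last
  prof2 <- rbind(prof, flat = rep(2, 20))
  rk2 <- coexpression_ranking(proto, prof2)
  expect_equal(rk2$gene[nrow(rk2)], "flat")
  expect_true(is.na(rk2$score[nrow(rk2)]))
  expect_error(coexpression_ranking(rep(1, 20), prof), "constant prototype")
})

test_that("gsea ES matches the exhaustive KS oracle at weight 0", {
  scores <- stats::setNames(seq(5, -4, length.out = 10), paste0("g", 1:10))
  set3 <- c("g2", "g5", "g9")
  # brute force: running sum with +1/3 at hits, -1/7 at misses
  inc <- ifelse(names(sort(scores, decreasing = TRUE)) %in% set3,
                1 / 3, -1 / 7)
  running <- cumsum(inc)
  oracle <- running[which.max(abs(running))]
  es <- sulcnet:::.gsea_es(sort(scores, decreasing = TRUE),
                           names(sort(scores, decreasing = TRUE)) %in% set3,
                           weight = 0)
  expect_equal(es, oracle, tolerance = 1e-12)
  # antisymmetry under ranking reversal at weight 0
  rev_scores <- stats::setNames(rev(unname(sort(scores, decreasing = TRUE))),
                                rev(names(sort(scores, decreasing = TRUE))))
  es_rev <- sulcnet:::.gsea_es(rev_scores, names(rev_scores) %in% set3, 0)
  expect_equal(abs(es_rev), abs(es), tolerance = 1e-12)
  # a single top-ranked gene at weight 1 attains ES = 1
  es_top <- sulcnet:::.gsea_es(sort(scores, decreasing = TRUE),
                               c(TRUE, rep(FALSE, 9)), weight = 1)
  expect_equal(es_top, 1)
})

test_that("gsea_preranked is calibrated and bounded", {
  set.seed(173)
  scores <- stats::setNames(rnorm(60), paste0("g", 1:60))
  sets <- lapply(1:150, function(i) sample(names(scores), 8))
  names(sets) <- paste0("s", 1:150)
  res <- gsea_preranked(scores, sets, n_perm = 400, seed = 7)
  expect_true(all(abs(res$es) <= 1))
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(res$q >= 0 & res$q <= 1))
  expect_error(gsea_preranked(scores, sets, n_perm = 10), ">= 100")
  expect_error(gsea_preranked(scores, list(tiny = "g1")), "size bounds")
})

test_that("the planted-module pipeline recovers labels and enrichment", {
  spec <- expression_spec(gene_sets = data.frame(
    name = "set_module1", module = 1L, overlap = 0.8, size = 10L),
    seed = 11L)
  sim <- simulate_expression(spec)
  prof <- flatten_profiles(zscore_by_timepoint(sim$cube))
  sw <- kmeans_sweep(prof, k_max = 10L, restarts = 30L, seed = 11L)
  k <- elbow_select(sw)
  expect_equal(k, 3L)
  assign <- sw$assignments[[match(k, sw$k)]]
  ari <- sulcnet:::adjusted_rand_index(assign, sim$truth[names(assign)])
  expect_gte(ari, 0.9)
  proto <- module_prototypes(prof, assign)
  # identify which k-means cluster is planted module 1 / module 3
  pick <- function(mod) {
    names(which.max(table(assign[names(sim$truth)[sim$truth == mod]])))
  }
  rank1 <- coexpression_ranking(proto$prototypes[pick("module_1"), ], prof)
  rank3 <- coexpression_ranking(proto$prototypes[pick("module_3"), ], prof)
  # module-1 members dominate the top of their own ranking
  m1 <- names(sim$truth)[sim$truth == "module_1"]
  expect_gte(sum(rank1$gene[seq_along(m1)] %in% m1), length(m1) - 2)
  g1 <- gsea_preranked(rank1, sim$gene_sets, n_perm = 1000, seed = 1)
  g3 <- gsea_preranked(rank3, sim$gene_sets, n_perm = 1000, seed = 1)
  expect_lt(g1$q[g1$set == "set_module1"], 0.05)
  expect_gt(g3$q[g3$set == "set_module1"], 0.2)
})
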