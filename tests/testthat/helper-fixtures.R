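# shared fixtures, built once per test run and cached

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_env)) {
    assign(name, builder(), .fixture_env)
  }
  get(name, .fixture_env)
}

# a default cohort (100/100, seed 7) with its complexity pipeline output
fx_cohort <- function() fixture("cohort7", function() {
  sim <- simulate_cohort(cohort_spec(seed = 7L))
  cc <- cohort_complexity(sim)
  list(sim = sim, cc = cc)
})

# a small cohort for cheap structural tests
fx_small_cohort <- function() fixture("small_cohort", function() {
  sim <- simulate_cohort(cohort_spec(n_cases = 8L, n_controls = 12L,
                                     seed = 3L))
  list(sim = sim, spns = cohort_spns(sim$phenotypes))
})

fx_annotation <- function() fixture("annotation", default_sulcus_annotation)

fx_classes <- function() {
  ann <- fx_annotation()
  stats::setNames(ann$class, ann$sulcus)
}

fx_parcellation <- function() fixture("parc40", function() {
  simulate_parcellation(40L, seed = 2L)
})

# long value table (subject, sulcus, value) from a complexity result
scores_long <- function(cc) {
  data.frame(subject = cc$scores$subject, sulcus = cc$scores$sulcus,
             value = cc$scores$fisher_z, stringsAsFactors = FALSE)
}

# an exact two-block SPN: +1 within blocks of size n/2, -1 between
two_block_spn <- function(n = 40L, labels = canonical_sulci(n %/% 2L)) {
  half <- n %/% 2L
  block <- rep(c(1, -1), each = half)
  m <- outer(block, block)
  diag(m) <- 1
  dimnames(m) <- list(labels, labels)
  structure(m, class = c("spn", "matrix", "array"))
}
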