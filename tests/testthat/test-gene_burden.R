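test_that("exact test matches the brute-force oracle on all small tables", {
  # exhaustive sweep over every 2x2 table with total <= 30
  total_max <- 30
  mismatches <- 0L
  for (a in 0:total_max) for (b in 0:(total_max - a)) {
    for (c_ in 0:(total_max - a - b)) {
      dmax <- total_max - a - b - c_
      for (d in 0:dmax) {
        p <- fisher_exact_two_sided(a, b, c_, d)
        po <- oracle_fisher_two_sided(a, b, c_, d)
        if (abs(p - po) > 1e-10) mismatches <- mismatches + 1L
      }
    }
  }
  expect_equal(mismatches, 0L)
})

test_that("exact test agrees with stats::fisher.test and printed reference tables", {
  expect_equal(signif(fisher_exact_two_sided(16, 122, 0, 45), 3), 0.0133)
  expect_equal(fisher_exact_two_sided(0, 60, 0, 543), 1.0)
  # frozen oracle value for the truncating carrier table (5,55,0,543)
  expect_equal(fisher_exact_two_sided(5, 55, 0, 543), 8.358489e-06,
               tolerance = 1e-6)
  set.seed(42)
  for (i in 1:50) {
    t <- rpois(4, 20)
    expect_equal(fisher_exact_two_sided(t[1], t[2], t[3], t[4]),
                 fisher.test(matrix(t, 2, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("exact test is invariant under simultaneous row and column swap", {
  set.seed(11)
  for (i in 1:30) {
    t <- rpois(4, 10)
    expect_equal(fisher_exact_two_sided(t[1], t[2], t[3], t[4]),
                 fisher_exact_two_sided(t[4], t[3], t[2], t[1]),
                 tolerance = 1e-12)
  }
})

test_that("adding a tumour carrier against zero control carriers never raises p", {
  for (b0 in c(10, 50)) {
    p_prev <- Inf
    for (a in 0:b0) {
      p <- fisher_exact_two_sided(a, b0 - a, 0, 100)
      expect_lte(p, p_prev + 1e-12)
      p_prev <- p
    }
  }
})

test_that("one-sided alternative gives the upper hypergeometric tail", {
  expect_equal(fisher_exact_two_sided(5, 5, 1, 9, alternative = "greater"),
               fisher.test(matrix(c(5, 5, 1, 9), 2, 2, byrow = TRUE),
                           alternative = "greater")$p.value,
               tolerance = 1e-9)
})

test_that("BH adjustment follows the step-up formula and its invariants", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(3)
  for (i in 1:10) {
    p <- runif(20)
    m <- sample(20:100, 1)
    q <- bh_fdr(p, m)
    expect_equal(q, oracle_bh(p, m), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-12))
    # a second adjustment never lowers a q-value (monotone operator)
    q1 <- bh_fdr(p)
    expect_true(all(bh_fdr(q1) >= q1 - 1e-12))
  }
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(bh_fdr(runif(5) / 2 + 0.1, m = 3), "m must be")
})

test_that("gene contingency counts carriers at the sample level", {
  meta <- make_metadata(60, 543)
  v <- fixture_setd2_variants()
  kept <- filter_cohort(v, "truncating")$kept
  t <- gene_contingency("SETD2", kept, meta)
  expect_equal(unlist(t), c(a = 5, b = 55, c = 0, d = 543))
  # a sample with 3 kept variants in one gene counts once
  v3 <- kept[c(1, 1, 1), ]
  t3 <- gene_contingency("SETD2", v3, meta)
  expect_equal(t3$a, 1L)
  # no variants in the gene
  t0 <- gene_contingency("NOGENE", kept, meta)
  expect_equal(c(t0$a, t0$c), c(0L, 0L))
  # unknown sample errors
  bad <- kept; bad$sample_id[1] <- "ZZZ"
  expect_error(gene_contingency("SETD2", bad, meta), "unknown sample 'ZZZ'")
})

test_that("burden scan is deterministic, sorted, and errors on an empty arm", {
  sim <- simulate_variant_cohort(cohort_sim_spec(
    n_tumor = 30, n_control = 100, n_genes = 60, background_rate = 0.01,
    seed = 5))
  r1 <- run_burden_scan(sim$variants, sim$metadata, "all")
  r2 <- run_burden_scan(sim$variants, sim$metadata, "all")
  expect_identical(r1, r2)
  expect_true(all(diff(r1$p) >= 0))
  expect_equal(r1$rank, seq_len(nrow(r1)))
  expect_true(all(r1$a + r1$b == 30 & r1$c + r1$d == 100))
  expect_true(all(r1$q >= r1$p - 1e-12))
  meta_t <- sim$metadata[sim$metadata$arm == "tumor", ]
  expect_error(run_burden_scan(sim$variants, meta_t, "all"),
               "tumor and one control")
})

test_that("identical per-gene counts give identical q values", {
  meta <- make_metadata(4, 6)
  v <- do.call(rbind, lapply(c("GA", "GB", "GC"), function(g) {
    data.frame(sample_id = c("T001", "C001"), gene = g, chrom = "1",
               pos = 1:2, ref = "A", alt = "T", consequence = "nonsense",
               sift = "unknown", polyphen = "unknown", conserved = TRUE,
               in_population_db = FALSE, in_control_exomes = FALSE,
               stringsAsFactors = FALSE)
  }))
  r <- run_burden_scan(v, meta, "all")
  expect_equal(length(unique(r$q)), 1L)
  expect_equal(r$gene, sort(r$gene))  # tie-break by symbol
})

test_that("null cohorts keep type-I error at or below nominal", {
  # fraction of genes with p < 0.05 under the generator's own null,
  # pooled over replicates; the exact test is conservative
  set.seed(101)
  frac_sig <- replicate(5, {
    sim <- simulate_variant_cohort(cohort_sim_spec(
      n_tumor = 60, n_control = 543, n_genes = 100, background_rate = 1e-3,
      seed = sample.int(1e6, 1)))
    r <- run_burden_scan(sim$variants, sim$metadata, "all")
    if (nrow(r) == 0) 0 else mean(r$p < 0.05)
  })
  expect_lte(mean(frac_sig), 0.05 + 2 * sqrt(0.05 * 0.95 / 500))
})

test_that("an injected driver is recovered at rank 1", {
  sim <- simulate_variant_cohort(cohort_sim_spec(
    n_tumor = 60, n_control = 543, n_genes = 100, background_rate = 1e-3,
    drivers = list(list(gene = 7, rate_multiplier = 100,
                        truncating_fraction = 0.5)),
    seed = 13))
  r <- run_burden_scan(sim$variants, sim$metadata, "all")
  expect_equal(r$gene[1], sim$truth$driver_genes)
})
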