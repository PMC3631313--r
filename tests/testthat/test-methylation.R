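make_bm <- function(n_probes = 20, n_samples = 8, seed = 5) {
  set.seed(seed)
  b <- matrix(runif(n_probes * n_samples), n_probes, n_samples,
              dimnames = list(sprintf("cg%03d", seq_len(n_probes)),
                              sprintf("S%02d", seq_len(n_samples))))
  ann <- data.frame(
    probe_id = rownames(b),
    chrom = sample(c("1", "7", "chrX", "chrY"), n_probes, replace = TRUE,
                   prob = c(0.4, 0.3, 0.2, 0.1)),
    cross_reactive = runif(n_probes) < 0.2,
    snp_maf = ifelse(runif(n_probes) < 0.5, NA, runif(n_probes, 0, 0.1)),
    stringsAsFactors = FALSE)
  beta_matrix(b, ann)
}

test_that("probe filtering applies the blacklist predicate exactly", {
  bm <- make_bm(seed = 5)
  ann <- bm$probe_annotations
  kept <- filter_probes(bm)
  # hand-computed predicate on the same annotations
  expect_kept <- !ann$cross_reactive &
    (is.na(ann$snp_maf) | ann$snp_maf < 2 / 120) &
    !(ann$chrom %in% c("chrX", "chrY", "X", "Y"))
  expect_equal(rownames(kept$beta), ann$probe_id[expect_kept])
  # sex-chromosome probes never survive
  expect_false(any(kept$probe_annotations$chrom %in% c("chrX", "chrY")))
  # idempotence
  expect_equal(filter_probes(kept)$beta, kept$beta)
  # an autosomal clean probe with no catalogued SNP survives
  one <- beta_matrix(bm$beta[1, , drop = FALSE],
                     data.frame(probe_id = rownames(bm$beta)[1], chrom = "1",
                                cross_reactive = FALSE, snp_maf = NA_real_))
  expect_equal(nrow(filter_probes(one)$beta), 1L)
  expect_error(filter_probes(beta_matrix(bm$beta)), "annotations")
})

test_that("top-variable selection ranks by SD with deterministic tie-break", {
  set.seed(8)
  sds <- c(0.30, 0.25, 0.25, 0.10, 0.02, 0)
  b <- t(sapply(sds, function(s) 0.5 + s * scale(rnorm(10))[, 1]))
  b <- pmin(pmax(b, 0), 1)
  dimnames(b) <- list(c("cgB", "cgA", "cgC", "cgD", "cgE", "cgF"),
                      sprintf("S%02d", 1:10))
  bm <- beta_matrix(b)
  # oracle: order by (-sd, probe_id)
  true_sd <- apply(b, 1, sd)
  oracle <- rownames(b)[order(-true_sd, rownames(b))]
  sel <- select_top_variable(bm, 4)
  expect_equal(rownames(sel$beta), oracle[1:4])
  # constant probe ranks last: n = 1 picks a varying probe
  two <- beta_matrix(b[c("cgF", "cgB"), ])
  expect_equal(rownames(select_top_variable(two, 1)$beta), "cgB")
  # n = probe count is the identity subset; larger n warns
  expect_equal(nrow(select_top_variable(bm, 6)$beta), 6L)
  expect_warning(select_top_variable(bm, 99), "only 6")
  expect_error(select_top_variable(beta_matrix(b[, 1, drop = FALSE]), 2),
               "2 samples")
})

test_that("average-linkage Pearson clustering matches a brute-force oracle", {
  set.seed(12)
  b <- matrix(runif(5 * 30), 30, 5,
              dimnames = list(sprintf("cg%02d", 1:30), sprintf("S%d", 1:5)))
  res <- hcluster_average_pearson(beta_matrix(b), 2)
  d <- 1 - cor(b)
  merges <- oracle_upgma_merges(as.dist(d))
  # compare merge member-sets at each agglomeration step
  hc <- res$tree
  members <- function(node) {
    # expand hclust merge row to leaf set
    get <- function(x) if (x < 0) -x else members_list[[x]]
    members_list <<- c(members_list,
                       list(sort(c(get(hc$merge[node, 1]),
                                   get(hc$merge[node, 2])))))
    members_list[[length(members_list)]]
  }
  members_list <- list()
  got <- lapply(seq_len(nrow(hc$merge)), members)
  expect_equal(got, merges)
})

test_that("Pearson distance groups affine-transformed profiles together", {
  set.seed(13)
  base1 <- runif(40); base2 <- runif(40)
  b <- cbind(S1 = base1, S2 = 0.5 * base1 + 0.2, S3 = 0.9 * base1 + 0.05,
             S4 = base2, S5 = 0.7 * base2 + 0.1)
  b <- pmin(pmax(b, 0), 1)
  rownames(b) <- sprintf("cg%02d", 1:40)
  res <- hcluster_average_pearson(beta_matrix(b), 2)
  expect_equal(unname(res$labels[c("S1", "S2", "S3")]), rep(1L, 3) * res$labels[["S1"]])
  expect_equal(length(unique(res$labels[c("S4", "S5")])), 1L)
  expect_false(res$labels[["S1"]] == res$labels[["S4"]])
  # duplicated sample has distance zero and merges first (use noisy columns
  # so the duplicate pair is the unique zero distance)
  set.seed(14)
  bn <- matrix(runif(40 * 4), 40, 4, dimnames = list(rownames(b),
                                                     paste0("S", 1:4)))
  bn <- cbind(bn, S5 = bn[, "S1"])
  res2 <- hcluster_average_pearson(beta_matrix(bn), 2)
  first <- sort(abs(res2$tree$merge[1, ]))
  expect_equal(first, sort(match(c("S1", "S5"), colnames(bn))))
  # zero-variance sample is named in the error
  b3 <- b; b3[, "S2"] <- 0.5
  expect_error(hcluster_average_pearson(beta_matrix(b3), 2), "S2")
})

test_that("consensus with B = 1 and full resampling is one k-means co-membership", {
  sim <- simulate_beta_matrix(beta_sim_spec(n_samples = 12, n_probes = 40,
                                            k_true = 2,
                                            n_informative_probes = 20,
                                            shift = 0.3, noise_sd = 0.02,
                                            seed = 3))
  cr <- consensus_kmeans(sim$bm, k_range = 2:3, B = 1, item_frac = 1.0,
                         seed = 5)
  for (k in c("2", "3")) {
    m <- cr$consensus[[k]]
    expect_true(all(m %in% c(0, 1)))
    expect_true(isSymmetric(m))
    expect_equal(diag(m), setNames(rep(1, 12), rownames(m)))
  }
})

test_that("well-separated clusters give near-binary consensus and dominant k = 2", {
  sim <- simulate_beta_matrix(beta_sim_spec(n_samples = 20, n_probes = 100,
                                            k_true = 2,
                                            n_informative_probes = 40,
                                            shift = 0.4, noise_sd = 0.02,
                                            seed = 1))
  cr <- consensus_kmeans(sim$bm, k_range = 2:4, B = 60, seed = 1)
  m2 <- cr$consensus[["2"]]
  expect_true(all(pmin(m2, 1 - m2) <= 0.02))
  # in the separated limit the k = 2 delta-area dominates all later gains
  expect_equal(which.max(cr$delta), c("2" = 1L))
  # k = 2 labels recover the planted split exactly
  agree <- max(sum(cr$labels[["2"]] == sim$labels),
               sum(cr$labels[["2"]] != sim$labels))
  expect_equal(agree, 20)
})

test_that("consensus matrices satisfy their structural invariants and reproduce under a seed", {
  sim <- simulate_beta_matrix(beta_sim_spec(n_samples = 15, n_probes = 60,
                                            k_true = 3,
                                            n_informative_probes = 30,
                                            seed = 2))
  cr1 <- consensus_kmeans(sim$bm, k_range = 2:4, B = 40, seed = 9)
  cr2 <- consensus_kmeans(sim$bm, k_range = 2:4, B = 40, seed = 9)
  expect_identical(cr1, cr2)
  for (k in names(cr1$consensus)) {
    m <- cr1$consensus[[k]]
    expect_true(isSymmetric(m))
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(unname(diag(m)), rep(1, nrow(m)))
  }
  expect_error(consensus_kmeans(sim$bm, k_range = 2:20, B = 5, seed = 1),
               "samples")
})

test_that("CDF areas and deltas match hand arithmetic on tiny consensus matrices", {
  # all-zero off-diagonal: CDF jumps to 1 at 0, trapezoid area = 1 - 1/200
  # (the first grid cell averages CDF(0)=1 with CDF(0.01)=1 => full area 1)
  cons0 <- diag(4); dimnames(cons0) <- list(paste0("S", 1:4), paste0("S", 1:4))
  cr <- structure(list(k_values = c(2L, 3L),
                       consensus = list("2" = cons0, "3" = cons0)),
                  class = "consensus_result")
  out <- cdf_delta_area(cr)
  expect_equal(unname(out$A[1]), 1.0)
  expect_equal(unname(out$delta[2]), 0)
  expect_equal(out$selected_k, 2L)

  # hand-built: upper triangle of m2 = (0, 0.5, 1, 0.5, 1, 0.5)
  m2 <- matrix(1, 4, 4)
  m2[upper.tri(m2)] <- c(0, 0.5, 1, 0.5, 1, 0.5)
  m2[lower.tri(m2)] <- t(m2)[lower.tri(m2)]
  diag(m2) <- 1
  dimnames(m2) <- dimnames(cons0)
  # CDF: 1/6 on [0, 0.5), 4/6 on [0.5, 1), 1 at 1
  # trapezoid area on the 101-point grid:
  #   cell [0,0.01]: mean(1/6,1/6)*0.01 ... analytic sum below
  grid <- seq(0, 1, length.out = 101)
  cdfv <- sapply(grid, function(t) mean(c(0, 0.5, 1, 0.5, 1, 0.5) <= t))
  A_hand <- sum(diff(grid) * (cdfv[-1] + cdfv[-101]) / 2)
  m3 <- matrix(1, 4, 4)
  m3[upper.tri(m3)] <- c(0, 0, 1, 0, 1, 1)
  m3[lower.tri(m3)] <- t(m3)[lower.tri(m3)]
  dimnames(m3) <- dimnames(cons0)
  cr2 <- structure(list(k_values = c(2L, 3L),
                        consensus = list("2" = m2, "3" = m3)),
                   class = "consensus_result")
  out2 <- cdf_delta_area(cr2)
  expect_equal(unname(out2$A[1]), A_hand, tolerance = 1e-12)
  cdf3 <- sapply(grid, function(t) mean(c(0, 0, 1, 0, 1, 1) <= t))
  A3 <- sum(diff(grid) * (cdf3[-1] + cdf3[-101]) / 2)
  expect_equal(unname(out2$A[2]), A3, tolerance = 1e-12)
  expect_equal(unname(out2$delta[2]), (A3 - A_hand) / A_hand, tolerance = 1e-12)
  # a more binary consensus never has a smaller area
  expect_gte(out2$A[2], out2$A[1])
})

test_that("quantile normalisation equalises per-sample distributions", {
  set.seed(6)
  b <- matrix(runif(200), 50, 4,
              dimnames = list(sprintf("cg%02d", 1:50), paste0("S", 1:4)))
  qn <- quantile_normalize_betas(beta_matrix(b))
  sorted <- apply(qn$beta, 2, sort)
  expect_equal(sorted[, 1], sorted[, 2], tolerance = 1e-12)
  expect_equal(sorted[, 1], sorted[, 4], tolerance = 1e-12)
})
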