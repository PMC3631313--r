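# Independent oracles: brute-force implementations kept deliberately naive
# so they share no code with the package's fast paths.

# Two-sided exact p by exhaustive enumeration using log-factorials only.
oracle_fisher_two_sided <- function(a, b, c, d) {
  lf <- lfactorial
  logp_table <- function(a2, b2, c2, d2) {
    lf(a2 + b2) + lf(c2 + d2) + lf(a2 + c2) + lf(b2 + d2) -
      lf(a2 + b2 + c2 + d2) - lf(a2) - lf(b2) - lf(c2) - lf(d2)
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  p_obs <- exp(logp_table(a, b, c, d))
  total <- 0
  for (a2 in lo:hi) {
    p2 <- exp(logp_table(a2, r1 - a2, c1 - a2, r2 - (c1 - a2)))
    if (p2 <= p_obs * (1 + 1e-7)) total <- total + p2
  }
  min(1, total)
}

# Step-up BH by literal application of the defining formula.
oracle_bh <- function(p, m = length(p)) {
  ord <- order(p)
  ps <- p[ord]
  n <- length(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(ps[i:n] * m / (i:n)))
  }
  out <- numeric(n)
  out[ord] <- q
  out
}

# O(n^3) average-linkage agglomeration by explicit pairwise-mean updates.
# Returns the sequence of merged cluster member-sets (as sorted id vectors).
oracle_upgma_merges <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  merges <- list()
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    best <- c(NA, NA); best_d <- Inf
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      dist_ij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dist_ij < best_d - 1e-12) {
        best_d <- dist_ij; best <- c(i, j)
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# Welch t statistic and p from the closed form.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

tmpfile <- function(ext = ".tsv") tempfile(fileext = ext)

# Minimal valid variant table for round-trip / predicate tests.
make_variants <- function(n = 6, seed = 1) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("S%02d", sample(1:20, n, replace = TRUE)),
    gene = sample(c("GENE1", "GENE2", "GENE3"), n, replace = TRUE),
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = sample.int(1e6, n),
    ref = "A", alt = "G",
    consequence = sample(c("missense", "nonsense", "frameshift", "splice_site",
                           "synonymous", "other"), n, replace = TRUE),
    sift = sample(c("damaging", "tolerated", "unknown"), n, replace = TRUE),
    polyphen = sample(c("damaging", "benign", "unknown"), n, replace = TRUE),
    conserved = sample(c(TRUE, FALSE), n, replace = TRUE),
    in_population_db = sample(c(TRUE, FALSE), n, replace = TRUE),
    in_control_exomes = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

make_metadata <- function(n_tumor = 60, n_control = 543) {
  data.frame(
    sample_id = c(sprintf("T%03d", seq_len(n_tumor)),
                  sprintf("C%03d", seq_len(n_control))),
    arm = c(rep("tumor", n_tumor), rep("control", n_control)),
    grade = c(rep("IV", n_tumor), rep(NA_character_, n_control)),
    age_group = NA_character_, age_years = NA_real_,
    location = NA_character_, stringsAsFactors = FALSE)
}

extdata <- function(f) system.file("extdata", f, package = "glioburden")
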