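#' Filter methylation probes
#'
#' Applies the standard 450K-style probe blacklist: drop probes flagged as
#' cross-reactive (>= 90\% sequence similarity to multiple genomic
#' locations), probes with a common sequence variant in the probe binding
#' region (minor allele frequency >= 2/120; probes with no catalogued SNP,
#' \code{snp_maf = NA}, are kept), and probes on the sex chromosomes. The
#' rule is a predicate over the supplied annotation table, so the surviving
#' probe count depends on the manifest and SNP build in use.
#'
#' @param bm Annotated [beta_matrix()].
#' @param maf_threshold SNP minor-allele-frequency cutoff (default 2/120).
#' @return The filtered \code{beta_matrix}.
#' @export
filter_probes <- function(bm, maf_threshold = 2 / 120) {
  stopifnot(inherits(bm, "beta_matrix"))
  ann <- bm$probe_annotations
  if (is.null(ann)) stop("filter_probes needs probe annotations", call. = FALSE)
  chrom <- sub("^chr", "", ann$chrom)
  keep <- !ann$cross_reactive &
    (is.na(ann$snp_maf) | ann$snp_maf < maf_threshold) &
    !(chrom %in% c("X", "Y"))
  beta_matrix(bm$beta[keep, , drop = FALSE], ann[keep, , drop = FALSE])
}

#' Select the most variable probes
#'
#' Ranks probes by their across-sample standard deviation (denominator
#' n - 1) and keeps the top \code{n}, breaking SD ties by probe id in
#' lexicographic order so the selection is deterministic. Requesting more
#' probes than exist returns all of them with a warning.
#'
#' @param bm A [beta_matrix()] with at least 2 samples.
#' @param n Number of probes to keep (default 8000, the conventional choice
#'   for whole-array clustering).
#' @return The subset \code{beta_matrix}, probes in rank order.
#' @export
select_top_variable <- function(bm, n = 8000) {
  stopifnot(inherits(bm, "beta_matrix"), n >= 1)
  if (ncol(bm$beta) < 2L) {
    stop("standard deviation needs at least 2 samples", call. = FALSE)
  }
  sds <- apply(bm$beta, 1L, stats::sd)
  ord <- order(-sds, rownames(bm$beta))
  if (n > nrow(bm$beta)) {
    warning(sprintf("requested %d probes but only %d available; returning all",
                    n, nrow(bm$beta)))
    n <- nrow(bm$beta)
  }
  keep <- ord[seq_len(n)]
  beta_matrix(bm$beta[keep, , drop = FALSE],
              if (is.null(bm$probe_annotations)) NULL else
                bm$probe_annotations[keep, , drop = FALSE])
}

#' Hierarchical clustering of samples (average linkage, Pearson distance)
#'
#' Unsupervised hierarchical clustering of sample columns with distance
#' \eqn{d(i,j) = 1 - r(i,j)} (Pearson correlation of beta profiles) and
#' UPGMA/average linkage. Correlation distance makes the grouping invariant
#' to positive affine transforms of a sample's profile, which is the desired
#' behaviour for methylation arrays where per-sample intensity scaling is a
#' nuisance.
#'
#' @param bm A [beta_matrix()] (or plain probes-by-samples matrix).
#' @param n_clusters Number of clusters to cut the tree into.
#' @return List with \code{labels} (named integer vector) and \code{tree}
#'   (the \code{hclust} object).
#' @export
hcluster_average_pearson <- function(bm, n_clusters) {
  beta <- if (inherits(bm, "beta_matrix")) bm$beta else bm
  if (ncol(beta) < 2L) stop("need at least 2 samples", call. = FALSE)
  sds <- apply(beta, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance sample: ", colnames(beta)[which(sds == 0)[1L]],
         call. = FALSE)
  }
  d <- stats::as.dist(1 - stats::cor(beta))
  tree <- stats::hclust(d, method = "average")
  list(labels = stats::cutree(tree, k = n_clusters), tree = tree)
}

# k-means++ seeding: spread the initial centers with probability
# proportional to squared distance from the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  if (k > 1L) {
    d2 <- colSums((t(x) - centers[1L, ])^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      i <- sample.int(n, 1L, prob = prob)
      centers[j, ] <- x[i, ]
      d2 <- pmin(d2, colSums((t(x) - centers[j, ])^2))
    }
  }
  centers
}

kmeans_once <- function(x, k) {
  for (attempt in 1:5) {
    centers <- kmeanspp_centers(x, k)
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centers, iter.max = 100L,
                                     nstart = 1L, algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(km)) return(km$cluster)
  }
  stop("k-means failed to produce k non-empty clusters", call. = FALSE)
}

#' Consensus k-means clustering of samples
#'
#' Resampling-based consensus clustering: for each candidate k, \code{B}
#' rounds each draw \code{ceiling(item_frac * n)} samples without
#' replacement, run one k-means (Euclidean distance on the probe vectors,
#' k-means++ seeding, Lloyd iterations capped at 100, one restart per round)
#' on the subsample, and record co-cluster events. The consensus matrix entry
#' for a sample pair is the fraction of rounds in which they were assigned to
#' the same cluster among rounds in which both were drawn; the diagonal is 1.
#' Final per-k labels come from average-linkage hierarchical clustering of
#' \code{1 - consensus} cut at k. Stable structure shows as near-binary
#' consensus entries.
#'
#' @param bm A [beta_matrix()] or probes-by-samples matrix.
#' @param k_range Candidate cluster numbers (default 2:10).
#' @param B Resampling rounds per k (default 1000).
#' @param item_frac Fraction of samples drawn per round (default 0.8).
#' @param seed Integer seed; the run is fully reproducible given it.
#' @param delta_threshold Passed to [cdf_delta_area()] for the advisory k.
#' @return A \code{consensus_result}: list with \code{k_values},
#'   \code{consensus} (named list of matrices), \code{labels} (named list of
#'   integer vectors), \code{A}, \code{delta}, \code{selected_k}.
#' @export
consensus_kmeans <- function(bm, k_range = 2:10, B = 1000, item_frac = 0.8,
                             seed = 1L, delta_threshold = 0.025) {
  beta <- if (inherits(bm, "beta_matrix")) bm$beta else bm
  n <- ncol(beta)
  if (n < max(k_range) + 1L) {
    stop("need at least max(k_range) + 1 samples", call. = FALSE)
  }
  stopifnot(item_frac > 0, item_frac <= 1)
  x <- t(beta)  # samples as points in probe space
  ids <- colnames(beta)
  set.seed(seed)

  n_draw <- ceiling(item_frac * n)
  consensus <- list()
  labels <- list()
  for (k in k_range) {
    co <- matrix(0, n, n)
    both <- matrix(0, n, n)
    for (b in seq_len(B)) {
      idx <- if (n_draw == n) seq_len(n) else sort(sample.int(n, n_draw))
      cl <- kmeans_once(x[idx, , drop = FALSE], k)
      same <- outer(cl, cl, "==") * 1
      co[idx, idx] <- co[idx, idx] + same
      both[idx, idx] <- both[idx, idx] + 1
    }
    off <- upper.tri(both)
    if (any(both[off] == 0)) {
      stop("some sample pairs were never co-sampled; increase B",
           call. = FALSE)
    }
    cons <- co / both
    diag(cons) <- 1
    dimnames(cons) <- list(ids, ids)
    consensus[[as.character(k)]] <- cons
    tree <- stats::hclust(stats::as.dist(1 - cons), method = "average")
    labels[[as.character(k)]] <- stats::cutree(tree, k = k)
  }
  res <- structure(list(k_values = as.integer(k_range), consensus = consensus,
                        labels = labels, A = NULL, delta = NULL,
                        selected_k = NULL),
                   class = "consensus_result")
  sel <- cdf_delta_area(res, delta_threshold = delta_threshold)
  res$A <- sel$A
  res$delta <- sel$delta
  res$selected_k <- sel$selected_k
  res
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: k in {%s}, %d samples, selected k = %s\n",
              paste(x$k_values, collapse = ","),
              nrow(x$consensus[[1L]]),
              x$selected_k %||% "?"))
  invisible(x)
}

#' CDF area and delta-area model selection
#'
#' For each k, forms the empirical CDF of the upper-triangle consensus
#' values on a fixed grid of 101 points spanning \eqn{[0,1]} and takes the
#' trapezoidal area under it, \eqn{A(k)}. The relative area increase
#' \eqn{\Delta(k)} is \eqn{A(2)} at the smallest k and
#' \eqn{(A(k) - A(k-1)) / A(k-1)} beyond; a k whose consensus is more
#' binary has a CDF that rises earlier and a larger area. The advisory
#' \code{selected_k} is the smallest k after which the relative gain drops
#' below \code{delta_threshold} (i.e. the k preceding the first
#' sub-threshold delta), or the largest k tried when the gain never
#' flattens.
#'
#' @param cr A \code{consensus_result} (only \code{consensus} and
#'   \code{k_values} are used).
#' @param delta_threshold Relative-gain cutoff (default 0.025).
#' @return List with \code{A}, \code{delta} (both named by k) and
#'   \code{selected_k}.
#' @export
cdf_delta_area <- function(cr, delta_threshold = 0.025) {
  ks <- cr$k_values
  if (length(ks) < 2L) stop("need at least 2 k values", call. = FALSE)
  grid <- seq(0, 1, length.out = 101L)
  A <- vapply(as.character(ks), function(k) {
    m <- cr$consensus[[k]]
    vals <- m[upper.tri(m)]
    cdf <- vapply(grid, function(t) mean(vals <= t), numeric(1))
    sum(diff(grid) * (cdf[-1L] + cdf[-length(cdf)]) / 2)
  }, numeric(1))
  delta <- numeric(length(ks))
  delta[1L] <- A[1L]
  for (i in seq_along(ks)[-1L]) delta[i] <- (A[i] - A[i - 1L]) / A[i - 1L]
  names(delta) <- names(A)
  below <- which(delta[-1L] < delta_threshold)
  selected_k <- if (length(below)) ks[min(below)] else ks[length(ks)]
  list(A = A, delta = delta, selected_k = as.integer(selected_k))
}

#' Per-sample quantile normalisation of beta values
#'
#' Maps every sample column onto the mean empirical distribution across
#' samples (classical quantile normalisation). This is a generic
#' distribution-matching helper and is NOT the SWAN within-array method used
#' for Infinium type-I/type-II probe correction; use it only when betas
#' arrive without any normalisation at all.
#'
#' @param bm A [beta_matrix()].
#' @return A \code{beta_matrix} with quantile-normalised columns.
#' @export
quantile_normalize_betas <- function(bm) {
  stopifnot(inherits(bm, "beta_matrix"))
  b <- bm$beta
  ranked <- apply(b, 2L, sort)
  ref <- rowMeans(ranked)
  ref_at <- stats::approxfun(seq_along(ref), ref, rule = 2)
  out <- apply(b, 2L, function(col) ref_at(rank(col, ties.method = "average")))
  dimnames(out) <- dimnames(b)
  beta_matrix(out, bm$probe_annotations)
}
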