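#' Per-gene carrier contingency table
#'
#' Builds the 2x2 case-control table for one gene: rows are cohort arm
#' (tumour, control), columns carrier / non-carrier. Carrier counting is at
#' the sample level — a sample with several kept variants in the gene counts
#' once — which keeps the table margins equal to the cohort sizes.
#'
#' @param gene Gene symbol.
#' @param kept_variants Filtered variant \code{data.frame} (see
#'   [filter_cohort()]).
#' @param metadata Sample metadata covering every \code{sample_id} in
#'   \code{kept_variants}.
#' @return A list with integer fields \code{a} (tumour carriers), \code{b}
#'   (tumour non-carriers), \code{c} (control carriers), \code{d} (control
#'   non-carriers).
#' @export
gene_contingency <- function(gene, kept_variants, metadata) {
  unknown <- setdiff(kept_variants$sample_id, metadata$sample_id)
  if (length(unknown)) {
    stop("variant references unknown sample '", unknown[1L], "'",
         call. = FALSE)
  }
  carriers <- unique(kept_variants$sample_id[kept_variants$gene == gene])
  arm <- metadata$arm[match(carriers, metadata$sample_id)]
  n_tumor <- sum(metadata$arm == "tumor")
  n_control <- sum(metadata$arm == "control")
  a <- sum(arm == "tumor")
  c_ <- sum(arm == "control")
  list(a = a, b = n_tumor - a, c = c_, d = n_control - c_)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value by direct hypergeometric enumeration with the
#' point-probability (minimum-likelihood) two-sided definition: holding the
#' table margins fixed, the p-value sums the probabilities of all tables
#' whose point probability does not exceed that of the observed table, with
#' a relative slack of 1e-7 guarding floating-point ties. A degenerate table
#' (an all-zero row or column) admits a single configuration and returns
#' \code{p = 1}.
#'
#' @param a,b,c,d Non-negative integer cells (rows = groups, columns =
#'   carrier status); alternatively pass a single list/vector with fields
#'   a, b, c, d as \code{a}.
#' @param alternative \code{"two.sided"} (default) or \code{"greater"}
#'   (enrichment in the first row).
#' @return p-value in \eqn{(0, 1]}.
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL,
                                   alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (is.list(a) || length(a) == 4L) {
    t <- unlist(a)
    if (!is.null(names(t)) && all(c("a", "b", "c", "d") %in% names(t))) {
      t <- t[c("a", "b", "c", "d")]
    }
    t <- as.integer(t)
    a <- t[1L]; b <- t[2L]; c <- t[3L]; d <- t[4L]
  }
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0)) {
    stop("contingency cells must be non-negative integers", call. = FALSE)
  }
  m <- a + b           # row 1 total
  n <- c + d           # row 2 total
  k <- a + c           # column 1 total
  lo <- max(0L, k - n)
  hi <- min(m, k)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- probs[support == a]
  p <- if (alternative == "greater") {
    sum(probs[support >= a])
  } else {
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  min(1, p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH q-values: with p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j} clipped to 1, mapped back to
#' input order. \code{m} may exceed the number of supplied p-values to adjust
#' against a larger test universe.
#'
#' @param p_values Numeric vector of p-values in \eqn{(0, 1]}.
#' @param m Universe size; defaults to \code{length(p_values)}.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values, m = length(p_values)) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (m < length(p_values)) stop("m must be >= length(p_values)", call. = FALSE)
  stats::p.adjust(p_values, method = "BH", n = m)
}

#' Per-gene case-control burden scan
#'
#' The full driver scan: filter variants to candidate somatic mutations
#' ([filter_cohort()]), count carriers per gene in each cohort arm, test each
#' gene's 2x2 table with [fisher_exact_two_sided()], and control FDR across
#' the gene universe with [bh_fdr()]. The default universe is every gene with
#' at least one kept variant in either arm; \code{universe} can supply a
#' larger m when the scan is conceptually genome-wide.
#'
#' @param variants Variant \code{data.frame}; filtered internally unless
#'   \code{prefiltered = TRUE}.
#' @param metadata Sample metadata with at least one sample per arm.
#' @param mode \code{"all"} or \code{"truncating"} (truncating-only scan).
#' @param universe Integer m for the FDR correction, or \code{NULL} for the
#'   observed-gene universe.
#' @param alternative Passed to [fisher_exact_two_sided()].
#' @param prefiltered Set \code{TRUE} if \code{variants} already passed
#'   [filter_cohort()] in the same mode.
#' @param require_conserved Passed to [filter_cohort()].
#' @return \code{data.frame} with columns \code{gene a b c d p q rank mode},
#'   sorted by p ascending with ties broken by gene symbol.
#' @export
run_burden_scan <- function(variants, metadata, mode = c("all", "truncating"),
                            universe = NULL,
                            alternative = c("two.sided", "greater"),
                            prefiltered = FALSE, require_conserved = FALSE) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  if (!any(metadata$arm == "tumor") || !any(metadata$arm == "control")) {
    stop("burden scan needs at least one tumor and one control sample",
         call. = FALSE)
  }
  kept <- if (prefiltered) variants else
    filter_cohort(variants, mode, require_conserved)$kept
  genes <- sort(unique(kept$gene))
  if (length(genes) == 0L) {
    return(data.frame(gene = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), p = numeric(),
                      q = numeric(), rank = integer(), mode = character(),
                      stringsAsFactors = FALSE))
  }
  m <- if (is.null(universe)) length(genes) else as.integer(universe)

  res <- do.call(rbind, lapply(genes, function(g) {
    t <- gene_contingency(g, kept, metadata)
    data.frame(gene = g, a = t$a, b = t$b, c = t$c, d = t$d,
               p = fisher_exact_two_sided(t$a, t$b, t$c, t$d,
                                          alternative = alternative),
               stringsAsFactors = FALSE)
  }))
  res$q <- bh_fdr(res$p, m = m)
  res <- res[order(res$p, res$gene), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  res$mode <- mode
  rownames(res) <- NULL
  res
}
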