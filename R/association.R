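status_for <- function(metadata, gene) {
  if (!gene %in% names(metadata)) {
    stop("gene '", gene, "' is not tracked in the metadata", call. = FALSE)
  }
  metadata[[gene]]
}

count_stratum <- function(status, sel) {
  st <- status[sel & status != "unknown"]
  mut <- sum(st == "mutated")
  wt <- sum(st == "wildtype")
  tot <- mut + wt
  data.frame(mutated = mut, wildtype = wt, total = tot,
             percent = if (tot > 0) round(100 * mut / tot, 2) else NA_real_)
}

#' Stratified mutation-frequency table
#'
#' Mutation frequencies for one gene across grade-by-age strata of the
#' tumour arm, in the layout of a clinical frequency table: each grade
#' (IV, III, II) with pediatric and adult sub-rows, then the overall cohort.
#' Samples with unknown mutation status are excluded from both numerator and
#' denominator (assay coverage varies by sample); an empty stratum reports
#' zero counts and an undefined percent (\code{NA}, rendered as a dash).
#' Percentages are \code{100 * mutated / total} rounded to 2 decimals.
#'
#' @param metadata Sample metadata (tumour rows are used).
#' @param gene Tracked gene symbol.
#' @return \code{data.frame} with columns \code{stratum grade age_group
#'   mutated wildtype total percent}.
#' @export
frequency_table <- function(metadata, gene) {
  status <- status_for(metadata, gene)
  tum <- metadata$arm == "tumor"
  rows <- list()
  add <- function(label, grade, age, sel) {
    r <- count_stratum(status, sel)
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(stratum = label, grade = grade, age_group = age,
                 stringsAsFactors = FALSE), r)
  }
  for (g in c("IV", "III", "II")) {
    in_g <- tum & !is.na(metadata$grade) & metadata$grade == g
    add(paste("Grade", g), g, "all", in_g)
    for (ag in c("pediatric", "adult")) {
      add(paste0("Grade ", g, " ", ag), g, ag,
          in_g & !is.na(metadata$age_group) & metadata$age_group == ag)
    }
  }
  add("Overall", "all", "all", tum)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

association_2x2 <- function(status, in_g1, in_g2) {
  known <- status != "unknown"
  a <- sum(in_g1 & known & status == "mutated")
  b <- sum(in_g1 & known & status == "wildtype")
  c_ <- sum(in_g2 & known & status == "mutated")
  d <- sum(in_g2 & known & status == "wildtype")
  tab <- list(a = a, b = b, c = c_, d = d)
  list(table = tab, p = fisher_exact_two_sided(tab))
}

#' Grade association test
#'
#' Tests whether mutations in \code{gene} concentrate in high-grade tumours:
#' 2x2 of mutation status against grade group (default high = III+IV,
#' low = II), exact two-sided p from the shared
#' [fisher_exact_two_sided()] implementation.
#'
#' @param metadata Sample metadata.
#' @param gene Tracked gene symbol.
#' @param high,low Character vectors of grades defining the two groups.
#' @return List with \code{table} (a, b = high-grade mutated/wildtype;
#'   c, d = low-grade) and \code{p}.
#' @export
grade_association <- function(metadata, gene, high = c("III", "IV"),
                              low = "II") {
  status <- status_for(metadata, gene)
  tum <- metadata$arm == "tumor" & !is.na(metadata$grade)
  in_high <- tum & metadata$grade %in% high
  in_low <- tum & metadata$grade %in% low
  if (!any(in_high) || !any(in_low)) {
    stop("both grade groups need at least one sample", call. = FALSE)
  }
  association_2x2(status, in_high, in_low)
}

#' Brain-location association test
#'
#' As [grade_association()], comparing hemispheric against non-hemispheric
#' tumours.
#'
#' @param metadata Sample metadata with a filled \code{location} column.
#' @param gene Tracked gene symbol.
#' @return List with \code{table} and \code{p}.
#' @export
location_association <- function(metadata, gene) {
  status <- status_for(metadata, gene)
  tum <- metadata$arm == "tumor" & !is.na(metadata$location)
  in_hem <- tum & metadata$location == "hemispheric"
  in_other <- tum & metadata$location != "hemispheric"
  if (!any(in_hem) || !any(in_other)) {
    stop("need both hemispheric and non-hemispheric samples", call. = FALSE)
  }
  association_2x2(status, in_hem, in_other)
}

#' Pairwise mutual-exclusivity / co-occurrence test
#'
#' Cross-tabulates the mutation statuses of two genes over the samples with
#' known status for both, tests the 2x2 with the shared exact test, and
#' calls the direction from the sign of observed minus expected double
#' mutants (expected under independence given the margins). Fewer double
#' mutants than expected suggests redundant pathway effects (mutual
#' exclusivity); more suggests co-occurrence.
#'
#' @param metadata Sample metadata.
#' @param geneA,geneB Tracked gene symbols.
#' @return List with \code{table} (a = both mutated, b = A only, c = B only,
#'   d = neither), \code{p}, \code{direction} in
#'   \code{exclusive / co_occurring / none}, and \code{expected_double}.
#' @export
mutual_exclusivity <- function(metadata, geneA, geneB) {
  sA <- status_for(metadata, geneA)
  sB <- status_for(metadata, geneB)
  use <- metadata$arm == "tumor" & sA != "unknown" & sB != "unknown"
  if (sum(use) < 2L) {
    stop("fewer than 2 samples with known status for both genes",
         call. = FALSE)
  }
  a <- sum(use & sA == "mutated" & sB == "mutated")
  b <- sum(use & sA == "mutated" & sB == "wildtype")
  c_ <- sum(use & sA == "wildtype" & sB == "mutated")
  d <- sum(use & sA == "wildtype" & sB == "wildtype")
  n <- a + b + c_ + d
  expected <- (a + b) * (a + c_) / n
  direction <- if (a < expected) "exclusive" else
    if (a > expected) "co_occurring" else "none"
  list(table = list(a = a, b = b, c = c_, d = d),
       p = fisher_exact_two_sided(a, b, c_, d),
       direction = direction, expected_double = expected)
}
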