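#' Private-variant predicate
#'
#' A variant is private when it is absent from the population databases
#' (1000 Genomes, NHLBI exomes) and from every control exome. Private
#' variants in tumours without matched normals are treated as candidate
#' somatic mutations.
#'
#' @param v Variant \code{data.frame} (vectorised over rows).
#' @return Logical vector.
#' @export
is_private <- function(v) {
  !v$in_population_db & !v$in_control_exomes
}

#' Truncating-consequence predicate
#'
#' Truncating classes are nonsense, frameshift and splice-site: variants
#' expected to abolish protein function.
#'
#' @param consequence Character vector of consequence classes.
#' @return Logical vector.
#' @export
is_truncating <- function(consequence) {
  bad <- !(consequence %in% CONSEQUENCE_LEVELS)
  if (any(bad)) {
    stop("unknown consequence token '", consequence[which(bad)[1L]], "'",
         call. = FALSE)
  }
  consequence %in% c("nonsense", "frameshift", "splice_site")
}

#' Damaging-prediction filter
#'
#' Removes variants predicted non-damaging by BOTH missense predictors: a
#' missense variant passes unless its SIFT call is tolerated/unknown AND its
#' PolyPhen-2 call is benign/unknown — a single "damaging" call from either
#' predictor keeps it. Truncating variants always pass (SIFT and PolyPhen-2
#' score amino-acid substitutions and cannot rate them). Synonymous and
#' \code{other} consequences never pass.
#'
#' With \code{require_conserved = TRUE}, missense variants must additionally
#' fall in a highly conserved vertebrate residue. By default conservation is
#' reported but not filtered on: it is a prioritisation flag, not a removal
#' rule.
#'
#' @param v Variant \code{data.frame} (vectorised over rows).
#' @param require_conserved Require conservation for missense variants.
#' @return Logical vector.
#' @export
passes_damaging_filter <- function(v, require_conserved = FALSE) {
  trunc <- is_truncating(v$consequence)
  damaging_call <- v$sift == "damaging" | v$polyphen == "damaging"
  mis <- v$consequence == "missense" & damaging_call
  if (require_conserved) mis <- mis & v$conserved
  trunc | mis
}

#' Candidate-somatic filtering cascade
#'
#' Applies the filtering cascade defining candidate somatic mutations:
#' private (not in population databases, not in control exomes), then
#' predicted damaging, then — in truncating mode — restricted to the
#' truncating classes. Every input variant receives a trace giving the first
#' rule it failed, in the fixed order \code{population_db},
#' \code{control_exomes}, \code{not_damaging}, \code{not_truncating}
#' (\code{none} when kept).
#'
#' @param variants Variant \code{data.frame} from [read_variants()].
#' @param mode \code{"all"} or \code{"truncating"}.
#' @param require_conserved Passed to [passes_damaging_filter()].
#' @return A list with \code{kept} (the surviving rows, order preserved) and
#'   \code{trace} (\code{data.frame} with \code{idx}, \code{passed},
#'   \code{failed_rule} for every input row).
#' @export
filter_cohort <- function(variants, mode = c("all", "truncating"),
                          require_conserved = FALSE) {
  mode <- match.arg(mode)
  n <- nrow(variants)
  rule <- rep("none", n)
  fails_damaging <- !passes_damaging_filter(variants, require_conserved)
  if (mode == "truncating") {
    rule[!is_truncating(variants$consequence)] <- "not_truncating"
  }
  rule[fails_damaging] <- "not_damaging"
  rule[variants$in_control_exomes] <- "control_exomes"
  rule[variants$in_population_db] <- "population_db"
  passed <- rule == "none"
  list(kept = variants[passed, , drop = FALSE],
       trace = data.frame(idx = seq_len(n), passed = passed,
                          failed_rule = rule, stringsAsFactors = FALSE))
}
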