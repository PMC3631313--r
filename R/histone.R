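#' Read a densitometry table
#'
#' TSV with header \code{blot_id sample_id group h3k36me3 h3_total}; group is
#' \code{setd2_mutant} or \code{wildtype_star} (wild type for the tracked
#' driver genes). Intensities are arbitrary densitometry units.
#'
#' @param path Input TSV.
#' @return Validated \code{data.frame}.
#' @export
read_densitometry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("blot_id", "sample_id", "group", "h3k36me3", "h3_total")
  if (!identical(names(raw), need)) {
    stop(path, ": header must be: ", paste(need, collapse = " "),
         call. = FALSE)
  }
  lines <- seq_len(nrow(raw)) + 1L
  check_enum(raw$group, c("setd2_mutant", "wildtype_star"), "group", path,
             lines)
  if (any(raw$h3k36me3 < 0)) {
    i <- which(raw$h3k36me3 < 0)[1L]
    stop_at(path, lines[i], "negative h3k36me3 intensity")
  }
  raw
}

#' Blot-normalised histone-mark ratios
#'
#' Within each blot, divides the mark intensity (H3K36me3) by the total-H3
#' loading control for the same sample, then summarises each sample as the
#' mean ratio across the blots it appears on. Normalising within blot
#' cancels exposure and loading differences; averaging across independent
#' blots averages out blot-level noise.
#'
#' @param dt Densitometry \code{data.frame} (see [read_densitometry()]).
#' @return \code{data.frame} with one row per sample: \code{sample_id group
#'   mean_ratio n_blots}.
#' @export
normalized_ratios <- function(dt) {
  if (any(dt$h3_total <= 0)) {
    i <- which(dt$h3_total <= 0)[1L]
    stop(sprintf("h3_total must be > 0 (sample '%s', blot '%s')",
                 dt$sample_id[i], dt$blot_id[i]), call. = FALSE)
  }
  ratio <- dt$h3k36me3 / dt$h3_total
  samples <- unique(dt$sample_id)
  out <- do.call(rbind, lapply(samples, function(s) {
    sel <- dt$sample_id == s
    grp <- unique(dt$group[sel])
    if (length(grp) != 1L) {
      stop("sample '", s, "' appears in more than one group", call. = FALSE)
    }
    data.frame(sample_id = s, group = grp, mean_ratio = mean(ratio[sel]),
               n_blots = sum(sel), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare normalised ratios between groups
#'
#' Two-sided two-sample t-test on the per-sample mean ratios, Welch
#' (unequal-variance) by default; set \code{var_equal = TRUE} for the pooled
#' Student variant.
#'
#' @param ratios Output of [normalized_ratios()] (or any \code{data.frame}
#'   with \code{group} and \code{mean_ratio}).
#' @param var_equal Use the pooled-variance t-test.
#' @return List with \code{t}, \code{df}, \code{p}, and per-group means.
#' @export
compare_groups <- function(ratios, var_equal = FALSE) {
  groups <- split(ratios$mean_ratio, ratios$group)
  if (length(groups) != 2L) stop("need exactly 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  if (stats::var(groups[[1L]]) == 0 && stats::var(groups[[2L]]) == 0) {
    # degenerate: constant groups; t.test refuses, but the answer is clear
    same <- mean(groups[[1L]]) == mean(groups[[2L]])
    return(list(t = if (same) 0 else sign(mean(groups[[1L]]) -
                                            mean(groups[[2L]])) * Inf,
                df = NA_real_, p = if (same) 1 else 0,
                group_means = vapply(groups, mean, numeric(1))))
  }
  tt <- stats::t.test(groups[[1L]], groups[[2L]], var.equal = var_equal,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, group_means = vapply(groups, mean, numeric(1)))
}
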