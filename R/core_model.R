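#' Read annotated variant calls
#'
#' Reads per-sample variant records from either the package's TSV dialect or
#' a VCF. Each record is one annotated variant call in one sample: gene
#' symbol, VCF-style coordinate (1-based, explicit ref/alt), a consequence
#' class, SIFT/PolyPhen-2 calls, a vertebrate-conservation flag, and
#' database-membership flags used by the private-variant filter. Annotations
#' are consumed as produced upstream; this package never recomputes them.
#'
#' The TSV dialect is tab-separated with header columns
#' \code{sample_id gene chrom pos ref alt consequence sift polyphen conserved
#' in_population_db in_control_exomes}; booleans are written \code{0/1}.
#'
#' VCF input is standard VCF 4.x with per-variant annotations in INFO keys
#' \code{GENE}, \code{CSQCLASS}, \code{SIFT}, \code{PPH2}, \code{CONS},
#' \code{POPDB} and \code{CTRLDB} (the last two \code{0/1}; \code{CTRLDB}
#' defaults to 0 when absent). Multi-sample VCFs expand to one record per
#' carrier sample, a carrier being any sample whose genotype contains a
#' non-reference allele.
#'
#' @param path File to read.
#' @param format \code{"tsv"} (default) or \code{"vcf"}.
#' @return A \code{data.frame} with one row per variant record and the nine
#'   annotation columns above; \code{pos} is integer, the three flags are
#'   logical. Row order follows the file.
#' @seealso [write_variants()], [filter_cohort()]
#' @export
read_variants <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "vcf") return(read_variants_vcf(path))

  cols <- c("sample_id", "gene", "chrom", "pos", "ref", "alt", "consequence",
            "sift", "polyphen", "conserved", "in_population_db",
            "in_control_exomes")
  raw <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(names(raw), cols)) {
    stop(sprintf("%s: header must be exactly: %s", path,
                 paste(cols, collapse = " ")), call. = FALSE)
  }
  lines <- seq_len(nrow(raw)) + 1L  # file line numbers (header is line 1)
  pos <- suppressWarnings(as.integer(raw$pos))
  if (anyNA(pos)) {
    i <- which(is.na(pos))[1L]
    stop_at(path, lines[i], sprintf("invalid pos token '%s'", raw$pos[i]))
  }
  v <- data.frame(
    sample_id = raw$sample_id, gene = raw$gene, chrom = raw$chrom, pos = pos,
    ref = raw$ref, alt = raw$alt, consequence = raw$consequence,
    sift = raw$sift, polyphen = raw$polyphen,
    conserved = parse_bool(raw$conserved, "conserved", path, lines),
    in_population_db = parse_bool(raw$in_population_db, "in_population_db",
                                  path, lines),
    in_control_exomes = parse_bool(raw$in_control_exomes, "in_control_exomes",
                                   path, lines),
    stringsAsFactors = FALSE)
  validate_variants(v, file = path, lines = lines)
}

read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF input requires the 'vcfR' package", call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  info_key <- function(key, default = NA_character_) {
    x <- vcfR::extract.info(vcf, element = key)
    if (is.null(x)) rep(default, nrow(fix)) else ifelse(is.na(x), default, x)
  }
  gene  <- info_key("GENE")
  csq   <- info_key("CSQCLASS")
  sift  <- info_key("SIFT", "unknown")
  pph2  <- info_key("PPH2", "unknown")
  cons  <- info_key("CONS", "0")
  popdb <- info_key("POPDB", "0")
  ctrl  <- info_key("CTRLDB", "0")
  if (anyNA(gene) || anyNA(csq)) {
    stop(path, ": every VCF record needs GENE and CSQCLASS INFO keys",
         call. = FALSE)
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop(path, ": VCF has no sample genotype columns",
                        call. = FALSE)
  carrier <- function(g) {
    !is.na(g) & grepl("[1-9]", g)
  }
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    samples <- colnames(gt)[carrier(gt[i, ])]
    for (s in samples) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, gene = gene[i], chrom = fix[i, "CHROM"],
        pos = as.integer(fix[i, "POS"]), ref = fix[i, "REF"],
        alt = fix[i, "ALT"], consequence = csq[i], sift = sift[i],
        polyphen = pph2[i], conserved = cons[i] == "1",
        in_population_db = popdb[i] == "1",
        in_control_exomes = ctrl[i] == "1", stringsAsFactors = FALSE)
    }
  }
  v <- if (length(rows)) do.call(rbind, rows) else empty_variants()
  rownames(v) <- NULL
  validate_variants(v, file = path, lines = seq_len(nrow(v)))
}

empty_variants <- function() {
  data.frame(sample_id = character(), gene = character(), chrom = character(),
             pos = integer(), ref = character(), alt = character(),
             consequence = character(), sift = character(),
             polyphen = character(), conserved = logical(),
             in_population_db = logical(), in_control_exomes = logical(),
             stringsAsFactors = FALSE)
}

#' Validate a variant table
#'
#' Enforces the record invariants: closed enums for consequence, SIFT and
#' PolyPhen; \code{pos >= 1}; \code{ref != alt}.
#'
#' @param v A variant \code{data.frame} as returned by [read_variants()].
#' @param file,lines Used in error messages; default to a generic label and
#'   row numbers.
#' @return \code{v}, invisibly-validated (returned unchanged).
#' @export
validate_variants <- function(v, file = "<variants>", lines = seq_len(nrow(v))) {
  check_enum(v$consequence, CONSEQUENCE_LEVELS, "consequence", file, lines)
  check_enum(v$sift, SIFT_LEVELS, "sift", file, lines)
  check_enum(v$polyphen, POLYPHEN_LEVELS, "polyphen", file, lines)
  if (any(v$pos < 1L)) {
    i <- which(v$pos < 1L)[1L]
    stop_at(file, lines[i], sprintf("pos must be >= 1, got %d", v$pos[i]))
  }
  same <- v$ref == v$alt
  if (any(same)) {
    i <- which(same)[1L]
    stop_at(file, lines[i], sprintf("ref equals alt ('%s')", v$ref[i]))
  }
  v
}

#' Write a variant table in the package TSV dialect
#'
#' Inverse of [read_variants()] for \code{format = "tsv"}: booleans written
#' as \code{0/1}, columns in the canonical order, no quoting.
#'
#' @param v Variant \code{data.frame}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_variants <- function(v, path) {
  out <- v
  for (col in c("conserved", "in_population_db", "in_control_exomes")) {
    out[[col]] <- as.integer(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Reads the cohort metadata TSV: one row per sample with columns
#' \code{sample_id arm grade age_group age_years location} followed by one
#' column per tracked gene holding \code{mutated/wildtype/unknown}. Missing
#' optional fields are the literal token \code{NA}. Control samples must have
#' \code{NA} grade and location (controls are non-tumour exomes; tumour-only
#' strata do not apply to them).
#'
#' @param path Metadata TSV.
#' @return A \code{data.frame}; tracked gene symbols are recorded in
#'   \code{attr(, "genes")}.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  fixed <- c("sample_id", "arm", "grade", "age_group", "age_years", "location")
  if (length(names(raw)) < length(fixed) ||
      !identical(names(raw)[seq_along(fixed)], fixed)) {
    stop(sprintf("%s: header must start with: %s", path,
                 paste(fixed, collapse = " ")), call. = FALSE)
  }
  genes <- setdiff(names(raw), fixed)
  lines <- seq_len(nrow(raw)) + 1L

  dup <- duplicated(raw$sample_id)
  if (any(dup)) {
    i <- which(dup)[1L]
    stop_at(path, lines[i],
            sprintf("duplicated sample_id '%s'", raw$sample_id[i]))
  }
  check_enum(raw$arm, c("tumor", "control"), "arm", path, lines)
  grade <- na_token(raw$grade)
  check_enum(grade, GRADE_LEVELS, "grade", path, lines, allow_na = TRUE)
  age_group <- na_token(raw$age_group)
  check_enum(age_group, AGE_LEVELS, "age_group", path, lines, allow_na = TRUE)
  location <- na_token(raw$location)
  check_enum(location, LOCATION_LEVELS, "location", path, lines,
             allow_na = TRUE)
  age_years <- suppressWarnings(as.numeric(na_token(raw$age_years)))
  bad_age <- !is.na(age_years) & age_years < 0
  if (any(bad_age)) {
    i <- which(bad_age)[1L]
    stop_at(path, lines[i], sprintf("negative age_years '%s'", raw$age_years[i]))
  }

  ctl <- raw$arm == "control"
  bad <- ctl & (!is.na(grade) | !is.na(location))
  if (any(bad)) {
    i <- which(bad)[1L]
    stop_at(path, lines[i],
            sprintf("control sample '%s' must have NA grade and location",
                    raw$sample_id[i]))
  }

  meta <- data.frame(sample_id = raw$sample_id, arm = raw$arm, grade = grade,
                     age_group = age_group, age_years = age_years,
                     location = location, stringsAsFactors = FALSE)
  for (g in genes) {
    check_enum(raw[[g]], STATUS_LEVELS, sprintf("%s status", g), path, lines)
    meta[[g]] <- raw[[g]]
  }
  attr(meta, "genes") <- genes
  meta
}

#' Write sample metadata
#'
#' @param meta Metadata \code{data.frame} as produced by [read_metadata()] or
#'   the cohort simulator.
#' @param path Output TSV.
#' @return \code{path}, invisibly.
#' @export
write_metadata <- function(meta, path) {
  out <- meta
  out$age_years <- ifelse(is.na(out$age_years), "NA",
                          format(out$age_years, trim = TRUE, digits = 15))
  for (col in c("grade", "age_group", "location")) {
    out[[col]][is.na(out[[col]])] <- "NA"
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a beta matrix object
#'
#' A \code{beta_matrix} couples a probes-by-samples matrix of methylation
#' fractions with per-probe annotations (\code{probe_id chrom cross_reactive
#' snp_maf}) used by [filter_probes()]. Betas must be finite and in
#' \eqn{[0,1]}; probe and sample ids must be unique.
#'
#' @param beta Numeric matrix, probes as rows (rownames = probe ids),
#'   samples as columns (colnames = sample ids).
#' @param annotations Optional probe annotation \code{data.frame} with
#'   columns \code{probe_id}, \code{chrom}, \code{cross_reactive} (logical),
#'   \code{snp_maf} (fraction or NA).
#' @return An object of class \code{beta_matrix}.
#' @export
beta_matrix <- function(beta, annotations = NULL) {
  stopifnot(is.matrix(beta), is.numeric(beta))
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop("beta matrix needs probe rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(beta))) stop("duplicated probe ids", call. = FALSE)
  if (anyDuplicated(colnames(beta))) stop("duplicated sample ids", call. = FALSE)
  bad <- !is.finite(beta) | beta < 0 | beta > 1
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("beta value %g out of [0,1] at probe '%s', sample '%s'",
                 beta[ij[1L], ij[2L]], rownames(beta)[ij[1L]],
                 colnames(beta)[ij[2L]]), call. = FALSE)
  }
  if (!is.null(annotations)) {
    need <- c("probe_id", "chrom", "cross_reactive", "snp_maf")
    if (!all(need %in% names(annotations))) {
      stop("annotations need columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    annotations <- annotations[match(rownames(beta), annotations$probe_id), ,
                               drop = FALSE]
    if (anyNA(annotations$probe_id)) {
      miss <- setdiff(rownames(beta), annotations$probe_id)
      stop("probe missing annotation: ", miss[1L], call. = FALSE)
    }
    rownames(annotations) <- NULL
  }
  structure(list(beta = beta, probe_annotations = annotations),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples%s\n", nrow(x$beta),
              ncol(x$beta),
              if (is.null(x$probe_annotations)) "" else ", annotated"))
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$beta)

#' Read a methylation beta matrix
#'
#' Reads a probes-by-samples table of beta values (first column
#' \code{probe_id}, remaining columns one per sample; TSV by default, CSV if
#' the file ends in \code{.csv}). Values outside \eqn{[0,1]} are an error
#' naming the probe and sample — betas are methylated fractions and an
#' out-of-range value indicates broken upstream normalisation, not something
#' to clip silently.
#'
#' @param path Beta-value table.
#' @param annotation_path Optional probe-annotation TSV with header
#'   \code{probe_id chrom cross_reactive snp_maf} (\code{cross_reactive} as
#'   0/1, \code{snp_maf} a fraction or \code{NA}).
#' @return A [beta_matrix()] object.
#' @export
read_beta_matrix <- function(path, annotation_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (names(raw)[1L] != "probe_id") {
    stop(path, ": first column must be 'probe_id'", call. = FALSE)
  }
  beta <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(beta)) stop(path, ": non-numeric beta values", call. = FALSE)
  rownames(beta) <- raw$probe_id

  ann <- NULL
  if (!is.null(annotation_path)) {
    a <- utils::read.delim(annotation_path, colClasses = "character",
                           stringsAsFactors = FALSE)
    need <- c("probe_id", "chrom", "cross_reactive", "snp_maf")
    if (!identical(names(a)[seq_along(need)], need)) {
      stop(annotation_path, ": header must be: probe_id chrom cross_reactive snp_maf",
           call. = FALSE)
    }
    ann <- data.frame(
      probe_id = a$probe_id, chrom = a$chrom,
      cross_reactive = parse_bool(a$cross_reactive, "cross_reactive",
                                  annotation_path, seq_len(nrow(a)) + 1L),
      snp_maf = suppressWarnings(as.numeric(na_token(a$snp_maf))),
      stringsAsFactors = FALSE)
  }
  beta_matrix(beta, ann)
}

#' Write a beta matrix
#'
#' Writes the beta values in the TSV dialect of [read_beta_matrix()] at full
#' double precision, so that write-then-read round-trips bit-identically.
#' Annotations, when present, are written alongside.
#'
#' @param bm A [beta_matrix()].
#' @param path Output TSV for the beta values.
#' @param annotation_path Optional output TSV for probe annotations.
#' @return \code{path}, invisibly.
#' @export
write_beta_matrix <- function(bm, path, annotation_path = NULL) {
  stopifnot(inherits(bm, "beta_matrix"))
  vals <- apply(bm$beta, 2L, function(col) sprintf("%.17g", col))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(bm$beta))
  out <- cbind(probe_id = rownames(bm$beta), as.data.frame(vals))
  names(out) <- c("probe_id", colnames(bm$beta))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path) && !is.null(bm$probe_annotations)) {
    a <- bm$probe_annotations
    a$cross_reactive <- as.integer(a$cross_reactive)
    a$snp_maf <- ifelse(is.na(a$snp_maf), "NA", sprintf("%.17g", a$snp_maf))
    utils::write.table(a, annotation_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
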