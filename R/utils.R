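# Internal validation helpers shared across readers.

CONSEQUENCE_LEVELS <- c("missense", "nonsense", "frameshift", "splice_site",
                        "synonymous", "other")
SIFT_LEVELS     <- c("damaging", "tolerated", "unknown")
POLYPHEN_LEVELS <- c("damaging", "benign", "unknown")
GRADE_LEVELS    <- c("II", "III", "IV")
AGE_LEVELS      <- c("pediatric", "adult")
LOCATION_LEVELS <- c("hemispheric", "midline", "other")
STATUS_LEVELS   <- c("mutated", "wildtype", "unknown")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_at <- function(file, line, msg) {
  stop(sprintf("%s, line %d: %s", file, line, msg), call. = FALSE)
}

# Closed-enum check with an error that names file, line and offending token.
check_enum <- function(x, levels, field, file, lines, allow_na = FALSE) {
  bad <- !(x %in% levels)
  if (allow_na) bad <- bad & !is.na(x) & x != "NA"
  if (any(bad)) {
    i <- which(bad)[1L]
    stop_at(file, lines[i],
            sprintf("invalid %s token '%s' (expected one of: %s)",
                    field, x[i], paste(levels, collapse = ", ")))
  }
  invisible(x)
}

# Parse 0/1 (also TRUE/FALSE for convenience) booleans from text tables.
parse_bool <- function(x, field, file, lines) {
  out <- rep(NA, length(x))
  out[x %in% c("0", "FALSE", "false")] <- FALSE
  out[x %in% c("1", "TRUE", "true")]   <- TRUE
  if (anyNA(out)) {
    i <- which(is.na(out))[1L]
    stop_at(file, lines[i],
            sprintf("invalid %s token '%s' (expected 0/1)", field, x[i]))
  }
  out
}

na_token <- function(x) {
  x[x == "NA" | x == ""] <- NA_character_
  x
}
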