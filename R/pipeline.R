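provenance_header <- function(stage, params, seed = NULL) {
  ver <- as.character(utils::packageVersion("glioburden"))
  kv <- paste(names(params), unname(vapply(params, function(x)
    paste(format(x), collapse = ","), character(1))), sep = "=",
    collapse = " ")
  c(sprintf("# glioburden %s stage=%s%s", ver, stage,
            if (is.null(seed)) "" else sprintf(" seed=%d", seed)),
    sprintf("# params: %s", kv))
}

write_tsv_with_header <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pipeline_log <- function(con, ...) {
  msg <- sprintf(...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the analysis pipeline from a configuration
#'
#' Orchestrates the stages in fixed order — \code{simulate}, \code{filter},
#' \code{scan}, \code{associate}, \code{methcluster} — writing each stage's
#' tables into \code{out_dir} with a provenance header (package version,
#' stage, seed, parameters). Any stage may be omitted from the
#' configuration. Input paths are checked before any stage runs, and a
#' stage failure aborts the run with the stage name in the error. Outputs
#' are deterministic for a fixed configuration: re-running an unchanged
#' config reproduces byte-identical TSVs (timestamps are confined to the
#' log).
#'
#' The configuration is a named list (or a YAML/JSON file path) with an
#' \code{out_dir} entry plus one entry per stage, e.g.:
#' \preformatted{
#' simulate:   {seed: 7, n_genes: 100, drivers: [{gene: 1, rate_multiplier: 10}]}
#' filter:     {mode: all}                 # variants: path, when not simulated
#' scan:       {mode: truncating}          # meta: path, when not simulated
#' associate:  {meta: meta.tsv, gene: SETD2, by: grade}
#' methcluster: {beta: b.tsv, annot: a.tsv, top: 2000, kmin: 2, kmax: 5,
#'               B: 100, seed: 17}
#' }
#'
#' @param config Named list or path to a YAML/JSON config file.
#' @return Invisibly, the output directory path.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  out_dir <- config$out_dir %||% stop("config needs out_dir", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # Validate every referenced input path before running anything.
  for (stage in c("filter", "scan", "associate", "methcluster")) {
    for (key in c("variants", "meta", "beta", "annot")) {
      p <- config[[stage]][[key]]
      if (!is.null(p) && !file.exists(p)) {
        stop(sprintf("stage '%s': input path not found: %s", stage, p),
             call. = FALSE)
      }
    }
  }

  logcon <- file(file.path(out_dir, "pipeline.log"), "w")
  on.exit(close(logcon))
  pipeline_log(logcon, "pipeline started %s", format(Sys.time()))

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  variants <- NULL
  metadata <- NULL

  if (!is.null(config$simulate)) {
    run_stage("simulate", function() {
      sc <- config$simulate
      drivers <- sc$drivers %||% list()
      if (is.data.frame(drivers)) drivers <- split(drivers, seq_len(nrow(drivers)))
      spec <- cohort_sim_spec(
        n_tumor = sc$n_tumor %||% 60, n_control = sc$n_control %||% 543,
        n_genes = sc$n_genes %||% 200,
        background_rate = sc$background_rate %||% 1e-3,
        drivers = drivers, db_flag_rate = sc$db_flag_rate %||% 0.3,
        seed = sc$seed %||% 1L)
      sim <- simulate_variant_cohort(spec)
      variants <<- sim$variants
      metadata <<- sim$metadata
      write_variants(sim$variants, file.path(out_dir, "simulated_variants.tsv"))
      write_metadata(sim$metadata, file.path(out_dir, "simulated_meta.tsv"))
      pipeline_log(logcon, "simulate: %d variants, %d samples",
                   nrow(sim$variants), nrow(sim$metadata))
    })
  }

  if (!is.null(config$filter)) {
    run_stage("filter", function() {
      fc <- config$filter
      v <- if (!is.null(fc$variants)) read_variants(fc$variants) else variants
      if (is.null(v)) stop("no variants available (give filter$variants or a simulate stage)")
      mode <- fc$mode %||% "all"
      res <- filter_cohort(v, mode = mode,
                           require_conserved = isTRUE(fc$require_conserved))
      dropped <- sum(!res$trace$passed)
      pipeline_log(logcon, "filter: kept %d of %d variants (%d dropped)",
                   nrow(res$kept), nrow(v), dropped)
      hdr <- provenance_header("filter", list(mode = mode))
      write_tsv_with_header(
        within(res$kept, {
          conserved <- as.integer(conserved)
          in_population_db <- as.integer(in_population_db)
          in_control_exomes <- as.integer(in_control_exomes)
        }), file.path(out_dir, "kept.tsv"), hdr)
      write_tsv_with_header(res$trace, file.path(out_dir, "trace.tsv"), hdr)
      variants <<- v
    })
  }

  if (!is.null(config$scan)) {
    run_stage("scan", function() {
      sc <- config$scan
      v <- if (!is.null(sc$variants)) read_variants(sc$variants) else variants
      m <- if (!is.null(sc$meta)) read_metadata(sc$meta) else metadata
      if (is.null(v) || is.null(m)) {
        stop("scan needs variants and metadata (from config paths or a simulate stage)")
      }
      mode <- sc$mode %||% "all"
      res <- run_burden_scan(v, m, mode = mode,
                             universe = sc$universe)
      pipeline_log(logcon, "scan: %d genes tested, %d at q<%.3g", nrow(res),
                   sum(res$q < (sc$alpha %||% 0.05)), sc$alpha %||% 0.05)
      write_tsv_with_header(res, file.path(out_dir, "burden.tsv"),
                            provenance_header("scan", list(mode = mode)))
    })
  }

  if (!is.null(config$associate)) {
    run_stage("associate", function() {
      ac <- config$associate
      m <- if (!is.null(ac$meta)) read_metadata(ac$meta) else metadata
      if (is.null(m)) stop("associate needs metadata")
      gene <- ac$gene %||% stop("associate needs a gene")
      freq <- frequency_table(m, gene)
      hdr <- provenance_header("associate", list(gene = gene))
      write_tsv_with_header(freq, file.path(out_dir, "frequency.tsv"), hdr)
      report <- list(gene = gene, frequency = freq)
      if (identical(ac$by, "grade") || is.null(ac$by)) {
        ga <- tryCatch(grade_association(m, gene), error = function(e) NULL)
        if (!is.null(ga)) report$grade <- ga
      }
      if (identical(ac$by, "location")) {
        report$location <- location_association(m, gene)
      }
      if (!is.null(ac$vs)) {
        report$exclusivity <- mutual_exclusivity(m, gene, ac$vs)
      }
      jsonlite::write_json(report, file.path(out_dir, "associate.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      pipeline_log(logcon, "associate: gene %s, %d strata", gene, nrow(freq))
    })
  }

  if (!is.null(config$methcluster)) {
    run_stage("methcluster", function() {
      mc <- config$methcluster
      bm <- read_beta_matrix(mc$beta, mc$annot)
      if (!is.null(bm$probe_annotations)) bm <- filter_probes(bm)
      bm <- select_top_variable(bm, n = mc$top %||% 8000)
      cr <- consensus_kmeans(bm, k_range = (mc$kmin %||% 2):(mc$kmax %||% 10),
                             B = mc$B %||% 1000,
                             item_frac = mc$item_frac %||% 0.8,
                             seed = mc$seed %||% 1L)
      hdr <- provenance_header("methcluster",
                               list(top = mc$top %||% 8000, B = mc$B %||% 1000),
                               seed = as.integer(mc$seed %||% 1L))
      for (k in cr$k_values) {
        write_tsv_with_header(
          as.data.frame(cr$consensus[[as.character(k)]]),
          file.path(out_dir, sprintf("consensus_k%d.tsv", k)), hdr)
      }
      labs <- do.call(cbind, cr$labels)
      write_tsv_with_header(
        cbind(data.frame(sample_id = rownames(labs)), as.data.frame(labs)),
        file.path(out_dir, "labels.tsv"), hdr)
      write_tsv_with_header(
        data.frame(k = cr$k_values, A = unname(cr$A),
                   delta = unname(cr$delta)),
        file.path(out_dir, "cdf_area.tsv"), hdr)
      pipeline_log(logcon, "methcluster: selected k = %d", cr$selected_k)
    })
  }

  pipeline_log(logcon, "pipeline finished %s", format(Sys.time()))
  invisible(out_dir)
}
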