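#' Cohort simulation specification
#'
#' Parameters for [simulate_variant_cohort()]. Defaults mirror a
#' discovery-scale exome study: 60 tumour exomes against 543 control exomes.
#' \code{background_rate} is the expected number of KEPT variants (private
#' and damaging) per gene per sample; the generator inflates the raw Poisson
#' rate so that database flagging and the damaging filter thin it back to
#' exactly this rate. Driver genes add an independent
#' Poisson(\code{background_rate * (rate_multiplier - 1)}) stream of
#' always-private, always-damaging variants in tumour samples only, with the
#' driver's own truncating fraction.
#'
#' @param n_tumor,n_control Cohort arm sizes.
#' @param n_genes Number of genes simulated (symbols G0001...).
#' @param background_rate Expected kept variants per gene per sample.
#' @param drivers List of \code{list(gene=, rate_multiplier=,
#'   truncating_fraction=)} entries; gene may be an index or a symbol.
#' @param db_flag_rate Probability a background variant carries a
#'   database-membership flag (split between population databases and
#'   control exomes).
#' @param truncating_fraction Background truncating fraction.
#' @param missense_damaging_fraction Fraction of background missense calls
#'   predicted damaging by at least one predictor.
#' @param seed Integer seed.
#' @return A \code{cohort_sim_spec} list.
#' @export
cohort_sim_spec <- function(n_tumor = 60, n_control = 543, n_genes = 200,
                            background_rate = 1e-3, drivers = list(),
                            db_flag_rate = 0.3, truncating_fraction = 0.05,
                            missense_damaging_fraction = 0.3, seed = 1L) {
  stopifnot(n_tumor >= 1, n_control >= 1, n_genes >= 1, background_rate >= 0,
            db_flag_rate >= 0, db_flag_rate <= 1,
            truncating_fraction >= 0, truncating_fraction <= 1,
            missense_damaging_fraction >= 0, missense_damaging_fraction <= 1)
  structure(list(n_tumor = n_tumor, n_control = n_control, n_genes = n_genes,
                 background_rate = background_rate, drivers = drivers,
                 db_flag_rate = db_flag_rate,
                 truncating_fraction = truncating_fraction,
                 missense_damaging_fraction = missense_damaging_fraction,
                 seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

draw_consequence <- function(n, truncating_fraction) {
  trunc <- stats::runif(n) < truncating_fraction
  csq <- rep("missense", n)
  csq[trunc] <- sample(c("frameshift", "nonsense", "splice_site"),
                       sum(trunc), replace = TRUE)
  csq
}

#' Simulate a tumour/control exome cohort
#'
#' Per sample-by-gene variant counts are Poisson with a shared background
#' rate; injected driver genes get an elevated rate in tumours only and an
#' excess of truncating consequences. Background variants are randomly
#' flagged as database members (population databases or control exomes) and
#' their missense predictor calls drawn so a known fraction survives the
#' damaging filter; driver-injected variants are always private and always
#' damaging, emulating real driver mutations which are somatic and
#' function-breaking. The truth record lists the injected drivers, so
#' downstream scans can be scored against known ground truth.
#'
#' @param spec A [cohort_sim_spec()].
#' @return List with \code{variants}, \code{metadata} (tumours are grade IV
#'   pediatric by convention; controls carry NA strata) and \code{truth}
#'   (driver gene symbols and parameters).
#' @export
simulate_variant_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(spec$seed)
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  tumor_ids <- sprintf("T%03d", seq_len(spec$n_tumor))
  control_ids <- sprintf("C%03d", seq_len(spec$n_control))
  sample_ids <- c(tumor_ids, control_ids)
  is_tumor <- c(rep(TRUE, spec$n_tumor), rep(FALSE, spec$n_control))

  drivers <- lapply(spec$drivers, function(d) {
    g <- if (is.numeric(d$gene)) genes[d$gene] else d$gene
    list(gene = g, rate_multiplier = d$rate_multiplier,
         truncating_fraction = d$truncating_fraction %||% 0.5)
  })
  driver_genes <- vapply(drivers, `[[`, character(1), "gene")

  # Raw background rate such that the expected KEPT rate is background_rate.
  tf <- spec$truncating_fraction
  mdf <- spec$missense_damaging_fraction
  p_keep <- (1 - spec$db_flag_rate) * (tf + (1 - tf) * mdf)
  raw_rate <- if (p_keep > 0) spec$background_rate / p_keep else 0

  rows <- list()
  pos_counter <- 0L
  emit <- function(sample_id, gene, csq, sift, polyphen, conserved, popdb,
                   ctrl) {
    pos_counter <<- pos_counter + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = sample_id, gene = gene, chrom = "1", pos = pos_counter,
      ref = "A", alt = "T", consequence = csq, sift = sift,
      polyphen = polyphen, conserved = conserved, in_population_db = popdb,
      in_control_exomes = ctrl, stringsAsFactors = FALSE)
  }

  n_samples <- length(sample_ids)
  for (gi in seq_along(genes)) {
    counts <- stats::rpois(n_samples, raw_rate)
    for (si in which(counts > 0L)) {
      for (rep_i in seq_len(counts[si])) {
        flagged <- stats::runif(1) < spec$db_flag_rate
        popdb <- flagged && stats::runif(1) < 0.5
        ctrl <- flagged && !popdb
        csq <- draw_consequence(1L, tf)
        if (csq == "missense") {
          damaging <- stats::runif(1) < mdf
          sift <- if (damaging) "damaging" else
            sample(c("tolerated", "unknown"), 1L)
          polyphen <- if (damaging && stats::runif(1) < 0.5) "damaging" else
            sample(c("benign", "unknown"), 1L)
          conserved <- stats::runif(1) < 0.5
        } else {
          sift <- "unknown"; polyphen <- "unknown"
          damaging <- TRUE
          conserved <- TRUE
        }
        emit(sample_ids[si], genes[gi], csq, sift, polyphen, conserved,
             popdb, ctrl)
      }
    }
  }

  # Driver excess: tumour arm only, always private and damaging.
  for (d in drivers) {
    excess <- spec$background_rate * (d$rate_multiplier - 1)
    if (excess <= 0) next
    counts <- stats::rpois(spec$n_tumor, excess)
    for (si in which(counts > 0L)) {
      for (rep_i in seq_len(counts[si])) {
        csq <- draw_consequence(1L, d$truncating_fraction)
        sift <- if (csq == "missense") "damaging" else "unknown"
        polyphen <- if (csq == "missense") "damaging" else "unknown"
        emit(tumor_ids[si], d$gene, csq, sift, polyphen, TRUE, FALSE, FALSE)
      }
    }
  }

  variants <- if (length(rows)) do.call(rbind, rows) else empty_variants()
  rownames(variants) <- NULL

  metadata <- data.frame(
    sample_id = sample_ids,
    arm = ifelse(is_tumor, "tumor", "control"),
    grade = ifelse(is_tumor, "IV", NA_character_),
    age_group = ifelse(is_tumor, "pediatric", NA_character_),
    age_years = NA_real_, location = NA_character_,
    stringsAsFactors = FALSE)
  attr(metadata, "genes") <- character(0)

  list(variants = variants, metadata = metadata,
       truth = list(driver_genes = driver_genes, drivers = drivers,
                    spec = spec))
}

#' Beta-matrix simulation specification
#'
#' Parameters for [simulate_beta_matrix()]. Clusters differ on blocks of
#' informative probes: block j sits at beta 0.5 + shift for cluster j and
#' 0.5 - shift for the others; uninformative probes sit at 0.5 everywhere.
#' Gaussian noise is added and values are clipped to \eqn{[0.001, 0.999]},
#' mimicking the bounded, noisy beta scale of methylation arrays.
#'
#' @param n_samples,n_probes Matrix dimensions.
#' @param k_true Number of planted clusters (at most \code{n_samples / 3}).
#' @param n_informative_probes Probes carrying cluster signal.
#' @param shift Beta offset between clusters, in \eqn{[0, 0.5]}.
#' @param noise_sd Gaussian noise SD.
#' @param seed Integer seed.
#' @return A \code{beta_sim_spec} list.
#' @export
beta_sim_spec <- function(n_samples = 60, n_probes = 500, k_true = 3,
                          n_informative_probes = 100, shift = 0.25,
                          noise_sd = 0.05, seed = 1L) {
  stopifnot(k_true >= 1, k_true <= n_samples / 3, shift >= 0, shift <= 0.5,
            noise_sd >= 0, n_informative_probes <= n_probes)
  structure(list(n_samples = n_samples, n_probes = n_probes, k_true = k_true,
                 n_informative_probes = n_informative_probes, shift = shift,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "beta_sim_spec")
}

#' Simulate a clustered methylation beta matrix
#'
#' @param spec A [beta_sim_spec()].
#' @return List with \code{bm} (an annotated [beta_matrix()]; annotations
#'   all pass [filter_probes()]) and \code{labels} (true cluster of each
#'   sample).
#' @export
simulate_beta_matrix <- function(spec) {
  stopifnot(inherits(spec, "beta_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  p <- spec$n_probes
  k <- spec$k_true
  labels <- rep(seq_len(k), length.out = n)
  probe_ids <- sprintf("cg%06d", seq_len(p))
  sample_ids <- sprintf("S%03d", seq_len(n))

  means <- matrix(0.5, p, n)
  if (spec$n_informative_probes > 0 && k > 1) {
    block <- split(seq_len(spec$n_informative_probes),
                   rep(seq_len(k), length.out = spec$n_informative_probes))
    for (j in seq_len(k)) {
      means[block[[j]], ] <- 0.5 - spec$shift
      means[block[[j]], labels == j] <- 0.5 + spec$shift
    }
  }
  beta <- means + matrix(stats::rnorm(p * n, 0, spec$noise_sd), p, n)
  beta <- pmin(pmax(beta, 0.001), 0.999)
  dimnames(beta) <- list(probe_ids, sample_ids)
  ann <- data.frame(probe_id = probe_ids, chrom = "1", cross_reactive = FALSE,
                    snp_maf = NA_real_, stringsAsFactors = FALSE)
  list(bm = beta_matrix(beta, ann), labels = stats::setNames(labels,
                                                             sample_ids))
}

#' Simulate a densitometry table
#'
#' Two groups of samples measured on several independent blots; the mutant
#' group's mean normalised ratio is reduced by \code{effect} single-blot
#' noise SDs, emulating loss of the histone mark in driver-mutant tumours.
#' Blot-to-blot measurement noise is the dominant noise term — which is why
#' the assay averages several independent blots per sample — so the
#' standardised separation of the per-sample blot means exceeds
#' \code{effect} by roughly \code{sqrt(n_blots)}.
#'
#' @param n_per_group Samples per group.
#' @param n_blots Independent blots.
#' @param effect Group separation in units of the single-blot noise SD.
#' @param sample_sd Between-sample SD of the true ratio (biological
#'   variation).
#' @param blot_sd Within-sample between-blot measurement noise SD.
#' @param seed Integer seed.
#' @return A densitometry \code{data.frame} (see [read_densitometry()]).
#' @export
simulate_densitometry <- function(n_per_group = 6, n_blots = 4, effect = 3,
                                  sample_sd = 0.05, blot_sd = 0.15,
                                  seed = 1L) {
  set.seed(seed)
  groups <- c(rep("setd2_mutant", n_per_group),
              rep("wildtype_star", n_per_group))
  ids <- sprintf("P%02d", seq_along(groups))
  true_ratio <- ifelse(groups == "wildtype_star", 1.0, 1.0 - effect * blot_sd)
  true_ratio <- pmax(0.05, true_ratio + stats::rnorm(length(ids), 0, sample_sd))
  rows <- list()
  for (b in seq_len(n_blots)) {
    h3 <- stats::runif(length(ids), 0.8, 1.2)
    ratio <- pmax(0.01, true_ratio + stats::rnorm(length(ids), 0, blot_sd))
    rows[[b]] <- data.frame(blot_id = sprintf("B%d", b), sample_id = ids,
                            group = groups, h3k36me3 = ratio * h3,
                            h3_total = h3, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Table 1 cell counts: grade x age_group x status, 183 gliomas.
TABLE1_CELLS <- data.frame(
  grade = c("IV", "IV", "III", "III", "II", "II"),
  age_group = c("pediatric", "adult", "pediatric", "adult", "pediatric",
                "adult"),
  mutated = c(9L, 3L, 2L, 2L, 0L, 0L),
  wildtype = c(51L, 34L, 11L, 26L, 23L, 22L),
  stringsAsFactors = FALSE)

#' Reference 183-glioma metadata fixture
#'
#' Deterministically regenerates the packaged 183-sample glioma cohort whose
#' SETD2 mutation counts stratify by grade and age group as: grade IV 12/97
#' (pediatric 9/60, adult 3/37), grade III 4/41 (pediatric 2/13, adult 2/28),
#' grade II 0/45 (pediatric 0/23, adult 0/22), overall 16/183. Locations and
#' ages are not part of the fixture (NA):
#' only the printed marginals are encoded. A TSV copy ships in
#' \code{inst/extdata/fixture_table1.tsv}.
#'
#' @return Metadata \code{data.frame} with a \code{SETD2} status column.
#' @export
fixture_table1 <- function() {
  rows <- list()
  i <- 0L
  for (r in seq_len(nrow(TABLE1_CELLS))) {
    cell <- TABLE1_CELLS[r, ]
    for (status in c("mutated", "wildtype")) {
      n <- cell[[status]]
      for (j in seq_len(n)) {
        i <- i + 1L
        rows[[i]] <- data.frame(
          sample_id = sprintf("GL%03d", i), arm = "tumor",
          grade = cell$grade, age_group = cell$age_group,
          age_years = NA_real_, location = NA_character_,
          SETD2 = status, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "genes") <- "SETD2"
  out
}

#' Reference tumour-arm truncating-variant fixture
#'
#' Deterministically regenerates the packaged 8-variant SETD2 tumour set:
#' 3 frameshift, 1 nonsense, 1 splice-site and 3 conserved missense variants
#' (damaging by both predictors), all private. Five are truncating. A TSV
#' copy ships in \code{inst/extdata/setd2_tumor_variants.tsv}.
#'
#' @return Variant \code{data.frame}.
#' @export
fixture_setd2_variants <- function() {
  csq <- c("frameshift", "frameshift", "frameshift", "nonsense", "splice_site",
           "missense", "missense", "missense")
  mis <- csq == "missense"
  v <- data.frame(
    sample_id = sprintf("T%03d", 1:8), gene = "SETD2", chrom = "3",
    pos = seq(47057898L, by = 1000L, length.out = 8L),
    ref = "C", alt = "T", consequence = csq,
    sift = ifelse(mis, "damaging", "unknown"),
    polyphen = ifelse(mis, "damaging", "unknown"),
    conserved = TRUE, in_population_db = FALSE, in_control_exomes = FALSE,
    stringsAsFactors = FALSE)
  validate_variants(v)
}
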