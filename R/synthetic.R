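#' Simulation configuration for the synthetic trial cohort
#'
#' Bundles every knob of the synthetic-data generators. Defaults emulate
#' the design of the motivating 30-patient single-arm trial: uniform
#' accrual over 24 months, administrative censoring at 48 months,
#' exponential survival with median 16 months in the biomarker-positive
#' group versus the 9.5-month historical-control median in the negative
#' group, and response probabilities matching the reported
#' biomarker-stratified response rates.
#'
#' The first entry of `biomarker_prevalence` is the "driver" biomarker:
#' its status defines the positive/negative groups that response and
#' survival are conditioned on.
#'
#' @param n_patients cohort size (>= 2).
#' @param accrual_months uniform enrolment window, months.
#' @param total_months administrative censoring time from study start,
#'   months (may be `Inf` to disable censoring).
#' @param median_os_by_group,median_pfs_by_group named numeric
#'   (`positive`, `negative`): exponential medians in months.
#' @param response_prob_by_group named numeric (`positive`, `negative`):
#'   probability of an objective response (PR) given driver status.
#' @param sd_frac_nonresponder among non-responders, probability of SD
#'   (rest are PD).
#' @param biomarker_prevalence named probabilities of carrying each
#'   biomarker; first entry is the driver.
#' @param gene_alteration_probs named per-gene marginal alteration
#'   probabilities for the mutation generator (interpreted as the
#'   non-responder probability when the gene is enriched).
#' @param enrichment_odds named odds ratios (gene -> OR) applied to
#'   responders' alteration odds; every name must appear in
#'   `gene_alteration_probs`.
#' @param n_msi_loci number of mononucleotide microsatellite loci.
#' @param n_baseline_samples size of the stable baseline panel.
#' @param baseline_unstable_rate mean per-locus unstable-read rate in
#'   stable samples.
#' @param msi_h_locus_fraction fraction of loci elevated in an MSI-high
#'   sample.
#' @param msi_h_unstable_rate unstable-read rate at elevated loci.
#' @param msi_mean_depth mean sequencing depth per locus (depths are drawn
#'   as `msi_min_depth + Poisson`).
#' @param msi_min_depth minimum guaranteed depth.
#' @param n_genes panel size for the expression generator (>= number of
#'   genes named in the registry).
#' @param signature_effect_log2 log2 shift added to responder columns of
#'   the up-shifted signature genes.
#' @param dispersion log2-scale standard deviation of expression noise.
#' @param seed integer master seed; each generator derives its own
#'   independent substream from it.
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_patients = 30,
                              accrual_months = 24,
                              total_months = 48,
                              median_os_by_group = c(positive = 16, negative = 9.5),
                              median_pfs_by_group = c(positive = 9.8, negative = 4.5),
                              response_prob_by_group = c(positive = 7 / 9, negative = 4 / 21),
                              sd_frac_nonresponder = 14 / 19,
                              biomarker_prevalence = c(hrr = 0.30, chromatin_remodeling = 0.367),
                              gene_alteration_probs = NULL,
                              enrichment_odds = NULL,
                              n_msi_loci = 60,
                              n_baseline_samples = 200,
                              baseline_unstable_rate = 0.01,
                              msi_h_locus_fraction = 0.4,
                              msi_h_unstable_rate = 0.3,
                              msi_mean_depth = 150,
                              msi_min_depth = 51,
                              n_genes = 289,
                              signature_effect_log2 = 0.8,
                              dispersion = 0.5,
                              seed = 1L) {
  if (is.null(gene_alteration_probs)) {
    gene_alteration_probs <- c(
      TP53 = 0.40, KRAS = 0.33, MUC16 = 0.27, CDKN2A = 0.23, MYC = 0.23,
      CDKN2B = 0.17, SMAD4 = 0.13, ARID1A = 0.15, PBRM1 = 0.10,
      BAP1 = 0.10, ATM = 0.06, BRCA1 = 0.03, BRCA2 = 0.03, PALB2 = 0.02,
      BLM = 0.02, RECQL4 = 0.02, KMT2C = 0.10, SMARCA4 = 0.06
    )
  }
  if (is.null(enrichment_odds)) {
    enr_genes <- intersect(
      c("ATM", "BAP1", "BRCA1", "BRCA2", "PALB2", "BLM", "RECQL4",
        "ARID1A", "PBRM1", "KMT2C", "SMARCA4"),
      names(gene_alteration_probs))
    enrichment_odds <- setNames(rep(5, length(enr_genes)), enr_genes)
  }
  cfg <- list(n_patients = n_patients, accrual_months = accrual_months,
              total_months = total_months,
              median_os_by_group = median_os_by_group,
              median_pfs_by_group = median_pfs_by_group,
              response_prob_by_group = response_prob_by_group,
              sd_frac_nonresponder = sd_frac_nonresponder,
              biomarker_prevalence = biomarker_prevalence,
              gene_alteration_probs = gene_alteration_probs,
              enrichment_odds = enrichment_odds,
              n_msi_loci = n_msi_loci,
              n_baseline_samples = n_baseline_samples,
              baseline_unstable_rate = baseline_unstable_rate,
              msi_h_locus_fraction = msi_h_locus_fraction,
              msi_h_unstable_rate = msi_h_unstable_rate,
              msi_mean_depth = msi_mean_depth,
              msi_min_depth = msi_min_depth,
              n_genes = n_genes,
              signature_effect_log2 = signature_effect_log2,
              dispersion = dispersion,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  probs <- c(cfg$response_prob_by_group, cfg$biomarker_prevalence,
             cfg$baseline_unstable_rate, cfg$msi_h_locus_fraction,
             cfg$msi_h_unstable_rate, cfg$sd_frac_nonresponder,
             cfg$gene_alteration_probs)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (cfg$n_patients < 2) stop("n_patients must be >= 2")
  if (cfg$accrual_months > cfg$total_months)
    stop("accrual_months must not exceed total_months")
  if (any(c(cfg$median_os_by_group, cfg$median_pfs_by_group) <= 0))
    stop("survival medians must be positive")
  if (!all(c("positive", "negative") %in% names(cfg$median_os_by_group)))
    stop("median_os_by_group needs 'positive' and 'negative' entries")
  if (cfg$dispersion <= 0) stop("dispersion must be positive")
  if (cfg$n_msi_loci < 1) stop("n_msi_loci must be >= 1")
  invisible(cfg)
}

# Independent per-generator RNG substream derived from the master seed, so
# adding a generator never perturbs the draws of earlier ones.
.substream_seed <- function(seed, stream_id) {
  as.integer((as.double(seed) * 48271 + stream_id * 16807) %% 2147483647)
}

#' Generate the synthetic clinical cohort table
#'
#' Biomarker statuses are Bernoulli draws at the configured prevalences;
#' the response category is drawn conditionally on the driver biomarker;
#' OS and PFS are independent exponentials with hazard `log(2)/median` of
#' the patient's group; enrolment is uniform over the accrual window and
#' follow-up is administratively censored at `total_months` after study
#' start. Continuous biomarkers (baseline CEA, CD8+ and PD-L1+ cell
#' percentages from immunofluorescence) are drawn with response-linked
#' shifts in the directions seen clinically (higher CEA and lower CD8 in
#' non-responders).
#'
#' @param config a [simulation_config()].
#' @return data.frame with one row per patient: `sample_id`, `group`,
#'   `true_<biomarker>` status columns, `response`, `enrol_month`,
#'   `os_months`, `os_event`, `pfs_months`, `pfs_event`, `cea_ng_ml`,
#'   `cd8_pct`, `pdl1_pct`.
#' @export
generate_cohort <- function(config) {
  validate_simulation_config(config)
  set.seed(.substream_seed(config$seed, 1L))
  n <- config$n_patients
  sample_id <- sprintf("P%03d", seq_len(n))

  status <- sapply(config$biomarker_prevalence,
                   function(p) stats::rbinom(n, 1L, p) == 1L)
  status <- matrix(status, nrow = n,
                   dimnames = list(NULL, names(config$biomarker_prevalence)))
  driver <- names(config$biomarker_prevalence)[1]
  group <- ifelse(status[, driver], "positive", "negative")

  p_resp <- config$response_prob_by_group[group]
  responder <- stats::runif(n) < p_resp
  response <- ifelse(responder, "PR",
                     ifelse(stats::runif(n) < config$sd_frac_nonresponder,
                            "SD", "PD"))

  enrol <- stats::runif(n, 0, config$accrual_months)
  fup <- config$total_months - enrol
  draw_tte <- function(medians) {
    t_true <- stats::rexp(n, rate = log(2) / medians[group])
    if (is.infinite(config$total_months)) {
      list(time = t_true, event = rep(1L, n))
    } else {
      list(time = pmin(t_true, fup), event = as.integer(t_true <= fup))
    }
  }
  os <- draw_tte(config$median_os_by_group)
  pfs <- draw_tte(config$median_pfs_by_group)

  cea <- exp(stats::rnorm(n, mean = ifelse(responder, log(3), log(15)),
                          sd = ifelse(responder, 0.8, 0.9)))
  cd8 <- pmin(100, exp(stats::rnorm(n, mean = ifelse(responder, log(8), log(4)),
                                    sd = 0.5)))
  pdl1 <- pmin(100, exp(stats::rnorm(n, mean = ifelse(responder, log(3), log(1)),
                                     sd = 1)))

  out <- data.frame(sample_id = sample_id, group = group,
                    response = response, enrol_month = enrol,
                    os_months = os$time, os_event = os$event,
                    pfs_months = pfs$time, pfs_event = pfs$event,
                    cea_ng_ml = cea, cd8_pct = cd8, pdl1_pct = pdl1,
                    stringsAsFactors = FALSE)
  for (bm in colnames(status)) out[[paste0("true_", bm)]] <- status[, bm]
  out
}

#' Generate synthetic somatic mutation calls
#'
#' Each gene in `config$gene_alteration_probs` is altered independently per
#' patient. For genes named in `config$enrichment_odds`, the configured
#' probability is the non-responder probability and responders' alteration
#' odds are multiplied by the gene's odds ratio, emulating the enrichment
#' of HRR and chromatin-remodeling hits among responders. Altered genes
#' receive a variant record with a sampled class (SNV/indel/copy-number)
#' and consequence; BRCA1/2 and PALB2 variants may be germline.
#'
#' @param cohort cohort table from [generate_cohort()].
#' @param config a [simulation_config()].
#' @return MAF-like data.frame of variant records (possibly zero rows per
#'   sample); see [read_mutations()] for columns.
#' @export
generate_mutations <- function(cohort, config) {
  validate_simulation_config(config)
  unknown <- setdiff(names(config$enrichment_odds),
                     names(config$gene_alteration_probs))
  if (length(unknown))
    stop("enrichment_odds names unknown gene(s): ",
         paste(unknown, collapse = ", "))
  set.seed(.substream_seed(config$seed, 2L))

  genes <- names(config$gene_alteration_probs)
  responder <- cohort$response %in% c("CR", "PR")
  germline_eligible <- c("BRCA1", "BRCA2", "PALB2")
  rows <- vector("list", 0L)
  for (g in genes) {
    p_n <- config$gene_alteration_probs[[g]]
    or <- config$enrichment_odds[g]
    p_r <- if (is.na(or) || p_n %in% c(0, 1)) p_n else {
      odds <- or * p_n / (1 - p_n); odds / (1 + odds)
    }
    p <- ifelse(responder, p_r, p_n)
    hit <- stats::runif(nrow(cohort)) < p
    if (!any(hit)) next
    ids <- cohort$sample_id[hit]
    k <- length(ids)
    vc <- sample(c("SNV", "INS", "DEL", "CNV_DEL", "CNV_AMP"), k, TRUE,
                 prob = c(0.70, 0.10, 0.10, 0.05, 0.05))
    cons <- character(k)
    is_snv <- vc == "SNV"
    cons[is_snv] <- sample(c("missense", "nonsense", "splice_site",
                             "synonymous", "other"),
                           sum(is_snv), TRUE,
                           prob = c(0.60, 0.15, 0.05, 0.10, 0.10))
    is_indel <- vc %in% c("INS", "DEL")
    cons[is_indel] <- sample(c("frameshift", "other"), sum(is_indel), TRUE,
                             prob = c(0.8, 0.2))
    cons[vc %in% c("CNV_DEL", "CNV_AMP")] <- "other"
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, k, TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    ref[vc == "INS"] <- "A"; alt[vc == "INS"] <- "AAT"
    ref[vc == "DEL"] <- "AAT"; alt[vc == "DEL"] <- "A"
    ref[vc %in% c("CNV_DEL", "CNV_AMP")] <- "."
    alt[vc %in% c("CNV_DEL", "CNV_AMP")] <- "."
    origin <- rep("somatic", k)
    if (g %in% germline_eligible)
      origin[stats::runif(k) < 0.3] <- "germline"
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = ids, gene = g,
      chrom = sample(paste0("chr", 1:22), k, TRUE),
      pos = sample.int(1e8, k, TRUE),
      ref = ref, alt = alt, variant_class = vc, consequence = cons,
      coding_flag = ifelse(vc %in% c("SNV", "INS", "DEL"),
                           stats::runif(k) < 0.95, TRUE),
      origin = origin, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(sample_id = character(), gene = character(),
                      chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      variant_class = character(), consequence = character(),
                      coding_flag = logical(), origin = character(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(out$sample_id, out$gene), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "sample_ids") <- cohort$sample_id
  out
}

#' Generate synthetic microsatellite locus read-support data
#'
#' Builds a panel of mononucleotide repeat loci (single-base repeat units,
#' reference repeat lengths 11-25) with locus-specific baseline
#' unstable-read rates drawn around `baseline_unstable_rate`; generates a
#' stable baseline panel of `n_baseline_samples` background samples and a
#' support table for every cohort sample. Samples listed in
#' `msi_h_sample_ids` have a random `msi_h_locus_fraction` of their loci
#' elevated to `msi_h_unstable_rate` (the trial cohort itself was entirely
#' microsatellite stable, so no cohort sample is MSI-high by default).
#'
#' @param cohort cohort table from [generate_cohort()].
#' @param config a [simulation_config()].
#' @param msi_h_sample_ids sample IDs to simulate as MSI-high.
#' @return list with `baseline` (an `msi_baseline` from [build_baseline()]),
#'   `baseline_panel` and `samples` (locus-support data.frames), and
#'   `loci` (locus metadata incl. the true baseline rate).
#' @export
generate_msi_data <- function(cohort, config, msi_h_sample_ids = character(0)) {
  validate_simulation_config(config)
  if (config$msi_h_unstable_rate <= config$baseline_unstable_rate)
    warning("msi_h_unstable_rate <= baseline_unstable_rate: ",
            "the caller will have no power to detect MSI-high samples")
  bad <- setdiff(msi_h_sample_ids, cohort$sample_id)
  if (length(bad)) stop("unknown msi_h_sample_ids: ", paste(bad, collapse = ", "))
  set.seed(.substream_seed(config$seed, 3L))

  L <- config$n_msi_loci
  kappa <- 200  # concentration of locus-to-locus baseline-rate variation
  p0 <- config$baseline_unstable_rate
  loci <- data.frame(
    locus_id = sprintf("L%03d", seq_len(L)),
    chrom = sample(paste0("chr", 1:22), L, TRUE),
    pos = sample.int(1e8, L, TRUE),
    repeat_unit = sample(c("A", "T"), L, TRUE),
    ref_repeat_length = sample(11:25, L, TRUE),
    true_baseline_rate = stats::rbeta(L, p0 * kappa, (1 - p0) * kappa),
    stringsAsFactors = FALSE)

  draw_support <- function(ids, rate_fun) {
    n <- length(ids)
    depth <- config$msi_min_depth +
      stats::rpois(n * L, max(config$msi_mean_depth - config$msi_min_depth, 0))
    rates <- rate_fun(ids)
    data.frame(
      sample_id = rep(ids, each = L),
      locus_id = rep(loci$locus_id, n),
      chrom = rep(loci$chrom, n), pos = rep(loci$pos, n),
      repeat_unit = rep(loci$repeat_unit, n),
      ref_repeat_length = rep(loci$ref_repeat_length, n),
      depth = depth,
      unstable_count = stats::rbinom(n * L, depth, rates),
      stringsAsFactors = FALSE)
  }
  base_rates <- function(ids) rep(loci$true_baseline_rate, length(ids))
  panel <- draw_support(sprintf("B%03d", seq_len(config$n_baseline_samples)),
                        base_rates)
  cohort_rates <- function(ids) {
    unlist(lapply(ids, function(id) {
      r <- loci$true_baseline_rate
      if (id %in% msi_h_sample_ids) {
        elev <- stats::runif(L) < config$msi_h_locus_fraction
        r[elev] <- config$msi_h_unstable_rate
      }
      r
    }))
  }
  samples <- draw_support(cohort$sample_id, cohort_rates)
  list(baseline = build_baseline(panel),
       baseline_panel = panel, samples = samples, loci = loci)
}

#' Generate a synthetic panel expression count matrix
#'
#' Counts are rounded log-normal: per-gene baseline log2 means are uniform
#' on [4, 10], each sample carries a library-size log2 offset (removed by
#' housekeeping normalization), and gene-level noise has log2 standard
#' deviation `config$dispersion`. Responder columns of genes in
#' `up_shifted_sets` are shifted by `+signature_effect_log2` and genes in
#' `down_shifted_sets` by the negative of it; housekeeping genes are never
#' shifted. Genes are independent — the generator does not emulate
#' inter-gene correlation within the panel.
#'
#' @param cohort cohort table from [generate_cohort()].
#' @param config a [simulation_config()].
#' @param registry gene-set registry supplying `housekeeping` and the
#'   shifted sets; defaults to [default_gene_sets()].
#' @param up_shifted_sets,down_shifted_sets registry set names receiving
#'   the responder shift (up: T-cell / interferon axis; down: mast cells,
#'   which track non-response clinically).
#' @return non-negative integer matrix, genes x samples.
#' @export
generate_expression <- function(cohort, config,
                                registry = default_gene_sets(),
                                up_shifted_sets = c("effector_t_cell_3gene",
                                                    "inflamed_t_cell_18gene",
                                                    "ifng_6gene", "t_cells",
                                                    "cytolytic_activity",
                                                    "chemokine"),
                                down_shifted_sets = "mast_cells") {
  validate_simulation_config(config)
  hk <- get_gene_set(registry, "housekeeping")
  shifted_sets <- c(up_shifted_sets, down_shifted_sets)
  shifted_genes <- unique(unlist(lapply(shifted_sets, get_gene_set,
                                        registry = registry)))
  overlap <- intersect(hk, shifted_genes)
  if (length(overlap))
    stop("housekeeping genes overlap shifted sets: ",
         paste(overlap, collapse = ", "))
  set.seed(.substream_seed(config$seed, 4L))

  panel <- unique(unlist(registry$sets))
  if (config$n_genes < length(panel))
    stop("n_genes (", config$n_genes, ") smaller than registry panel (",
         length(panel), " genes)")
  filler <- sprintf("GENE%04d", seq_len(config$n_genes - length(panel)))
  genes <- c(panel, filler)
  n <- nrow(cohort)

  mu <- stats::runif(length(genes), 4, 10)
  lib <- stats::rnorm(n, 0, 0.3)
  responder <- cohort$response %in% c("CR", "PR")
  up <- unique(unlist(lapply(up_shifted_sets, get_gene_set, registry = registry)))
  down <- unique(unlist(lapply(down_shifted_sets, get_gene_set, registry = registry)))
  shift <- matrix(0, length(genes), n)
  shift[genes %in% up, responder] <- config$signature_effect_log2
  shift[genes %in% down, responder] <- -config$signature_effect_log2

  log2x <- matrix(mu, length(genes), n) +
    matrix(lib, length(genes), n, byrow = TRUE) + shift +
    matrix(stats::rnorm(length(genes) * n, 0, config$dispersion),
           length(genes), n)
  counts <- round(2^log2x)
  dimnames(counts) <- list(genes, cohort$sample_id)
  counts
}

#' Generate a complete synthetic trial dataset
#'
#' Runs all four generators from one configuration; every component shares
#' the cohort's sample identifiers and regeneration with the same config
#' (same seed) is identical.
#'
#' @param config a [simulation_config()].
#' @param registry gene-set registry passed to [generate_expression()].
#' @param msi_h_sample_ids passed to [generate_msi_data()].
#' @return object of class `synthetic_dataset`: list with `cohort`,
#'   `mutations`, `msi`, `expression`, `registry`, `config`.
#' @export
generate_dataset <- function(config = simulation_config(),
                             registry = default_gene_sets(),
                             msi_h_sample_ids = character(0)) {
  cohort <- generate_cohort(config)
  structure(list(
    cohort = cohort,
    mutations = generate_mutations(cohort, config),
    msi = generate_msi_data(cohort, config, msi_h_sample_ids),
    expression = generate_expression(cohort, config, registry),
    registry = registry,
    config = config
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic trial dataset:", nrow(x$cohort), "patients\n")
  cat("  mutations:", nrow(x$mutations), "variant records\n")
  cat("  MSI loci:", nrow(x$msi$loci), "| baseline samples:",
      x$config$n_baseline_samples, "\n")
  cat("  expression:", nrow(x$expression), "genes x",
      ncol(x$expression), "samples\n")
  invisible(x)
}

#' Write a synthetic dataset's components to a directory as TSV/GMT files
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(dataset$cohort, file.path(dir, "cohort.tsv"))
  write_mutations(dataset$mutations, file.path(dir, "mutations.tsv"))
  write_msi_support(dataset$msi$samples, file.path(dir, "msi_support.tsv"))
  write_msi_baseline(dataset$msi$baseline, file.path(dir, "msi_baseline.tsv"))
  write_expression(dataset$expression, file.path(dir, "expression.tsv"))
  write_gmt(dataset$registry, file.path(dir, "genesets.gmt"))
  cfg <- dataset$config
  scalar <- vapply(cfg, function(x) length(x) == 1 && !is.list(x), logical(1))
  lines <- c(
    vapply(names(cfg)[scalar], function(k) paste0(k, ": ", cfg[[k]]), character(1)),
    vapply(names(cfg)[!scalar], function(k)
      paste0(k, ": ", paste(names(cfg[[k]]), unname(cfg[[k]]), sep = "=",
                            collapse = ", ")), character(1)))
  writeLines(lines, file.path(dir, "config.yaml"))
  invisible(dir)
}
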