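#' Pipeline configuration
#'
#' Declares where the data come from (exactly one of a simulation
#' configuration or a set of input file paths), the gene-set registry, the
#' biomarkers to stratify, and every threshold the pipeline applies.
#'
#' @param simulation a [simulation_config()], or `NULL`.
#' @param paths named list of input files (`cohort`, `mutations`,
#'   `msi_support`, `msi_baseline`, `expression`, optionally `genesets`),
#'   or `NULL`. Missing optional components skip their sections.
#' @param registry a [gene_set_registry()].
#' @param biomarkers list of biomarker definitions; each a list with
#'   `name`, `type` (`"gene"`, `"pathway"`, `"tmb"`, `"expression_set"`,
#'   `"continuous"`) and type-specific fields (`gene`/`set`/`column`,
#'   `lof_only`, `cutoff`, `abnormal_is_high`).
#' @param tmb_footprint_mb coding footprint for TMB, Mb.
#' @param msi_alpha,msi_score_threshold MSI caller thresholds.
#' @param cea_cutoff CEA abnormality cutoff, ng/ml; the boundary value is
#'   assigned to the abnormal group (`>=`), configurable via
#'   `cea_boundary_abnormal`.
#' @param cea_boundary_abnormal logical; `FALSE` uses a strict `>`.
#' @param cd8_cutoff,pdl1_cutoff strict-`>` percentages for
#'   [classify_time_quadrant()].
#' @param seed integer seed echoed into the report (the simulation's own
#'   seed governs data generation).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = NULL, paths = NULL,
                            registry = default_gene_sets(),
                            biomarkers = default_biomarkers(),
                            tmb_footprint_mb = 1.0,
                            msi_alpha = 0.001, msi_score_threshold = 20,
                            cea_cutoff = 10, cea_boundary_abnormal = TRUE,
                            cd8_cutoff = 5, pdl1_cutoff = 1,
                            seed = 1L) {
  if (is.null(simulation) == is.null(paths))
    stop("supply exactly one of 'simulation' or 'paths'")
  if (any(c(tmb_footprint_mb, msi_alpha, msi_score_threshold, cea_cutoff,
            cd8_cutoff, pdl1_cutoff) <= 0))
    stop("thresholds must be positive")
  structure(list(simulation = simulation, paths = paths,
                 registry = registry, biomarkers = biomarkers,
                 tmb_footprint_mb = tmb_footprint_mb,
                 msi_alpha = msi_alpha,
                 msi_score_threshold = msi_score_threshold,
                 cea_cutoff = cea_cutoff,
                 cea_boundary_abnormal = cea_boundary_abnormal,
                 cd8_cutoff = cd8_cutoff, pdl1_cutoff = pdl1_cutoff,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Default biomarker panel for the pipeline
#'
#' Mirrors the stratifications of the motivating trial: single genes (ATM,
#' BAP1), HRR pathway alterations, loss-of-function chromatin-remodeling
#' alterations, median-split TMB, median-split expression scores (mast
#' cells, total T cells, HRD transcriptomic, the 3-gene effector and
#' 18-gene inflamed T-cell signatures), abnormal CEA, and median-split
#' CD8+ and PD-L1+ immunofluorescence percentages.
#'
#' @return list of biomarker definitions for [pipeline_config()].
#' @export
default_biomarkers <- function() {
  list(
    list(name = "atm_mutation", type = "gene", gene = "ATM", lof_only = FALSE),
    list(name = "bap1_mutation", type = "gene", gene = "BAP1", lof_only = FALSE),
    list(name = "hrr_pathway", type = "pathway", set = "hrr_pathway",
         lof_only = FALSE),
    list(name = "chromatin_remodeling", type = "pathway",
         set = "chromatin_remodeling", lof_only = TRUE),
    list(name = "tmb_high", type = "tmb"),
    list(name = "mast_cells_high", type = "expression_set", set = "mast_cells"),
    list(name = "t_cells_high", type = "expression_set", set = "t_cells"),
    list(name = "hrd_transcriptomic_high", type = "expression_set",
         set = "hrd_transcriptomic"),
    list(name = "effector_t_cell_3gene_high", type = "expression_set",
         set = "effector_t_cell_3gene"),
    list(name = "inflamed_t_cell_18gene_high", type = "expression_set",
         set = "inflamed_t_cell_18gene"),
    list(name = "cea_abnormal", type = "continuous", column = "cea_ng_ml"),
    list(name = "cd8_high", type = "expression_column", column = "cd8_pct"),
    list(name = "pdl1_high", type = "expression_column", column = "pdl1_pct")
  )
}

.load_pipeline_inputs <- function(config) {
  if (!is.null(config$simulation)) {
    ds <- generate_dataset(config$simulation, config$registry)
    return(list(cohort = ds$cohort, mutations = ds$mutations,
                msi_support = ds$msi$samples, msi_baseline = ds$msi$baseline,
                expression = ds$expression, synthetic = TRUE))
  }
  p <- config$paths
  out <- list(cohort = read_cohort(p$cohort), synthetic = FALSE)
  out$mutations <- if (!is.null(p$mutations)) read_mutations(p$mutations)
  out$msi_support <- if (!is.null(p$msi_support)) read_msi_support(p$msi_support)
  out$msi_baseline <- if (!is.null(p$msi_baseline)) read_msi_baseline(p$msi_baseline)
  out$expression <- if (!is.null(p$expression)) read_expression(p$expression)
  out
}

.check_sample_ids <- function(inputs) {
  ids <- inputs$cohort$sample_id
  check <- function(x, what) {
    if (is.null(x)) return()
    orphans <- setdiff(unique(x), ids)
    if (length(orphans))
      stop(what, " contains sample IDs absent from the cohort: ",
           paste(orphans, collapse = ", "))
  }
  check(inputs$mutations$sample_id, "mutation table")
  check(inputs$msi_support$sample_id, "MSI support table")
  check(colnames(inputs$expression), "expression matrix")
  invisible(TRUE)
}

# Positive/negative status vector (named by sample) for one biomarker.
.biomarker_status <- function(bm, inputs, config, tmb = NULL, scores = NULL) {
  cohort <- inputs$cohort
  ids <- cohort$sample_id
  switch(bm$type,
    gene = {
      if (is.null(inputs$mutations)) return(NULL)
      st <- vapply(ids, function(id)
        classify_gene_status(inputs$mutations[inputs$mutations$sample_id == id, ,
                                              drop = FALSE],
                             bm$gene, lof_only = isTRUE(bm$lof_only)),
        character(1))
      setNames(st == "mutant", ids)
    },
    pathway = {
      if (is.null(inputs$mutations)) return(NULL)
      st <- classify_pathway_cohort(inputs$mutations, ids, bm$set,
                                    config$registry,
                                    lof_only = isTRUE(bm$lof_only))
      setNames(st == "mutant", ids)
    },
    tmb = {
      if (is.null(tmb)) return(NULL)
      setNames(tmb >= tmb_high_threshold(tmb), names(tmb))
    },
    expression_set = {
      if (is.null(scores) || is.null(scores[[bm$set]])) return(NULL)
      sc <- dichotomize_at_median(scores[[bm$set]])
      setNames(sc$split_label == "high", sc$sample_id)[ids]
    },
    continuous = {
      x <- cohort[[bm$column]]
      if (is.null(x)) return(NULL)
      cut <- config$cea_cutoff
      setNames(if (config$cea_boundary_abnormal) x >= cut else x > cut, ids)
    },
    expression_column = {
      x <- cohort[[bm$column]]
      if (is.null(x)) return(NULL)
      sc <- dichotomize_at_median(data.frame(sample_id = ids, score = x))
      setNames(sc$split_label == "high", ids)
    },
    stop("unknown biomarker type: ", bm$type))
}

# Association + survival stratification for one binary status vector.
.stratify <- function(status, cohort) {
  responder <- cohort$response %in% c("CR", "PR")
  pos <- status[cohort$sample_id]
  tab <- c(a = sum(pos & responder), b = sum(pos & !responder),
           c = sum(!pos & responder), d = sum(!pos & !responder))
  fish <- fisher_exact_2x2(tab, odds_ratio = "sample")
  orr <- c(positive = if (sum(pos)) mean(responder[pos]) else NA_real_,
           negative = if (sum(!pos)) mean(responder[!pos]) else NA_real_)
  surv_block <- function(time_col, event_col) {
    a <- data.frame(time = cohort[[time_col]][pos],
                    event = cohort[[event_col]][pos])
    b <- data.frame(time = cohort[[time_col]][!pos],
                    event = cohort[[event_col]][!pos])
    if (nrow(a) == 0 || nrow(b) == 0)
      return(list(median_positive = NA, median_negative = NA,
                  logrank_p = NA_real_, hr = NA_real_,
                  hr_lower = NA_real_, hr_upper = NA_real_))
    lr <- logrank_test(a, b)
    cx <- cox_univariate_hr(data.frame(
      time = cohort[[time_col]], event = cohort[[event_col]],
      group = ifelse(pos, "positive", "negative")))
    # coxph contrasts 'positive' vs 'negative' (sorted levels)
    list(median_positive = km_median(km_estimate(a)),
         median_negative = km_median(km_estimate(b)),
         logrank_p = lr$p, hr = cx$hr, hr_lower = cx$lower,
         hr_upper = cx$upper)
  }
  list(n_positive = sum(pos), n_negative = sum(!pos),
       table_2x2 = tab, fisher_p = fish$p_two_sided,
       odds_ratio = fish$odds_ratio, orr_by_stratum = orr,
       os = surv_block("os_months", "os_event"),
       pfs = surv_block("pfs_months", "pfs_event"))
}

#' Run the end-to-end biomarker pipeline
#'
#' Ingests the cohort and whichever omics inputs are available (or
#' generates them synthetically), derives every configured biomarker,
#' and for each one computes the 2x2 response association (Fisher exact),
#' response rates per stratum, Kaplan-Meier medians, log-rank p and Cox
#' hazard ratio for OS and PFS. Cohort-level ORR/DCR with Clopper-Pearson
#' intervals, overall survival curves, and MSI calls complete the report.
#'
#' @param config a [pipeline_config()].
#' @return object of class `biomarker_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- .load_pipeline_inputs(config)
  .check_sample_ids(inputs)
  cohort <- inputs$cohort
  ids <- cohort$sample_id
  notices <- character()

  tmb <- NULL
  if (!is.null(inputs$mutations)) {
    tmb <- compute_tmb_cohort(inputs$mutations, ids, config$tmb_footprint_mb)
  } else notices <- c(notices, "no mutation input: genomic sections skipped")

  scores <- NULL
  if (!is.null(inputs$expression)) {
    normalized <- normalize_housekeeping(
      inputs$expression, get_gene_set(config$registry, "housekeeping"))
    score_sets <- unique(c("mast_cells", "t_cells", "hrd_transcriptomic",
                           "effector_t_cell_3gene", "inflamed_t_cell_18gene",
                           "ifng_6gene"))
    scores <- setNames(lapply(score_sets, function(s)
      metagene_score(normalized, s, config$registry)), score_sets)
  } else notices <- c(notices, "no expression input: scoring sections skipped")

  msi <- NULL
  if (!is.null(inputs$msi_support) && !is.null(inputs$msi_baseline)) {
    msi <- classify_msi_cohort(inputs$msi_support, inputs$msi_baseline,
                               alpha = config$msi_alpha,
                               score_threshold = config$msi_score_threshold)
  } else notices <- c(notices, "no MSI input: MSI section skipped")

  biomarker_results <- list()
  for (bm in config$biomarkers) {
    status <- .biomarker_status(bm, inputs, config, tmb = tmb, scores = scores)
    if (is.null(status)) {
      notices <- c(notices, paste0("biomarker '", bm$name,
                                   "' skipped (missing input)"))
      next
    }
    biomarker_results[[bm$name]] <- .stratify(status, cohort)
  }

  quadrant <- NULL
  if (all(c("cd8_pct", "pdl1_pct") %in% names(cohort))) {
    quadrant <- classify_time_quadrant(cohort$cd8_pct, cohort$pdl1_pct,
                                       config$cd8_cutoff, config$pdl1_cutoff)
    names(quadrant) <- ids
  }

  structure(list(
    response = response_summary(cohort),
    os_curve = km_estimate(data.frame(time = cohort$os_months,
                                      event = cohort$os_event)),
    pfs_curve = km_estimate(data.frame(time = cohort$pfs_months,
                                       event = cohort$pfs_event)),
    tmb = tmb, msi = msi, scores = scores,
    biomarkers = biomarker_results,
    time_quadrant = quadrant,
    notices = notices,
    provenance = list(seed = config$seed,
                      synthetic = isTRUE(inputs$synthetic),
                      thresholds = config[c("tmb_footprint_mb", "msi_alpha",
                                            "msi_score_threshold", "cea_cutoff",
                                            "cd8_cutoff", "pdl1_cutoff")],
                      package_version = as.character(utils::packageVersion("btcbm")),
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  ), class = "biomarker_report")
}

#' @export
print.biomarker_report <- function(x, ...) {
  r <- x$response
  cat("Biomarker report -", r$n, "patients",
      if (x$provenance$synthetic) "(synthetic cohort)" else "", "\n")
  cat(sprintf("  ORR %.1f%% (95%% CI %.1f-%.1f), DCR %.1f%% (95%% CI %.1f-%.1f)\n",
              100 * r$orr, 100 * r$orr_ci[1], 100 * r$orr_ci[2],
              100 * r$dcr, 100 * r$dcr_ci[1], 100 * r$dcr_ci[2]))
  fmt_med <- function(m) if (is.character(m)) m else sprintf("%.1f", m)
  cat("  median OS:", fmt_med(km_median(x$os_curve)),
      "| median PFS:", fmt_med(km_median(x$pfs_curve)), "months\n")
  if (length(x$biomarkers)) {
    cat("  biomarkers:\n")
    for (nm in names(x$biomarkers)) {
      b <- x$biomarkers[[nm]]
      cat(sprintf("    %-28s n=%2d/%2d  Fisher p=%.3g  OS log-rank p=%.3g\n",
                  nm, b$n_positive, b$n_negative, b$fisher_p, b$os$logrank_p))
    }
  }
  for (msg in x$notices) cat("  note:", msg, "\n")
  invisible(x)
}

#' Write a biomarker report to disk
#'
#' Emits a single JSON report plus sidecar TSVs (biomarker summary table,
#' TMB values, MSI calls).
#'
#' @param report a `biomarker_report`.
#' @param dir output directory (created if absent).
#' @param include_timestamp include the run timestamp in the JSON
#'   (disable for byte-reproducible output).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, include_timestamp = TRUE) {
  stopifnot(inherits(report, "biomarker_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep <- unclass(report)
  rep$os_curve <- as.data.frame(report$os_curve)
  rep$pfs_curve <- as.data.frame(report$pfs_curve)
  if (!include_timestamp) rep$provenance$timestamp <- NULL
  jsonlite::write_json(rep, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (length(report$biomarkers)) {
    tab <- do.call(rbind, lapply(names(report$biomarkers), function(nm) {
      b <- report$biomarkers[[nm]]
      data.frame(biomarker = nm, n_positive = b$n_positive,
                 n_negative = b$n_negative,
                 a = b$table_2x2["a"], b = b$table_2x2["b"],
                 c = b$table_2x2["c"], d = b$table_2x2["d"],
                 fisher_p = b$fisher_p,
                 orr_positive = b$orr_by_stratum["positive"],
                 orr_negative = b$orr_by_stratum["negative"],
                 os_logrank_p = b$os$logrank_p, os_hr = b$os$hr,
                 pfs_logrank_p = b$pfs$logrank_p, pfs_hr = b$pfs$hr,
                 stringsAsFactors = FALSE)
    }))
    rownames(tab) <- NULL
    .write_tsv(tab, file.path(dir, "biomarkers.tsv"))
  }
  if (!is.null(report$tmb))
    .write_tsv(data.frame(sample_id = names(report$tmb),
                          tmb = unname(report$tmb)),
               file.path(dir, "tmb.tsv"))
  if (!is.null(report$msi)) .write_tsv(report$msi, file.path(dir, "msi.tsv"))
  invisible(dir)
}

#' Tumor-immune microenvironment quadrant from CD8 and PD-L1 percentages
#'
#' Classifies each patient by the classical four-quadrant scheme using
#' strict `>` comparisons on both cutoffs: highly infiltrated CD8+ T cells
#' (> `cd8_cut` %) crossed with positive PD-L1 expression (> `pdl1_cut` %).
#'
#' @param cd8_pct,pdl1_pct percentages in [0, 100] (vectorized).
#' @param cd8_cut,pdl1_cut strict cutoffs, percent.
#' @return character vector in `CD8hi_PDL1pos`, `CD8hi_PDL1neg`,
#'   `CD8lo_PDL1pos`, `CD8lo_PDL1neg`.
#' @export
classify_time_quadrant <- function(cd8_pct, pdl1_pct, cd8_cut = 5,
                                   pdl1_cut = 1) {
  if (any(cd8_pct < 0 | cd8_pct > 100 | pdl1_pct < 0 | pdl1_pct > 100))
    stop("percentages must lie in [0, 100]")
  paste0(ifelse(cd8_pct > cd8_cut, "CD8hi", "CD8lo"), "_",
         ifelse(pdl1_pct > pdl1_cut, "PDL1pos", "PDL1neg"))
}
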