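VARIANT_CLASSES <- c("SNV", "INS", "DEL", "CNV_AMP", "CNV_DEL")
CONSEQUENCES <- c("missense", "nonsense", "frameshift", "splice_site",
                  "synonymous", "other")
LOF_CONSEQUENCES <- c("nonsense", "frameshift", "splice_site")
GERMLINE_ELIGIBLE_DEFAULT <- c("BRCA1", "BRCA2", "PALB2")

#' Validate a table of variant records
#'
#' @param variants MAF-like data.frame (see [read_mutations()]).
#' @return the table, invisibly; errors on malformed records.
#' @export
validate_variants <- function(variants) {
  if (nrow(variants) == 0) return(invisible(variants))
  if (any(!variants$variant_class %in% VARIANT_CLASSES))
    stop("unknown variant_class value(s)")
  if (any(!variants$consequence %in% CONSEQUENCES))
    stop("unknown consequence value(s)")
  if (any(variants$pos < 1)) stop("pos must be >= 1 (1-based coordinates)")
  snv <- variants$variant_class == "SNV"
  if (any(nchar(variants$ref[snv]) != 1 | nchar(variants$alt[snv]) != 1))
    stop("SNV records must have single-base ref and alt")
  invisible(variants)
}

#' Tumor mutational burden (mutations per megabase)
#'
#' Counts somatic coding single-nucleotide variants, insertions and
#' deletions — copy-number records never count — and divides by the coding
#' footprint of the panel. Synonymous variants are excluded by default
#' (the usual targeted-panel convention); set `include_synonymous = TRUE`
#' to count them.
#'
#' @param profile variant records of one sample (data.frame; may be empty).
#' @param coding_footprint_mb coding territory of the panel in Mb (> 0).
#' @param include_synonymous count synonymous coding variants too?
#' @return TMB in mutations/Mb.
#' @export
compute_tmb <- function(profile, coding_footprint_mb = 1.0,
                        include_synonymous = FALSE) {
  if (coding_footprint_mb <= 0) stop("coding_footprint_mb must be > 0")
  if (nrow(profile) == 0) return(0.0)
  validate_variants(profile)
  keep <- profile$variant_class %in% c("SNV", "INS", "DEL") &
    profile$coding_flag & profile$origin == "somatic"
  if (!include_synonymous) keep <- keep & profile$consequence != "synonymous"
  sum(keep) / coding_footprint_mb
}

#' Per-sample TMB for a whole cohort
#'
#' @param mutations variant records of all samples.
#' @param sample_ids sample identifiers (so zero-mutation samples get TMB 0).
#' @inheritParams compute_tmb
#' @return named numeric vector of TMB values.
#' @export
compute_tmb_cohort <- function(mutations, sample_ids,
                               coding_footprint_mb = 1.0,
                               include_synonymous = FALSE) {
  vapply(sample_ids, function(id)
    compute_tmb(mutations[mutations$sample_id == id, , drop = FALSE],
                coding_footprint_mb, include_synonymous),
    numeric(1))
}

#' TMB-high threshold: the cohort median
#'
#' TMB-high is defined as the top 50% of the cohort; a sample is high when
#' its value is at or above the returned median.
#'
#' @param tmb_values numeric vector of per-sample TMB (>= 2 values).
#' @return the median threshold.
#' @export
tmb_high_threshold <- function(tmb_values) {
  if (length(tmb_values) < 2) stop("need >= 2 TMB values")
  stats::median(tmb_values)
}

#' Single-gene mutation status
#'
#' A sample is `mutant` for a gene when it carries any non-synonymous
#' coding variant in it (`lof_only = FALSE`), or — for loss-of-function
#' biomarkers such as the chromatin-remodeling genes — any variant with an
#' inactivating consequence (nonsense, frameshift, splice-site) or a
#' copy-number deletion (`lof_only = TRUE`). Germline variants count only
#' for genes in `germline_eligible`.
#'
#' @param profile variant records of one sample.
#' @param gene gene symbol.
#' @param lof_only restrict to inactivating alterations?
#' @param germline_eligible genes whose germline variants count.
#' @return `"mutant"` or `"wild_type"`.
#' @export
classify_gene_status <- function(profile, gene, lof_only = FALSE,
                                 germline_eligible = GERMLINE_ELIGIBLE_DEFAULT) {
  if (!nzchar(gene)) stop("gene symbol must be non-empty")
  v <- profile[profile$gene == gene, , drop = FALSE]
  if (nrow(v) == 0) return("wild_type")
  v <- v[v$origin == "somatic" | gene %in% germline_eligible, , drop = FALSE]
  lof_hit <- v$consequence %in% LOF_CONSEQUENCES | v$variant_class == "CNV_DEL"
  hit <- if (lof_only) lof_hit else {
    lof_hit |
      (v$coding_flag & v$consequence != "synonymous" &
         v$variant_class %in% c("SNV", "INS", "DEL")) |
      v$variant_class %in% c("CNV_DEL", "CNV_AMP")
  }
  if (any(hit)) "mutant" else "wild_type"
}

#' Pathway-level mutation status
#'
#' `mutant` when [classify_gene_status()] is mutant for at least one
#' member gene of the named set.
#'
#' @param profile variant records of one sample.
#' @param set_name gene-set name in `registry`.
#' @param registry a [gene_set_registry()].
#' @inheritParams classify_gene_status
#' @return `"mutant"` or `"wild_type"`.
#' @export
classify_pathway_status <- function(profile, set_name, registry,
                                    lof_only = FALSE,
                                    germline_eligible = GERMLINE_ELIGIBLE_DEFAULT) {
  genes <- get_gene_set(registry, set_name)
  for (g in genes)
    if (classify_gene_status(profile, g, lof_only, germline_eligible) == "mutant")
      return("mutant")
  "wild_type"
}

#' Pathway status for a whole cohort
#'
#' @param mutations variant records of all samples.
#' @param sample_ids sample identifiers.
#' @inheritParams classify_pathway_status
#' @return named character vector (`mutant` / `wild_type`).
#' @export
classify_pathway_cohort <- function(mutations, sample_ids, set_name, registry,
                                    lof_only = FALSE,
                                    germline_eligible = GERMLINE_ELIGIBLE_DEFAULT) {
  vapply(sample_ids, function(id)
    classify_pathway_status(mutations[mutations$sample_id == id, , drop = FALSE],
                            set_name, registry, lof_only, germline_eligible),
    character(1))
}
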