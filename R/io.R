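#' @title Tab-separated readers and writers for the pipeline's file formats
#' @description Plain-TSV interchange: cohort clinical table, MAF-like
#'   mutation calls, per-locus MSI read support, pooled MSI baseline, and
#'   the genes-by-samples expression matrix.
#' @name btcbm-io
NULL

.read_tsv <- function(path, ...) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the cohort clinical table
#'
#' Required columns: `sample_id`, `response` (CR/PR/SD/PD/NE), `os_months`,
#' `os_event`, `pfs_months`, `pfs_event`. Continuous biomarkers
#' (`cea_ng_ml`, `cd8_pct`, `pdl1_pct`) and group labels are carried
#' through untouched.
#'
#' @param path TSV file path.
#' @return data.frame, one row per patient.
#' @export
read_cohort <- function(path) {
  df <- .read_tsv(path)
  need <- c("sample_id", "response", "os_months", "os_event",
            "pfs_months", "pfs_event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort table missing columns: ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_cohort
#' @param cohort cohort data.frame.
#' @export
write_cohort <- function(cohort, path) .write_tsv(cohort, path)

#' Read / write MAF-like somatic mutation calls
#'
#' Columns: `sample_id`, `gene`, `chrom`, `pos` (1-based), `ref`, `alt`,
#' `variant_class` (SNV/INS/DEL/CNV_AMP/CNV_DEL), `consequence`
#' (missense/nonsense/frameshift/splice_site/synonymous/other),
#' `coding_flag` (logical), `origin` (somatic/germline).
#'
#' @param path TSV file path.
#' @return data.frame of variant records.
#' @export
read_mutations <- function(path) {
  df <- .read_tsv(path)
  need <- c("sample_id", "gene", "chrom", "pos", "ref", "alt",
            "variant_class", "consequence", "coding_flag", "origin")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("mutation table missing columns: ", paste(miss, collapse = ", "))
  df$coding_flag <- as.logical(df$coding_flag)
  validate_variants(df)
  df
}

#' @rdname read_mutations
#' @param mutations mutation data.frame.
#' @export
write_mutations <- function(mutations, path) .write_tsv(mutations, path)

#' Read / write per-locus MSI read-support tables
#'
#' Columns: `sample_id`, `locus_id`, `chrom`, `pos`, `repeat_unit` (single
#' base), `ref_repeat_length` (repeat units), `depth`, `unstable_count`
#' (reads with an MSI-high pattern, i.e. an observed repeat length that
#' differs from the reference).
#'
#' @param path TSV file path.
#' @return data.frame of locus support records.
#' @export
read_msi_support <- function(path) {
  df <- .read_tsv(path)
  need <- c("sample_id", "locus_id", "repeat_unit", "ref_repeat_length",
            "depth", "unstable_count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("MSI support table missing columns: ", paste(miss, collapse = ", "))
  if (any(df$unstable_count > df$depth | df$unstable_count < 0))
    stop("unstable_count must lie in [0, depth]")
  df
}

#' @rdname read_msi_support
#' @param support MSI locus-support data.frame.
#' @export
write_msi_support <- function(support, path) .write_tsv(support, path)

#' Read / write a pooled MSI baseline
#'
#' Columns: `locus_id`, `pooled_depth`, `pooled_unstable`, `prior_p`.
#'
#' @param path TSV file path.
#' @return an `msi_baseline` object (see [build_baseline()]).
#' @export
read_msi_baseline <- function(path) {
  df <- .read_tsv(path)
  need <- c("locus_id", "pooled_depth", "pooled_unstable", "prior_p")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("MSI baseline missing columns: ", paste(miss, collapse = ", "))
  structure(list(table = df,
                 n_baseline_samples = attr(df, "n_baseline_samples", exact = TRUE),
                 pseudocount = NA_real_),
            class = "msi_baseline")
}

#' @rdname read_msi_baseline
#' @param baseline an `msi_baseline` object.
#' @export
write_msi_baseline <- function(baseline, path) {
  stopifnot(inherits(baseline, "msi_baseline"))
  .write_tsv(baseline$table, path)
}

#' Read / write a genes-by-samples expression matrix
#'
#' TSV layout: first column `gene`, remaining columns one per sample.
#'
#' @param path TSV file path.
#' @return numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_expression <- function(path) {
  df <- .read_tsv(path)
  if (names(df)[1] != "gene") stop("expression TSV must have a leading 'gene' column")
  if (anyDuplicated(df$gene)) stop("duplicate gene symbols in expression matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression
#' @param mat expression matrix (genes x samples, rownames = genes).
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  .write_tsv(df, path)
}

#' Summary-level counts from the motivating phase II trial
#'
#' Returns the published summary counts of a 30-patient single-arm phase II
#' trial of anti-PD-1 plus gemcitabine/cisplatin in advanced biliary tract
#' cancer: response-category counts, the 2x2 biomarker-by-response tables
#' reported in its figure legends, and the survival design parameters.
#' These are summary statistics (the patient-level data are access
#' restricted) and are the worked-example input for [fisher_exact_2x2()],
#' [response_summary()] and the design functions.
#'
#' @return list with `design` (named numeric), `response_counts` (named
#'   integer), and `tables_2x2` (data.frame: biomarker, a, b, c, d where
#'   rows of each 2x2 are biomarker-positive / negative and columns
#'   responder / non-responder).
#' @export
btc_trial_summary <- function() {
  path <- system.file("extdata", "btc_trial_summary.tsv", package = "btcbm")
  df <- .read_tsv(path)
  tabs <- df[df$section == "table2x2",
             c("name", "a", "b", "c", "d")]
  names(tabs)[1] <- "biomarker"
  rownames(tabs) <- NULL
  resp <- df[df$section == "response", ]
  design <- df[df$section == "design", ]
  list(
    design = setNames(design$a, design$name),
    response_counts = setNames(as.integer(resp$a), resp$name),
    tables_2x2 = tabs
  )
}
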