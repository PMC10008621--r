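#' Housekeeping normalization of panel expression counts
#'
#' Panel-style content normalization: each sample's counts are multiplied
#' by `mean(HK geometric means across samples) / (its own HK geometric
#' mean)`, where HK is the housekeeping gene set. After normalization the
#' housekeeping geometric mean is identical in every sample, and the
#' normalization is invariant to per-sample library scaling.
#'
#' @param raw non-negative count matrix, genes x samples (rownames =
#'   gene symbols).
#' @param hk_set character vector of housekeeping gene symbols; at least 3
#'   must be present in the matrix, each nonzero in every sample.
#' @return normalized matrix with attributes `scale_factors` (named per
#'   sample) and `stage = "normalized"`.
#' @export
normalize_housekeeping <- function(raw, hk_set) {
  hk <- intersect(hk_set, rownames(raw))
  if (length(hk) < 3) stop("need >= 3 housekeeping genes present in the matrix")
  hk_mat <- raw[hk, , drop = FALSE]
  zero_cols <- colnames(raw)[apply(hk_mat == 0, 2, any)]
  if (length(zero_cols))
    stop("housekeeping gene with zero count in sample(s): ",
         paste(zero_cols, collapse = ", "))
  geomeans <- exp(colMeans(log(hk_mat)))
  factors <- mean(geomeans) / geomeans
  out <- sweep(raw, 2, factors, `*`)
  attr(out, "scale_factors") <- factors
  attr(out, "stage") <- "normalized"
  out
}

#' Metagene score of a gene set
#'
#' The score is the log2 geometric mean of the member genes' normalized
#' expression, i.e. the mean of `log2(count + pseudocount)` over the
#' members present in the matrix. Members absent from the matrix are
#' dropped with a warning; a set with no present members is an error.
#'
#' @param normalized normalized expression matrix, genes x samples.
#' @param set_name gene-set name in `registry` (used to label the output;
#'   ignored when `genes` is supplied directly).
#' @param registry a [gene_set_registry()].
#' @param genes optional explicit member vector overriding the registry
#'   lookup.
#' @param pseudocount added before the log (default 1).
#' @return data.frame of class `score_table`: `sample_id`, `score`,
#'   `set_name`.
#' @export
metagene_score <- function(normalized, set_name, registry = NULL,
                           genes = NULL, pseudocount = 1) {
  if (is.null(genes)) genes <- get_gene_set(registry, set_name)
  present <- intersect(genes, rownames(normalized))
  missing <- setdiff(genes, present)
  if (length(present) == 0)
    stop("no member genes of '", set_name, "' present in the matrix")
  if (length(missing))
    warning("set '", set_name, "': dropping ", length(missing),
            " absent gene(s): ", paste(missing, collapse = ", "))
  score <- colMeans(log2(normalized[present, , drop = FALSE] + pseudocount))
  structure(data.frame(sample_id = colnames(normalized),
                       score = unname(score), set_name = set_name,
                       stringsAsFactors = FALSE),
            class = c("score_table", "data.frame"))
}

#' Scores for the immunotherapy-response signature sets
#'
#' Iterates [metagene_score()] over the seven published signature sets
#' (6-gene IFN-gamma, 18-gene inflamed T cell, 3-gene effector T cell,
#' chemokine, cytolytic activity, cytotoxic T cell, angiogenesis).
#'
#' @param normalized normalized expression matrix.
#' @param registry a [gene_set_registry()] containing the signature sets.
#' @param sets signature set names (defaults to the seven).
#' @inheritParams metagene_score
#' @return named list of `score_table`s.
#' @export
signature_scores <- function(normalized, registry,
                             sets = c("ifng_6gene", "inflamed_t_cell_18gene",
                                      "effector_t_cell_3gene", "chemokine",
                                      "cytolytic_activity", "cytotoxic_t_cell",
                                      "angiogenesis"),
                             pseudocount = 1) {
  setNames(lapply(sets, function(s)
    metagene_score(normalized, s, registry, pseudocount = pseudocount)), sets)
}

#' HRD transcriptomic signature score
#'
#' Metagene score over the fixed 7-gene homologous-recombination set (ATM,
#' BLM, BRCA1, BRCA2, BRIP1, NBN, RAD51) — the HRR-pathway genes present
#' on the immune panel.
#'
#' @inheritParams metagene_score
#' @return a `score_table` with `set_name = "hrd_transcriptomic"`.
#' @export
hrd_transcriptomic_score <- function(normalized, registry = default_gene_sets(),
                                     pseudocount = 1) {
  metagene_score(normalized, "hrd_transcriptomic", registry,
                 pseudocount = pseudocount)
}

#' Median-split dichotomization of a score table
#'
#' `high` iff the score is at or above the cohort median (ties go high, so
#' degenerate all-equal input is entirely `high`).
#'
#' @param scores a `score_table` from [metagene_score()], or any
#'   data.frame with `sample_id` and `score` columns (>= 2 rows).
#' @return the table with a `split_label` column added and the threshold
#'   in `attr(, "threshold")`.
#' @export
dichotomize_at_median <- function(scores) {
  if (nrow(scores) < 2) stop("need >= 2 samples to median-split")
  thr <- stats::median(scores$score)
  scores$split_label <- ifelse(scores$score >= thr, "high", "low")
  attr(scores, "threshold") <- thr
  scores
}
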