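#' Microsatellite-instability calling from per-locus read support
#'
#' The caller works on mononucleotide-repeat loci. For every locus it
#' compares the sample's count of unstable reads (reads whose observed
#' repeat length differs from the reference) against the locus's prior
#' unstable-read probability, estimated from a panel of stable baseline
#' samples. A locus is called MSI-high in a sample when the upper binomial
#' tail probability of its unstable count is at or below `alpha`; the
#' sample's MSI score is the percentage of MSI-high loci among the
#' evaluable loci, and the sample is labelled unstable when the score
#' reaches `score_threshold`.
#'
#' @name msi-caller
NULL

#' Filter microsatellite loci for evaluability
#'
#' Keeps mononucleotide loci (single-base repeat unit) whose reference
#' repeat length is at least `min_repeat_length` units and whose depth is
#' at least `min_depth` reads. The defaults encode the strict readings
#' "repeat length exceeds 10" (>= 11) and "depth greater than 50" (>= 51).
#'
#' @param supports locus-support data.frame (see [read_msi_support()]).
#' @param min_repeat_length minimum reference repeat length, units.
#' @param min_depth minimum read depth.
#' @return the eligible subset (possibly empty).
#' @export
filter_loci <- function(supports, min_repeat_length = 11L, min_depth = 51L) {
  if (min_repeat_length < 1 || min_depth < 1) stop("thresholds must be >= 1")
  keep <- supports$ref_repeat_length >= min_repeat_length &
    supports$depth >= min_depth &
    nchar(supports$repeat_unit) == 1L
  supports[keep, , drop = FALSE]
}

#' Estimate per-locus prior unstable-read probabilities from a baseline panel
#'
#' Reads are pooled across baseline samples per locus and smoothed with a
#' symmetric pseudocount (Jeffreys-style, default 0.5):
#' `prior_p = (unstable + pc) / (depth + 2 pc)`, so the prior is strictly
#' inside (0, 1) even for loci with no unstable reads. Loci with zero
#' pooled depth are dropped with a warning.
#'
#' @param panel locus-support data.frame of baseline (stable) samples,
#'   already restricted to eligible loci if desired.
#' @param pseudocount smoothing pseudocount (> 0).
#' @return object of class `msi_baseline`: list with `table` (locus_id,
#'   pooled_depth, pooled_unstable, prior_p), `n_baseline_samples`,
#'   `pseudocount`.
#' @export
build_baseline <- function(panel, pseudocount = 0.5) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (nrow(panel) == 0) stop("empty baseline panel")
  depth <- tapply(panel$depth, panel$locus_id, sum)
  unstable <- tapply(panel$unstable_count, panel$locus_id, sum)
  zero <- depth == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " locus/loci with zero pooled depth")
    depth <- depth[!zero]; unstable <- unstable[!zero]
  }
  tab <- data.frame(locus_id = names(depth),
                    pooled_depth = as.numeric(depth),
                    pooled_unstable = as.numeric(unstable),
                    prior_p = (as.numeric(unstable) + pseudocount) /
                      (as.numeric(depth) + 2 * pseudocount),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 n_baseline_samples = length(unique(panel$sample_id)),
                 pseudocount = pseudocount),
            class = "msi_baseline")
}

#' @export
print.msi_baseline <- function(x, ...) {
  cat("MSI baseline:", nrow(x$table), "loci pooled from",
      x$n_baseline_samples, "samples (pseudocount",
      format(x$pseudocount), ")\n")
  cat("  prior_p range:",
      format(range(x$table$prior_p), digits = 3), "\n")
  invisible(x)
}

#' Upper binomial tail probability of an unstable-read count
#'
#' `P(X >= x)` for `X ~ Binomial(d, p0)`, inclusive of the observed count.
#'
#' @param x observed unstable reads (0 <= x <= d).
#' @param d locus depth.
#' @param p0 locus prior unstable-read probability, in (0, 1).
#' @return tail probability (vectorized over `x`, `d`, `p0`).
#' @export
locus_tail_probability <- function(x, d, p0) {
  if (any(p0 <= 0 | p0 >= 1)) stop("p0 must lie strictly in (0, 1)")
  if (any(x < 0 | x > d)) stop("x must lie in [0, d]")
  stats::pbinom(x - 1, d, p0, lower.tail = FALSE)
}

#' Call one locus MSI-high or stable
#'
#' MSI-high iff the upper tail probability is at or below `alpha`
#' (inclusive comparison).
#'
#' @param support one locus-support row (or vector-compatible columns).
#' @param baseline an `msi_baseline`; loci absent from it cannot be called.
#' @param alpha per-locus significance cutoff.
#' @return `"MSI_H"` or `"stable"` per row.
#' @export
call_locus <- function(support, baseline, alpha = 0.001) {
  stopifnot(inherits(baseline, "msi_baseline"))
  p0 <- baseline$table$prior_p[match(support$locus_id, baseline$table$locus_id)]
  if (anyNA(p0)) stop("locus/loci missing from baseline: ",
                      paste(unique(support$locus_id[is.na(p0)]), collapse = ", "))
  tail <- locus_tail_probability(support$unstable_count, support$depth, p0)
  ifelse(tail <= alpha, "MSI_H", "stable")
}

#' Classify a sample's microsatellite status
#'
#' Applies [filter_loci()], drops (and records) loci absent from the
#' baseline, computes the per-locus binomial tail against the baseline
#' prior, and summarizes: the MSI score is `100 * unstable loci /
#' evaluable loci`, and the sample is `MSI_unstable` when the score is at
#' or above `score_threshold` (else `MSS`).
#'
#' @param supports locus-support data.frame of one sample.
#' @param baseline an `msi_baseline` from [build_baseline()].
#' @param alpha per-locus binomial tail cutoff (inclusive).
#' @param score_threshold MSI-score percentage for the unstable label.
#' @param min_repeat_length,min_depth passed to [filter_loci()].
#' @return object of class `msi_result`: `sample_id`, `n_evaluable_loci`,
#'   `n_unstable_loci`, `msi_score` (percent), `label`, `per_locus`
#'   (locus_id, tail_probability, call), `dropped_loci`.
#' @export
classify_sample <- function(supports, baseline, alpha = 0.001,
                            score_threshold = 20,
                            min_repeat_length = 11L, min_depth = 51L) {
  stopifnot(inherits(baseline, "msi_baseline"))
  sid <- unique(supports$sample_id)
  if (length(sid) > 1) stop("classify_sample expects a single sample")
  elig <- filter_loci(supports, min_repeat_length, min_depth)
  known <- elig$locus_id %in% baseline$table$locus_id
  dropped <- elig$locus_id[!known]
  elig <- elig[known, , drop = FALSE]
  if (nrow(elig) == 0)
    stop("sample ", if (length(sid)) sid else "?",
         " has zero evaluable loci: microsatellite status unevaluable")
  p0 <- baseline$table$prior_p[match(elig$locus_id, baseline$table$locus_id)]
  tail <- locus_tail_probability(elig$unstable_count, elig$depth, p0)
  call <- ifelse(tail <= alpha, "MSI_H", "stable")
  n_unstable <- sum(call == "MSI_H")
  score <- 100 * n_unstable / nrow(elig)
  structure(list(
    sample_id = if (length(sid)) sid else NA_character_,
    n_evaluable_loci = nrow(elig),
    n_unstable_loci = n_unstable,
    msi_score = score,
    label = if (score >= score_threshold) "MSI_unstable" else "MSS",
    per_locus = data.frame(locus_id = elig$locus_id,
                           tail_probability = tail, call = call,
                           stringsAsFactors = FALSE),
    dropped_loci = dropped,
    alpha = alpha, score_threshold = score_threshold
  ), class = "msi_result")
}

#' @export
print.msi_result <- function(x, ...) {
  cat("MSI call for sample", x$sample_id, "\n")
  cat(sprintf("  %d / %d evaluable loci MSI-high -> score %.1f%% -> %s\n",
              x$n_unstable_loci, x$n_evaluable_loci, x$msi_score, x$label))
  if (length(x$dropped_loci))
    cat("  dropped (absent from baseline):", length(x$dropped_loci), "loci\n")
  invisible(x)
}

#' MSI status for a whole cohort
#'
#' @param supports locus-support data.frame of all samples.
#' @inheritParams classify_sample
#' @return data.frame: sample_id, n_evaluable_loci, n_unstable_loci,
#'   msi_score, label.
#' @export
classify_msi_cohort <- function(supports, baseline, alpha = 0.001,
                                score_threshold = 20,
                                min_repeat_length = 11L, min_depth = 51L) {
  ids <- unique(supports$sample_id)
  res <- lapply(ids, function(id)
    classify_sample(supports[supports$sample_id == id, , drop = FALSE],
                    baseline, alpha, score_threshold,
                    min_repeat_length, min_depth))
  data.frame(sample_id = ids,
             n_evaluable_loci = vapply(res, `[[`, 0L, "n_evaluable_loci"),
             n_unstable_loci = vapply(res, `[[`, 0L, "n_unstable_loci"),
             msi_score = vapply(res, `[[`, 0, "msi_score"),
             label = vapply(res, `[[`, "", "label"),
             stringsAsFactors = FALSE)
}
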