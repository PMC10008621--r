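#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test with fixed margins. The two-sided p-value is
#' the sum of the probabilities of all tables (under the fixed margins)
#' whose probability does not exceed the observed table's probability,
#' with a 1e-7 relative slack in the comparison — the dominant
#' "probability-at-most-observed" convention. A zero margin gives p = 1
#' by convention, flagged in the method note.
#'
#' @param table 2x2 matrix or length-4 vector `c(a, b, c, d)` read
#'   row-wise: rows biomarker-positive/negative, columns
#'   responder/non-responder.
#' @param odds_ratio `"cmle"` (conditional MLE, via [stats::fisher.test()]),
#'   `"sample"` (ad/bc), or `"none"`.
#' @return list of class `association_result`: `p_two_sided`,
#'   `odds_ratio`, `table`, `method`.
#' @export
fisher_exact_2x2 <- function(table, odds_ratio = c("cmle", "sample", "none")) {
  odds_ratio <- match.arg(odds_ratio)
  m <- if (is.matrix(table)) table else
    matrix(as.numeric(table), 2, 2, byrow = TRUE)
  if (!all(dim(m) == c(2, 2))) stop("need a 2x2 table")
  storage.mode(m) <- "double"
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
  note <- "two-sided Fisher exact (probability-at-most-observed rule)"
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    p <- 1
    note <- paste(note, "- degenerate zero margin, p = 1 by convention")
  } else {
    p <- .fisher_p(a, b, cc, d)
  }
  or <- switch(odds_ratio,
               cmle = unname(stats::fisher.test(m)$estimate),
               sample = (a * d) / (b * cc),
               none = NA_real_)
  structure(list(p_two_sided = p, odds_ratio = or, table = m, method = note),
            class = "association_result")
}

# Hypergeometric enumeration of the two-sided p for fixed margins.
.fisher_p <- function(a, b, cc, d) {
  r1 <- a + b; c1 <- a + cc; n <- a + b + cc + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, n - r1, c1)
  obs <- stats::dhyper(a, r1, n - r1, c1)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

#' @export
print.association_result <- function(x, ...) {
  cat("2x2 exact association test\n")
  print(x$table)
  cat(sprintf("  p (two-sided) = %.4g; odds ratio = %.3g\n",
              x$p_two_sided, x$odds_ratio))
  cat(" ", x$method, "\n")
  invisible(x)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Inverse incomplete-beta bounds: lower = `qbeta(alpha/2, k, n-k+1)`
#' (0 when k = 0), upper = `qbeta(1-alpha/2, k+1, n-k)` (1 when k = n).
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (>= 1).
#' @param conf confidence level.
#' @return named numeric `c(lower, upper)`.
#' @export
clopper_pearson <- function(k, n, conf = 0.95) {
  if (n < 1 || k < 0 || k > n || k != round(k) || n != round(n))
    stop("need integers 0 <= k <= n, n >= 1")
  alpha <- 1 - conf
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Objective response and disease control rates with exact intervals
#'
#' ORR = (CR + PR) / n, DCR = (CR + PR + SD) / n, each with a
#' Clopper-Pearson interval. Patients not evaluable (NE) stay in the
#' denominator (intention-to-treat).
#'
#' @param cohort cohort data.frame with a `response` column whose values
#'   are in CR/PR/SD/PD/NE.
#' @param conf confidence level for the intervals.
#' @return list: `n`, `counts` (by category), `orr`, `orr_ci`, `dcr`,
#'   `dcr_ci` (rates as proportions in [0, 1]).
#' @export
response_summary <- function(cohort, conf = 0.95) {
  if (nrow(cohort) == 0) stop("empty cohort")
  resp <- cohort$response
  bad <- setdiff(unique(resp), c("CR", "PR", "SD", "PD", "NE"))
  if (length(bad)) stop("unknown response categories: ", paste(bad, collapse = ", "))
  n <- length(resp)
  counts <- table(factor(resp, levels = c("CR", "PR", "SD", "PD", "NE")))
  k_orr <- sum(resp %in% c("CR", "PR"))
  k_dcr <- sum(resp %in% c("CR", "PR", "SD"))
  list(n = n, counts = counts,
       orr = k_orr / n, orr_ci = clopper_pearson(k_orr, n, conf),
       dcr = k_dcr / n, dcr_ci = clopper_pearson(k_dcr, n, conf))
}

#' Wilcoxon rank-sum comparison of two score vectors
#'
#' Mid-ranks for ties; the exact distribution when the smaller sample has
#' at most `exact_max` observations and there are no ties, otherwise the
#' normal approximation with continuity correction.
#'
#' @param x,y numeric vectors (non-empty).
#' @param exact_max largest min-group size for the exact p.
#' @return list: `statistic` (rank-sum W for `x`), `p`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 10) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1)
    return(list(statistic = length(x) * length(y) / 2, p = 1, exact = FALSE))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && min(length(x), length(y)) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value, exact = exact)
}
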