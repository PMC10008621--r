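# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths (and where possible the distribution functions) that
# the package itself uses.

# Two-sided Fisher p by explicit enumeration over all tables with the
# observed margins, using log-binomial coefficients directly.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  p_obs <- exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1))
  min(1, sum(exp(logp)[exp(logp) <= p_obs * (1 + 1e-7)]))
}

# Upper binomial tail P(X >= x) by direct term-by-term summation in
# log space (no pbinom).
oracle_binom_tail <- function(x, d, p0) {
  if (x <= 0) return(1)
  k <- x:d
  sum(exp(lchoose(d, k) + k * log(p0) + (d - k) * log1p(-p0)))
}

# Hand-computed two-group log-rank chi-square from the O/E table.
oracle_logrank_chi2 <- function(time1, event1, time2, event2) {
  times <- sort(unique(c(time1[event1 == 1], time2[event2 == 1])))
  O1 <- E1 <- V <- 0
  for (t in times) {
    n1 <- sum(time1 >= t); n2 <- sum(time2 >= t); n <- n1 + n2
    d1 <- sum(time1 == t & event1 == 1)
    d2 <- sum(time2 == t & event2 == 1)
    d <- d1 + d2
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Clopper-Pearson bounds by bisection on the binomial tail equalities,
# not via beta quantiles.
oracle_cp_bisect <- function(k, n, conf = 0.95, tol = 1e-10) {
  alpha <- 1 - conf
  bisect <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (k == 0) 0 else
    bisect(function(p) sum(dbinom(k:n, n, p)) - alpha / 2, 0, 1)
  upper <- if (k == n) 1 else
    bisect(function(p) -(sum(dbinom(0:k, n, p)) - alpha / 2), 0, 1)
  c(lower = lower, upper = upper)
}

# Agreement with a published p-value at its printed precision: within half
# a unit in the last printed digit (with a whisker of slack for values that
# sit exactly on a rounding boundary).
expect_printed <- function(p, printed) {
  digits <- max(nchar(sub(".*\\.", "", format(printed))), 1)
  expect_lt(abs(p - printed), 0.55 * 10^-digits)
}

# Small, fast simulation configuration for structural tests.
fast_config <- function(seed = 1, ...) {
  simulation_config(n_patients = 12, n_msi_loci = 20,
                    n_baseline_samples = 30, n_genes = 160,
                    msi_mean_depth = 80, seed = seed, ...)
}

# Minimal variant-record constructor for genomics tests.
variant <- function(sample_id = "S1", gene = "ATM", variant_class = "SNV",
                    consequence = "missense", coding_flag = TRUE,
                    origin = "somatic", ref = "A", alt = "G") {
  data.frame(sample_id = sample_id, gene = gene, chrom = "chr1", pos = 100L,
             ref = ref, alt = alt, variant_class = variant_class,
             consequence = consequence, coding_flag = coding_flag,
             origin = origin, stringsAsFactors = FALSE)
}

empty_profile <- function() variant()[0, ]

# Locus-support row constructor for MSI tests.
locus_row <- function(sample_id = "S1", locus_id = "L1", repeat_unit = "A",
                      ref_repeat_length = 15L, depth = 100L,
                      unstable_count = 0L) {
  data.frame(sample_id = sample_id, locus_id = locus_id, chrom = "chr1",
             pos = 1000L, repeat_unit = repeat_unit,
             ref_repeat_length = ref_repeat_length, depth = depth,
             unstable_count = unstable_count, stringsAsFactors = FALSE)
}
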