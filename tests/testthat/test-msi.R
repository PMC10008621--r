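test_that("locus filtering applies strict length and depth thresholds", {
  sup <- rbind(locus_row(locus_id = "L1", ref_repeat_length = 10L, depth = 200L),
               locus_row(locus_id = "L2", ref_repeat_length = 15L, depth = 50L),
               locus_row(locus_id = "L3", ref_repeat_length = 11L, depth = 51L),
               locus_row(locus_id = "L4", repeat_unit = "AT"))
  kept <- filter_loci(sup)
  expect_identical(kept$locus_id, "L3")
  expect_error(filter_loci(sup, min_repeat_length = 0), ">= 1")
})

test_that("baseline priors pool reads across samples with pseudocount smoothing", {
  one <- locus_row(depth = 1000L, unstable_count = 10L)
  b1 <- build_baseline(one)
  expect_equal(b1$table$prior_p, 10.5 / 1001)

  zero <- locus_row(depth = 500L, unstable_count = 0L)
  expect_gt(build_baseline(zero)$table$prior_p, 0)

  two <- rbind(locus_row(sample_id = "B1", depth = 500L, unstable_count = 5L),
               locus_row(sample_id = "B2", depth = 500L, unstable_count = 5L))
  expect_equal(build_baseline(two)$table$prior_p, b1$table$prior_p)

  dead <- rbind(one, locus_row(locus_id = "L9", depth = 0L, unstable_count = 0L))
  expect_warning(b <- build_baseline(dead), "zero pooled depth")
  expect_false("L9" %in% b$table$locus_id)
})

test_that("binomial tail probability matches direct summation to 1e-9", {
  expect_equal(locus_tail_probability(0, 100, 0.01), 1.0)
  expect_equal(locus_tail_probability(20, 20, 0.5), 0.5^20)
  expect_equal(locus_tail_probability(10, 100, 0.01),
               oracle_binom_tail(10, 100, 0.01), tolerance = 1e-9)
  set.seed(12)
  for (d in c(5, 60, 200, 500)) {
    for (x in unique(c(0, 1, sample(0:d, 4)))) {
      for (p0 in c(0.005, 0.02, 0.3)) {
        got <- locus_tail_probability(x, d, p0)
        want <- oracle_binom_tail(x, d, p0)
        if (want > 1e-290) expect_lt(abs(got / want - 1), 1e-9)
        else expect_lt(got, 1e-290)  # both beyond double underflow
      }
    }
  }
  expect_error(locus_tail_probability(5, 10, 0), "p0")
  expect_error(locus_tail_probability(11, 10, 0.1), "x must lie")
})

test_that("locus calls use an inclusive alpha and are monotone in the count", {
  panel <- locus_row(sample_id = "B1", depth = 10000L, unstable_count = 100L)
  base <- build_baseline(panel)
  p0 <- base$table$prior_p
  x <- 5L
  tail_x <- locus_tail_probability(x, 100, p0)
  sup <- locus_row(depth = 100L, unstable_count = x)
  # alpha exactly equal to the tail probability: still MSI-high (<= rule)
  expect_identical(unname(call_locus(sup, base, alpha = tail_x)), "MSI_H")
  expect_identical(unname(call_locus(sup, base, alpha = tail_x * 0.999)),
                   "stable")
  expect_identical(unname(call_locus(locus_row(unstable_count = 0L), base)),
                   "stable")
  tails <- locus_tail_probability(0:100, 100, p0)
  expect_true(all(diff(tails) <= 0))  # more unstable reads never rescue a call
  expect_error(call_locus(locus_row(locus_id = "LX"), base), "missing from baseline")
})

test_that("sample classification scores and labels follow the 20% rule", {
  panel <- do.call(rbind, lapply(1:30, function(i)
    locus_row(sample_id = "B1", locus_id = sprintf("L%02d", i),
              depth = 5000L, unstable_count = 50L)))
  base <- build_baseline(panel)
  sup <- do.call(rbind, lapply(1:30, function(i)
    locus_row(locus_id = sprintf("L%02d", i), depth = 100L,
              unstable_count = if (i <= 7) 30L else 1L)))
  res <- classify_sample(sup, base)
  expect_equal(res$n_evaluable_loci, 30)
  expect_equal(res$n_unstable_loci, 7)
  expect_equal(res$msi_score, 100 * 7 / 30, tolerance = 1e-12)
  expect_identical(res$label, "MSI_unstable")

  quiet <- sup; quiet$unstable_count <- 0L
  res0 <- classify_sample(quiet, base)
  expect_equal(res0$msi_score, 0)
  expect_identical(res0$label, "MSS")

  shuffled <- sup[sample(nrow(sup)), ]
  res_sh <- classify_sample(shuffled, base)
  expect_equal(res_sh$msi_score, res$msi_score)
  expect_identical(res_sh$label, res$label)

  shallow <- sup; shallow$depth <- 10L
  expect_error(classify_sample(shallow, base), "unevaluable")
})

test_that("per-locus type-I error stays at alpha on baseline-like samples", {
  set.seed(99)
  n_loci <- 50; n_test <- 2000          # 1e5 locus tests
  true_p <- rbeta(n_loci, 2, 198)       # heterogeneous loci around 1%
  pool_depth <- rpois(n_loci, 3e4)
  panel <- data.frame(sample_id = "pool", locus_id = sprintf("L%03d", 1:n_loci),
                      chrom = "chr1", pos = 1L, repeat_unit = "A",
                      ref_repeat_length = 15L, depth = pool_depth,
                      unstable_count = rbinom(n_loci, pool_depth, true_p))
  base <- build_baseline(panel)
  depth <- 51L + rpois(n_loci * n_test, 100)
  x <- rbinom(n_loci * n_test, depth, rep(true_p, n_test))
  p0 <- base$table$prior_p[rep(1:n_loci, n_test)]
  calls <- locus_tail_probability(x, depth, p0) <= 0.001
  rate <- mean(calls)
  expect_lte(rate, 0.001 + 3 * sqrt(0.001 * 0.999 / (n_loci * n_test)))
})

test_that("synthetic MSI-high and stable samples are separated by the caller", {
  cfg <- fast_config(seed = 23)
  cohort <- generate_cohort(cfg)
  msi <- generate_msi_data(cohort, cfg,
                           msi_h_sample_ids = cohort$sample_id[1:3])
  res <- classify_msi_cohort(msi$samples, msi$baseline)
  expect_identical(res$label[match(cohort$sample_id[1:3], res$sample_id)],
                   rep("MSI_unstable", 3))
  expect_true(all(res$label[!res$sample_id %in% cohort$sample_id[1:3]] == "MSS"))
  expect_true(all(res$msi_score >= 0 & res$msi_score <= 100))
})
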