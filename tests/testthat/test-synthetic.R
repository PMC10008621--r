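test_that("all four generators are deterministic under a fixed seed", {
  cfg <- fast_config(seed = 42)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$cohort, ds2$cohort)
  expect_identical(ds1$mutations, ds2$mutations)
  expect_identical(ds1$msi$samples, ds2$msi$samples)
  expect_identical(ds1$msi$baseline$table, ds2$msi$baseline$table)
  expect_identical(ds1$expression, ds2$expression)
})

test_that("dataset components share the cohort's sample identifiers", {
  ds <- generate_dataset(fast_config(seed = 3))
  ids <- ds$cohort$sample_id
  expect_true(all(ds$mutations$sample_id %in% ids))
  expect_setequal(unique(ds$msi$samples$sample_id), ids)
  expect_identical(colnames(ds$expression), ids)
})

test_that("empirical event fraction matches the uniform-accrual exponential value", {
  # analytic P(event) = 1 - (e^{-l(T-A)} - e^{-lT})/(lA), l = ln2/16;
  # cross-checked against a numerical integration oracle over entry times
  lam <- log(2) / 16
  p_analytic <- 1 - (exp(-lam * 24) - exp(-lam * 48)) / (lam * 24)
  p_oracle <- 1 - integrate(function(u) exp(-lam * (48 - u)) / 24, 0, 24)$value
  expect_equal(p_analytic, p_oracle, tolerance = 1e-8)

  cfg <- simulation_config(n_patients = 1e4,
                           median_os_by_group = c(positive = 16, negative = 16),
                           seed = 11)
  cohort <- generate_cohort(cfg)
  se <- sqrt(p_analytic * (1 - p_analytic) / 1e4)
  expect_lt(abs(mean(cohort$os_event) - p_analytic), 3 * se)
})

test_that("disabling censoring yields events for every patient", {
  cfg <- fast_config(seed = 5, total_months = Inf)
  cohort <- generate_cohort(cfg)
  expect_true(all(cohort$os_event == 1))
  expect_true(all(cohort$pfs_event == 1))
})

test_that("conditional response frequencies converge to the configured probabilities", {
  cfg <- simulation_config(n_patients = 1e4, seed = 21)
  cohort <- generate_cohort(cfg)
  for (g in c("positive", "negative")) {
    sel <- cohort$group == g
    p <- cfg$response_prob_by_group[[g]]
    phat <- mean(cohort$response[sel] == "PR")
    expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / sum(sel)))
  }
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_patients = 1), "n_patients")
  expect_error(simulation_config(accrual_months = 50, total_months = 48),
               "accrual")
  expect_error(simulation_config(
    median_os_by_group = c(positive = -1, negative = 9.5)), "positive")
  expect_error(simulation_config(baseline_unstable_rate = 1.5), "probabilities")
})

test_that("zero alteration probabilities give empty mutation profiles", {
  cfg <- fast_config(seed = 2,
                     gene_alteration_probs = c(TP53 = 0, KRAS = 0),
                     enrichment_odds = c(TP53 = 5))
  muts <- generate_mutations(generate_cohort(cfg), cfg)
  expect_equal(nrow(muts), 0)
})

test_that("unknown gene in the enrichment map is an error", {
  cfg <- fast_config(seed = 2, gene_alteration_probs = c(TP53 = 0.3),
                     enrichment_odds = c(NOTAGENE = 5))
  expect_error(generate_mutations(generate_cohort(cfg), cfg), "NOTAGENE")
})

test_that("responder enrichment reproduces the configured odds ratio", {
  # closed form: non-responder p = 0.2, OR 5 => responder p = 1/1.8*... = 5/9
  p_n <- 0.2; or <- 5
  p_r <- or * p_n / (1 - p_n) / (1 + or * p_n / (1 - p_n))
  cfg <- simulation_config(n_patients = 1e4,
                           response_prob_by_group = c(positive = 0.5, negative = 0.5),
                           gene_alteration_probs = c(GENEX = p_n),
                           enrichment_odds = c(GENEX = or), seed = 31)
  cohort <- generate_cohort(cfg)
  muts <- generate_mutations(cohort, cfg)
  mutant <- cohort$sample_id %in% muts$sample_id
  resp <- cohort$response == "PR"
  phat_r <- mean(mutant[resp]); phat_n <- mean(mutant[!resp])
  expect_lt(abs(phat_r - p_r), 3 * sqrt(p_r * (1 - p_r) / sum(resp)))
  expect_lt(abs(phat_n - p_n), 3 * sqrt(p_n * (1 - p_n) / sum(!resp)))
})

test_that("MSI generator respects count bounds and warns on powerless settings", {
  cfg <- fast_config(seed = 7)
  cohort <- generate_cohort(cfg)
  msi <- generate_msi_data(cohort, cfg)
  expect_true(all(msi$samples$unstable_count <= msi$samples$depth))
  expect_true(all(msi$baseline_panel$unstable_count >= 0))
  expect_true(all(msi$samples$depth >= cfg$msi_min_depth))

  cfg_flat <- fast_config(seed = 7, msi_h_unstable_rate = 0.005)
  expect_warning(generate_msi_data(cohort, cfg_flat), "power")
})

test_that("a zero MSI-H locus fraction leaves samples baseline-like", {
  cfg <- fast_config(seed = 9, msi_h_locus_fraction = 0)
  cohort <- generate_cohort(cfg)
  msi <- generate_msi_data(cohort, cfg, msi_h_sample_ids = cohort$sample_id[1])
  res <- classify_sample(
    msi$samples[msi$samples$sample_id == cohort$sample_id[1], ],
    msi$baseline)
  expect_identical(res$label, "MSS")
})

test_that("a zero signature effect leaves responder scores centred at zero,
           and a unit effect is recovered", {
  for (eff in c(0, 1)) {
    cfg <- simulation_config(
      n_patients = 400,
      response_prob_by_group = c(positive = 0.5, negative = 0.5),
      signature_effect_log2 = eff, n_genes = 160, seed = 13 + eff)
    cohort <- generate_cohort(cfg)
    expr <- generate_expression(cohort, cfg)
    norm <- normalize_housekeeping(expr,
                                   get_gene_set(default_gene_sets(), "housekeeping"))
    sc <- metagene_score(norm, "effector_t_cell_3gene", default_gene_sets())
    resp <- cohort$response == "PR"
    tt <- t.test(sc$score[resp], sc$score[!resp])
    diff <- unname(tt$estimate[1] - tt$estimate[2])
    expect_lt(abs(diff - eff), 3 * tt$stderr)
  }
})

test_that("housekeeping genes overlapping shifted sets are rejected", {
  reg <- gene_set_registry(list(
    housekeeping = c("ACTB", "GAPDH", "TUBB", "CD8A"),
    effector_t_cell_3gene = c("CD8A", "GZMB", "PRF1"),
    inflamed_t_cell_18gene = c("STAT1", "IDO1"), ifng_6gene = c("IFNG", "CXCL9"),
    t_cells = c("CD3D"), cytolytic_activity = c("GZMA", "PRF1"),
    chemokine = c("CCL2"), mast_cells = c("TPSAB1")))
  cfg <- fast_config(seed = 2)
  expect_error(generate_expression(generate_cohort(cfg), cfg, registry = reg),
               "overlap")
})

test_that("writing a dataset round-trips through the TSV readers", {
  ds <- generate_dataset(fast_config(seed = 17))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  cohort <- read_cohort(file.path(dir, "cohort.tsv"))
  expect_equal(cohort$sample_id, ds$cohort$sample_id)
  expect_equal(cohort$os_months, ds$cohort$os_months, tolerance = 1e-6)
  muts <- read_mutations(file.path(dir, "mutations.tsv"))
  expect_equal(nrow(muts), nrow(ds$mutations))
  expr <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(expr, ds$expression, ignore_attr = TRUE)
  reg <- read_gmt(file.path(dir, "genesets.gmt"))
  expect_identical(reg$sets, ds$registry$sets)
})
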