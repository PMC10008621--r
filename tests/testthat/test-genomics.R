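test_that("TMB counts coding somatic SNV/indel per megabase", {
  prof <- rbind(
    variant(consequence = "missense"),
    variant(gene = "TP53", consequence = "nonsense"),
    variant(gene = "KRAS", variant_class = "INS", consequence = "frameshift",
            ref = "A", alt = "AAT"),
    variant(gene = "BRCA1", variant_class = "DEL", consequence = "frameshift",
            ref = "AAT", alt = "A"),
    variant(gene = "MYC", consequence = "missense"),
    variant(gene = "MUC16", consequence = "other"),
    variant(gene = "SMAD4", consequence = "splice_site"))
  expect_equal(compute_tmb(prof, coding_footprint_mb = 2.0), 3.5)
  expect_equal(compute_tmb(empty_profile(), 2.0), 0.0)
  expect_error(compute_tmb(prof, 0), "footprint")
})

test_that("copy-number, synonymous, non-coding and germline records never count toward TMB", {
  cnv <- rbind(variant(variant_class = "CNV_DEL", consequence = "other",
                       ref = ".", alt = "."),
               variant(gene = "MYC", variant_class = "CNV_AMP",
                       consequence = "other", ref = ".", alt = "."))
  expect_equal(compute_tmb(cnv, 1.0), 0.0)
  syn <- variant(consequence = "synonymous")
  expect_equal(compute_tmb(syn, 1.0), 0.0)
  expect_equal(compute_tmb(syn, 1.0, include_synonymous = TRUE), 1.0)
  expect_equal(compute_tmb(variant(coding_flag = FALSE), 1.0), 0.0)
  expect_equal(compute_tmb(variant(gene = "BRCA1", origin = "germline"), 1.0), 0.0)
})

test_that("TMB is additive over disjoint variant subsets and scale-inverse in footprint", {
  set.seed(4)
  prof <- do.call(rbind, lapply(1:20, function(i)
    variant(gene = paste0("G", i),
            variant_class = sample(c("SNV", "INS", "DEL", "CNV_DEL"), 1),
            consequence = sample(c("missense", "synonymous", "frameshift",
                                   "other"), 1),
            coding_flag = sample(c(TRUE, FALSE), 1))))
  prof$ref[prof$variant_class != "SNV"] <- "."
  prof$alt[prof$variant_class != "SNV"] <- "."
  split_at <- 8
  expect_equal(compute_tmb(prof, 1),
               compute_tmb(prof[1:split_at, ], 1) +
                 compute_tmb(prof[-(1:split_at), ], 1))
  expect_equal(compute_tmb(prof, 4), compute_tmb(prof, 1) / 4)
})

test_that("TMB-high threshold is the cohort median with an at-or-above rule", {
  expect_equal(tmb_high_threshold(c(1, 2, 3, 4)), 2.5)
  thr <- tmb_high_threshold(c(1, 2, 3, 4))
  expect_identical(c(1, 2, 3, 4) >= thr, c(FALSE, FALSE, TRUE, TRUE))
  all_equal <- rep(3.2, 5)
  expect_true(all(all_equal >= tmb_high_threshold(all_equal)))
  expect_error(tmb_high_threshold(3.2), ">= 2")
})

test_that("single-gene status distinguishes any-alteration from loss-of-function", {
  fs <- variant(variant_class = "DEL", consequence = "frameshift",
                ref = "AAT", alt = "A")
  expect_identical(classify_gene_status(fs, "ATM"), "mutant")
  expect_identical(classify_gene_status(fs, "ATM", lof_only = TRUE), "mutant")
  syn <- variant(consequence = "synonymous")
  expect_identical(classify_gene_status(syn, "ATM"), "wild_type")
  mis <- variant(consequence = "missense")
  expect_identical(classify_gene_status(mis, "ATM", lof_only = TRUE), "wild_type")
  expect_identical(classify_gene_status(mis, "ATM"), "mutant")
  del <- variant(variant_class = "CNV_DEL", consequence = "other",
                 ref = ".", alt = ".")
  expect_identical(classify_gene_status(del, "ATM", lof_only = TRUE), "mutant")
  expect_identical(classify_gene_status(empty_profile(), "ATM"), "wild_type")
})

test_that("germline variants count only for germline-eligible genes", {
  g_brca <- variant(gene = "BRCA1", origin = "germline",
                    consequence = "nonsense")
  g_atm <- variant(gene = "ATM", origin = "germline", consequence = "nonsense")
  expect_identical(classify_gene_status(g_brca, "BRCA1"), "mutant")
  expect_identical(classify_gene_status(g_atm, "ATM"), "wild_type")
})

test_that("pathway status is mutant iff any member gene is mutant", {
  reg <- default_gene_sets()
  bap1 <- variant(gene = "BAP1", consequence = "nonsense")
  expect_identical(classify_pathway_status(bap1, "hrr_pathway", reg), "mutant")
  expect_identical(classify_pathway_status(empty_profile(), "hrr_pathway", reg),
                   "wild_type")
  toy <- gene_set_registry(list(setX = c("g1", "g2")))
  g2 <- variant(gene = "g2", consequence = "missense")
  expect_identical(classify_pathway_status(g2, "setX", toy), "mutant")
  expect_error(classify_pathway_status(g2, "nope", toy), "unknown gene set")
})

test_that("pathway status is monotone and loss-of-function implies any-alteration", {
  reg <- gene_set_registry(list(s = paste0("g", 1:4)))
  set.seed(8)
  for (i in 1:25) {
    k <- sample(0:5, 1)
    prof <- if (k == 0) empty_profile() else do.call(rbind, lapply(1:k, function(j)
      variant(gene = sample(paste0("g", 1:6), 1),
              variant_class = sample(c("SNV", "DEL", "CNV_DEL"), 1),
              consequence = sample(c("missense", "nonsense", "synonymous",
                                     "frameshift", "other"), 1),
              coding_flag = sample(c(TRUE, FALSE), 1))))
    if (nrow(prof)) {
      prof$ref[prof$variant_class != "SNV"] <- "."
      prof$alt[prof$variant_class != "SNV"] <- "."
    }
    before <- classify_pathway_status(prof, "s", reg)
    more <- rbind(prof, variant(gene = "g1", consequence = "nonsense"))
    expect_identical(classify_pathway_status(more, "s", reg), "mutant")
    if (before == "mutant")
      expect_identical(classify_pathway_status(more, "s", reg), "mutant")
    if (classify_pathway_status(prof, "s", reg, lof_only = TRUE) == "mutant")
      expect_identical(classify_pathway_status(prof, "s", reg), "mutant")
  }
})

test_that("gene sets round-trip through GMT files", {
  reg <- default_gene_sets()
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(reg, path)
  back <- read_gmt(path)
  expect_identical(back$sets, reg$sets)
  expect_error(gene_set_registry(list(s = c("a", "a"))), "duplicate")
})
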