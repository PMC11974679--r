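test_that("eQTL significance uses an inclusive 0.05 bound in either region", {
  tb <- data.frame(variant = c("v1", "v2", "v3", "v3"),
                   tissue_region = c("macular", "macular", "non_macular", "macular"),
                   fdr = c(0.05, 0.06, 0.01, 0.9), stringsAsFactors = FALSE)
  expect_setequal(eqtl_significant(tb), c("v1", "v3"))
  tb$tissue_region[1] <- "retina"
  expect_error(eqtl_significant(tb), "region")
})

test_that("criteria matrix bookkeeping matches the upstream sets exactly", {
  integ <- sim_integration(n_variants = 120, seed = 3)
  cm <- build_criteria_matrix(integ$variants, integ$peaks, integ$promoter_pairs,
                              integ$peak_gene_pairs, integ$loops, integ$promoters,
                              integ$abc_pairs, integ$enhancer_snps,
                              integ$functional_snps, integ$eqtl_snps,
                              integ$high_effect_snps)
  prof <- integ$truth$profiles
  for (cn in colnames(prof)) {
    expect_equal(sum(cm[[cn]]), sum(prof[, cn]), info = cn)
  }
  expect_equal(cm$n_criteria_met,
               unname(rowSums(prof[cm$rsid, , drop = FALSE])))

  # a variant outside every peak is an internal-consistency error
  bad <- integ$variants
  bad$pos[1] <- bad$pos[1] + 10000
  expect_error(build_criteria_matrix(bad, integ$peaks, integ$promoter_pairs,
                                     integ$peak_gene_pairs, integ$loops,
                                     integ$promoters, integ$abc_pairs,
                                     character(0), character(0), character(0),
                                     character(0)), "containing peak")
})

test_that("prioritization is an inclusive >=3 rule and monotone", {
  integ <- sim_integration(n_variants = 150, seed = 8)
  cm <- build_criteria_matrix(integ$variants, integ$peaks, integ$promoter_pairs,
                              integ$peak_gene_pairs, integ$loops, integ$promoters,
                              integ$abc_pairs, integ$enhancer_snps,
                              integ$functional_snps, integ$eqtl_snps,
                              integ$high_effect_snps)
  pri <- call_prioritized(cm, k_min = 3, n_catalog = 1000)
  expect_true(all(cm$n_criteria_met[cm$rsid %in% pri$prioritized] >= 3))
  expect_true(all(cm$n_criteria_met[!cm$rsid %in% pri$prioritized] <= 2))
  expect_equal(pri$pct_of_accessible,
               round_half_away(100 * pri$n_prioritized / nrow(cm), 1))

  # adding a criterion never removes a variant from the prioritized set
  cm2 <- cm
  cm2$significant_eqtl <- TRUE
  cm2$n_criteria_met <- rowSums(cm2[, setdiff(names(cm2), c("rsid", "n_criteria_met"))])
  pri2 <- call_prioritized(cm2, k_min = 3)
  expect_true(all(pri$prioritized %in% pri2$prioritized))
})

test_that("upset combinations partition the accessible variants", {
  integ <- sim_integration(n_variants = 100, seed = 12)
  cm <- build_criteria_matrix(integ$variants, integ$peaks, integ$promoter_pairs,
                              integ$peak_gene_pairs, integ$loops, integ$promoters,
                              integ$abc_pairs, integ$enhancer_snps,
                              integ$functional_snps, integ$eqtl_snps,
                              integ$high_effect_snps)
  up <- upset_summary(cm)
  expect_equal(sum(up$combinations$count), nrow(cm))
  expect_true("(none)" %in% up$combinations$combination ||
                all(cm$n_criteria_met > 0))
  for (i in seq_len(nrow(up$marginals))) {
    expect_equal(up$marginals$count[i], sum(cm[[up$marginals$criterion[i]]]))
  }
})

test_that("locus reports rank candidates and flag inaccessible-index loci", {
  catalog <- data.frame(
    rsid = c("rs_idx", "rs_a", "rs_b", "rs_c"),
    locus_id = 31, is_index = c(TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  cm <- data.frame(rsid = c("rs_a", "rs_b", "rs_c"),
                   coaccessible_with_promoter = c(TRUE, TRUE, FALSE),
                   accessibility_correlated_with_gene = c(TRUE, TRUE, FALSE),
                   hichip_linked = FALSE, abc_connected = FALSE,
                   in_starrseq_enhancer = c(TRUE, TRUE, TRUE),
                   functional_snp = FALSE, significant_eqtl = FALSE,
                   chrombpnet_high_effect = FALSE, stringsAsFactors = FALSE)
  cm$n_criteria_met <- rowSums(cm[, 2:9])
  allelic <- data.frame(snp_id = c("rs_a", "rs_b"), log2fc = c(0.2, 1.5))
  rep31 <- locus_report(31, catalog, cm, prioritized = c("rs_a", "rs_b"),
                        allelic = allelic)
  # index not accessible (absent from the matrix), alternative flagged
  expect_false(rep31$index_variants$accessible)
  expect_true(rep31$index_inaccessible_alternative)
  # tie on criteria broken by |allelic log2FC|
  expect_equal(rep31$candidates$rsid, c("rs_b", "rs_a", "rs_c"))
  expect_error(locus_report(99, catalog, cm, character(0)), "unknown locus")

  # deterministic ordering on re-run
  rep31b <- locus_report(31, catalog, cm, prioritized = c("rs_a", "rs_b"),
                         allelic = allelic)
  expect_identical(rep31$candidates, rep31b$candidates)
})
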