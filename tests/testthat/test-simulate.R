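test_that("LD-block genotypes hit the target R2 and are reproducible", {
  spec <- list(list(n_variants = 6, r2 = 0.8), list(n_variants = 4, r2 = 1.0))
  g1 <- sim_genotypes(500, spec, seed = 11)
  g2 <- sim_genotypes(500, spec, seed = 11)
  expect_identical(g1$genotypes, g2$genotypes)

  # r2 = 1 duplicates the index dosages exactly
  expect_equal(g1$genotypes["rs2_2", ], g1$genotypes["rs2_1", ])

  # realized within-block R2 near target (sampling tolerance +/- 0.15)
  r2 <- apply(g1$genotypes[paste0("rs1_", 2:6), ], 1,
              function(v) cor(v, g1$genotypes["rs1_1", ])^2)
  expect_true(all(abs(r2 - 0.8) < 0.15))

  # cross-block independence: realized R2 stays below the 0.5 threshold
  cross <- cor(g1$genotypes["rs1_1", ], g1$genotypes["rs2_1", ])^2
  expect_lt(cross, 0.5)
})

test_that("atlas planting gives the stated link correlation and promoter peaks", {
  atl <- sim_atlas(n_cell_types = 3, n_peaks = 60, n_genes = 30,
                   n_planted_links = 10, link_corr = 1.0, seed = 5)
  truth <- atl$truth$true_peak_gene_links
  # link_corr = 1: peak accessibility is an exact affine image of expression
  for (i in seq_len(nrow(truth))) {
    r <- cor(atl$accessibility[truth$peak_id[i], ],
             atl$expression[truth$gene_id[i], ])
    expect_gt(r, 0.999)
  }
  # planted links sit within 250 kb of the TSS
  mids <- (atl$peaks$start + atl$peaks$end) / 2
  d <- abs(mids[match(truth$peak_id, atl$peaks$peak_id)] -
             atl$genes$tss[match(truth$gene_id, atl$genes$gene_id)])
  expect_true(all(d <= 250e3))
  # determinism
  atl2 <- sim_atlas(3, 60, 30, 10, 1.0, seed = 5)
  expect_identical(atl$accessibility, atl2$accessibility)
})

test_that("contact maps decay as a power law, stay symmetric, and mark loops", {
  genes <- gene_models(paste0("g", 1:5), "chr1", seq(2e4, 1.6e5, length.out = 5), "+")
  sim <- sim_contacts(genes, list(n_loops = 3, fold = 5, min_dist_bins = 5,
                                  max_dist_bins = 15),
                      gamma = 1, resolution_bp = 5000, seed = 9,
                      genome = c(chr1 = 2e5))
  m <- sim$contacts$maps$chr1
  expect_equal(m, t(m))
  expect_true(all(m >= 0))
  # background follows d^-gamma exactly away from planted loops
  expect_equal(m[1, 3], 2^-1, tolerance = 1e-12)
  # a 5x planted loop dominates its row off-diagonal beyond the decay
  l <- sim$loops[1, ]
  b1 <- l$anchor1_start / 5000 + 1
  b2 <- l$anchor2_start / 5000 + 1
  d <- abs(b1 - b2)
  expect_equal(m[b1, b2], 5 * d^-1, tolerance = 1e-12)
  # row maximum among bins at distance >= that loop's distance
  far <- which(abs(seq_len(ncol(m)) - b1) >= d)
  expect_equal(unname(which.max(m[b1, far])), unname(which(far == b2)))
})

test_that("STARR-seq simulation plants allelic effects on the mean ratio", {
  sim <- sim_starrseq(n_test_snps = 100, n_control_snps = 20,
                      frac_enhancer = 1, effect_grid = 1.0,
                      bc_mean_input = 3000, bc_mean_output = 300,
                      dispersion = 0.01, n_reps = 4, seed = 21,
                      frac_allelic = 1)
  oc <- sim$counts
  out_cols <- oc$sample_info$sample_id[oc$sample_info$class == "output"]
  eff <- sim$truth$true_allelic_effects
  planted <- eff[abs(eff$log2fc) > 0 & !grepl("^ctrl", eff$snp_id), ]
  ratios <- vapply(planted$snp_id, function(s) {
    a <- mean(oc$counts[paste0(s, "|alt"), out_cols])
    r <- mean(oc$counts[paste0(s, "|ref"), out_cols])
    log2(a / r)
  }, numeric(1))
  # mean realized log2 ratio concentrates at the planted value
  expect_equal(mean(ratios * sign(planted$log2fc)), 1.0, tolerance = 0.1)
  # determinism
  sim2 <- sim_starrseq(100, 20, 1, 1.0, 3000, 300, 0.01, 4, seed = 21,
                       frac_allelic = 1)
  expect_identical(oc$counts, sim2$counts$counts)
  # empty effect grid with planted allelic fraction is an error
  expect_error(sim_starrseq(10, 2, 0.5, numeric(0), 300, 300, 0.1, 2, 1,
                            frac_allelic = 1), "effect_grid")
})

test_that("predicted-count simulation plants exact fold changes without jitter", {
  sim <- sim_predicted_counts(paste0("v", 1:20), c("RPE", "endo"), n_folds = 5,
                              frac_high_effect = 0.5, effect_size = 1,
                              seed = 2, jitter_sd = 0)
  p <- sim$predictions
  th <- sim$truth$true_high_effect
  key <- paste(p$variant, p$cell_type)
  planted <- paste(th$variant, th$cell_type)
  ratio <- p$alt_count / p$ref_count
  hit <- match(key, planted)
  expected <- ifelse(is.na(hit), 1, 2^th$log2fc[hit])
  expect_equal(ratio, expected, tolerance = 1e-12)
  expect_warning(sim_predicted_counts(paste0("v", 1:5), "RPE", 2, 0.5, 0.2, seed = 1),
                 "threshold")
})

test_that("eQTL simulation yields exactly the requested significant count", {
  for (frac in c(0, 0.3, 1)) {
    tb <- sim_eqtl_table(paste0("v", 1:50), paste0("g", 1:10), frac, seed = 4)
    sig <- unique(tb$variant[tb$fdr <= 0.05])
    expect_equal(length(sig), round(frac * 50))
  }
  expect_true(all(sim_eqtl_table(paste0("v", 1:20), "g1", 1, 1)$tissue_region %in%
                    c("macular", "non_macular")))
})
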