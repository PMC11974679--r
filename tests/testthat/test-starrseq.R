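make_oc <- function(counts, snp_ids, is_control = FALSE, n_reps = 2,
                    condition = "naive") {
  n <- length(snp_ids)
  info <- data.frame(oligo_id = c(rbind(paste0(snp_ids, "|alt"), paste0(snp_ids, "|ref"))),
                     snp_id = rep(snp_ids, each = 2),
                     allele = rep(c("alt", "ref"), n),
                     is_control = rep(rep_len(is_control, n), each = 2),
                     stringsAsFactors = FALSE)
  samp <- data.frame(
    sample_id = c(paste0("input_rep", 1:n_reps), paste0(condition, "_rep", 1:n_reps)),
    class = rep(c("input", "output"), each = n_reps),
    condition = rep(c(NA, condition), each = n_reps),
    replicate = rep(1:n_reps, 2), stringsAsFactors = FALSE)
  dimnames(counts) <- list(info$oligo_id, samp$sample_id)
  oligo_counts(counts, info, samp)
}

test_that("amplicon parsing enforces adapter, barcode length, and known insert", {
  lookup <- c(ACGTACGT = "oligoA", TTTTCCCC = "oligoB")
  read <- paste0("ACGTACGT", starr_adapter, "AAAAACCCCC")
  r <- parse_amplicon(read, lookup)
  expect_equal(r$status, "ok")
  expect_equal(r$oligo_id, "oligoA")
  expect_equal(r$barcode, "AAAAACCCCC")

  expect_equal(parse_amplicon(paste0("ACGTACGT", starr_adapter, "AAAAACCCC"),
                              lookup)$status, "bad_barcode_length")
  expect_equal(parse_amplicon("ACGTACGTAAAAACCCCC", lookup)$status, "no_adapter")
  expect_equal(parse_amplicon(paste0("GGGGGGGG", starr_adapter, "AAAAACCCCC"),
                              lookup)$status, "unknown_insert")
  expect_equal(parse_amplicon("", lookup)$status, "no_adapter")
})

test_that("unique-barcode counting deduplicates and ignores order", {
  parsed <- data.frame(oligo_id = c("a", "a", "a", "b", "b"),
                       barcode = c("X", "X", "Y", "Z", "Z"),
                       stringsAsFactors = FALSE)
  counts <- count_unique_barcodes(parsed, c("a", "b", "c"))
  expect_equal(unname(counts), c(2L, 1L, 0L))
  shuf <- parsed[sample(nrow(parsed)), ]
  expect_equal(count_unique_barcodes(shuf, c("a", "b", "c")), counts)
  # duplicating every read changes nothing
  expect_equal(count_unique_barcodes(rbind(parsed, parsed), c("a", "b", "c")), counts)
})

test_that("oligo QC keeps >=5 in every replicate and pairs alleles", {
  counts <- rbind(c(5, 5, 5, 5),      # s1|alt boundary: retained
                  c(9, 9, 9, 9),      # s1|ref
                  c(12, 4, 30, 20),   # s2|alt: one replicate below 5
                  c(9, 9, 9, 9),      # s2|ref fine, but snp excluded by pairing
                  c(9, 9, 9, 9),      # s3|alt
                  c(9, 9, 9, 9))      # s3|ref
  oc <- make_oc(counts, c("s1", "s2", "s3"))
  qc <- qc_filter_oligos(oc, min_barcodes = 5)
  expect_setequal(qc$retained_snps, c("s1", "s3"))
  expect_equal(qc$n_snps_total, 3)
  expect_equal(qc$pct_retained, 66.7)
})

test_that("size factors are median-of-ratios and match the oracle", {
  a <- matrix(rpois(100, 50) + 1, ncol = 2)
  a[, 2] <- a[, 1] * 2
  sf <- size_factor_normalize(a)$size_factors
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)

  set.seed(6)
  counts <- matrix(rnbinom(100 * 4, mu = 100, size = 5), 100, 4)
  counts[counts == 0] <- 1
  expect_equal(unname(size_factor_normalize(counts)$size_factors),
               unname(oracle_size_factors(counts)), tolerance = 1e-12)
  # cross-check against the established count-model implementation (which
  # takes the even-n median midpoint in log space, hence the loose tolerance)
  skip_if_not_installed("DESeq2")
  expect_equal(unname(size_factor_normalize(counts)$size_factors),
               unname(DESeq2::estimateSizeFactorsForMatrix(counts)),
               tolerance = 1e-3)
  expect_error(size_factor_normalize(matrix(c(0, 1, 1, 0), 2, 2)), "nonzero")
})

test_that("enhancer calling needs both the fold-change and significance gates", {
  set.seed(12)
  n <- 200
  base <- matrix(rnbinom(n * 8, mu = 300, size = 50), n, 8)
  boosted <- base
  boosted[1:20, 5:8] <- matrix(rnbinom(20 * 4, mu = 300 * 4, size = 50), 20, 4)
  snps <- sprintf("s%03d", 1:(n / 2))
  oc <- make_oc(boosted, snps, n_reps = 4)
  r <- call_enhancers(oc, "naive")
  called <- r$snp_id[r$enhancer]
  expect_gte(mean(snps[1:10] %in% called), 0.9)    # snps built from oligo pairs 1:20
  expect_lte(sum(!called %in% snps[1:10]), 2)

  # identical output and input libraries yield zero enhancers
  same <- make_oc(cbind(base[, 1:4], base[, 1:4]), snps, n_reps = 4)
  expect_equal(sum(call_enhancers(same, "naive")$enhancer), 0)

  # a sub-threshold fold change never qualifies, whatever the p-value
  mild <- base
  mild[21:60, 5:8] <- matrix(rnbinom(40 * 4, mu = 300 * 2^0.5, size = 1e4), 40, 4)
  oc2 <- make_oc(mild, snps, n_reps = 4)
  r2 <- call_enhancers(oc2, "naive")
  low_fc <- r2$snp_id[abs(r2$log2fc) <= log2(1.5)]
  expect_false(any(r2$enhancer[r2$snp_id %in% low_fc]))
})

test_that("allelic activity is antisymmetric and null-calibrated", {
  set.seed(14)
  n_snp <- 150
  alt <- matrix(rnbinom(n_snp * 4, mu = 300, size = 20), n_snp, 4)
  ref <- matrix(rnbinom(n_snp * 4, mu = 300, size = 20), n_snp, 4)
  counts <- matrix(0L, 2 * n_snp, 8)
  counts[seq(1, 2 * n_snp, 2), ] <- cbind(matrix(300L, n_snp, 4), alt)
  counts[seq(2, 2 * n_snp, 2), ] <- cbind(matrix(300L, n_snp, 4), ref)
  snps <- sprintf("s%03d", 1:n_snp)
  oc <- make_oc(counts, snps, n_reps = 4)
  r <- allelic_activity(oc, "naive")

  # swapping allele rows negates the estimate exactly
  swapped <- counts
  swapped[seq(1, 2 * n_snp, 2), ] <- counts[seq(2, 2 * n_snp, 2), ]
  swapped[seq(2, 2 * n_snp, 2), ] <- counts[seq(1, 2 * n_snp, 2), ]
  r_sw <- allelic_activity(make_oc(swapped, snps, n_reps = 4), "naive")
  expect_equal(r_sw$log2fc, -r$log2fc, tolerance = 1e-12)
  expect_equal(r_sw$p, r$p, tolerance = 1e-12)

  # alt identical to ref in every replicate: estimate 0, p near 1
  eq <- counts; eq[seq(2, 2 * n_snp, 2), ] <- eq[seq(1, 2 * n_snp, 2), ]
  r_eq <- allelic_activity(make_oc(eq, snps, n_reps = 4), "naive")
  expect_true(all(r_eq$log2fc == 0))
  expect_true(all(r_eq$p > 0.99))
})

test_that("allelic estimates recover planted effects on simulated counts", {
  sim <- sim_starrseq(n_test_snps = 150, n_control_snps = 30, frac_enhancer = 1,
                      effect_grid = 1.0, bc_mean_input = 3000, bc_mean_output = 300,
                      dispersion = 0.01, n_reps = 4, seed = 33, frac_allelic = 1)
  qc <- qc_filter_oligos(sim$counts)
  r <- allelic_activity(qc$object, "naive")
  eff <- sim$truth$true_allelic_effects
  m <- merge(r, eff, by = "snp_id", suffixes = c("", "_true"))
  planted <- m[m$log2fc_true != 0, ]
  expect_gte(mean(abs(planted$log2fc - planted$log2fc_true) <= 0.2), 0.9)
})

test_that("the control percentile threshold interpolates order statistics", {
  expect_equal(empirical_threshold(seq(0.1, 1.0, by = 0.1), q = 0.8), 0.82)
  expect_equal(empirical_threshold(rep(0.4, 25)), 0.4)
  expect_equal(empirical_threshold(c(3, 1, 2, 5, 4, 7, 6, 9, 8, 10), q = 1.0), 10)
  expect_error(empirical_threshold(numeric(0)), "control")
  expect_warning(empirical_threshold(1:5), "unstable")
})

test_that("functional SNP calls are the strict three-way conjunction", {
  allelic <- data.frame(snp_id = c("s1", "s2", "s3", "s4", "c1"),
                        condition = "naive",
                        is_control = c(FALSE, FALSE, FALSE, FALSE, TRUE),
                        log2fc = c(1.2, 1.2, 0.5, 0.8, 2.0),
                        p = 0.001, padj = c(0.01, 0.01, 0.01, 0.2, 0.001),
                        stringsAsFactors = FALSE)
  r <- call_functional_snps(allelic, enhancer_snps = c("s1", "s3", "s4", "c1"),
                            threshold = 0.8)
  expect_equal(r$snp_id[r$functional], "s1")
  expect_false(any(r$snp_id == "c1"))          # controls never called
  # |log2fc| exactly at the threshold does not qualify (strict exceeding)
  expect_false(r$functional[r$snp_id == "s4"])
})

test_that("QQ quantile pairs sit on the diagonal for identical groups and shift with effects", {
  set.seed(15)
  x <- abs(rnorm(500))
  qq <- qq_abs_log2fc(x, x, n_points = 357)
  expect_equal(nrow(qq), 357)
  expect_equal(qq$test_quantile, qq$control_quantile)
  qq2 <- qq_abs_log2fc(x + 0.3, x, n_points = 357)
  expect_equal(qq2$test_quantile, qq2$control_quantile + 0.3, tolerance = 1e-12)
  expect_error(qq_abs_log2fc(numeric(0), x), "empty")
})
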