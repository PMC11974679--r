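make_peaks <- function(start, chrom = "chr1", width = 500) {
  data.frame(chrom = chrom, start = start, end = start + width, strand = ".",
             peak_id = sprintf("p%02d", seq_along(start)), stringsAsFactors = FALSE)
}

test_that("co-accessibility links respect the window and the signed cutoff", {
  set.seed(1)
  n <- 50
  base <- rnorm(n)
  acc <- rbind(p01 = 10 + base, p02 = 20 + 2 * base,       # perfectly correlated
               p03 = 10 + rnorm(n),                        # independent
               p04 = 10 - base)                            # anti-correlated
  peaks <- make_peaks(c(1000, 2000, 3000, 4000))
  links <- coaccessibility_links(acc, peaks, window_bp = 250e3, cutoff = 0.3)
  key <- paste(links$peak_a, links$peak_b)
  expect_true("p01 p02" %in% key)
  expect_false(any(grepl("p04", key)))   # negative correlation never passes

  # pairs beyond the window are never tested
  far <- make_peaks(c(0, 400000))
  acc2 <- rbind(p01 = 10 + base, p02 = 10 + base)
  expect_equal(nrow(coaccessibility_links(acc2, far, window_bp = 250e3)), 0)

  # constant profiles are skipped with a warning
  acc3 <- rbind(p01 = 10 + base, p02 = rep(5, n))
  expect_warning(coaccessibility_links(acc3, make_peaks(c(0, 1000))), "constant")
})

test_that("promoter co-accessibility requires overlap with a promoter peak", {
  genes <- gene_models("g1", "chr1", 50000, "+")
  promoters <- make_promoters(genes)            # [48000, 50101)
  peaks <- data.frame(chrom = "chr1",
                      start = c(10000, 48100, 47000), end = c(10500, 48600, 47999),
                      strand = ".", peak_id = c("distal", "inprom", "outside"),
                      stringsAsFactors = FALSE)
  links <- data.frame(peak_a = c("distal", "distal"), peak_b = c("inprom", "outside"),
                      correlation = 0.9, stringsAsFactors = FALSE)
  r <- promoter_coaccessible(links, peaks, promoters)
  expect_equal(r$pairs, data.frame(peak_id = "distal", gene_id = "g1",
                                   stringsAsFactors = FALSE))
  # peak ending 1 bp before the window never links
  links2 <- links[2, , drop = FALSE]
  expect_equal(nrow(promoter_coaccessible(links2, peaks, promoters)$pairs), 0)
})

test_that("all four strategies recover planted links on synthetic truth", {
  atl <- sim_atlas(n_cell_types = 2, n_peaks = 40, n_genes = 25,
                   n_planted_links = 12, link_corr = 0.9, seed = 13,
                   n_samples = 150)
  peaks_all <- rbind(atl$peaks,
                     cbind(atl$promoter_peaks[, c("chrom", "start", "end", "strand", "peak_id")]))
  truth <- atl$truth$true_peak_gene_links

  # peak-gene correlation
  pg <- peak_gene_links(atl$accessibility, atl$expression, peaks_all, atl$genes)
  got <- paste(pg$peak_id, pg$gene_id)
  want <- paste(truth$peak_id, truth$gene_id)
  expect_gte(mean(want %in% got), 0.9)
  # false-positive pairs are rare
  expect_lt(mean(!got %in% c(want, paste(atl$promoter_peaks$peak_id,
                                         atl$promoter_peaks$gene_id))), 0.05)

  # promoter co-accessibility through the planted promoter peaks
  promoters <- make_promoters(atl$genes)
  ca <- coaccessibility_links(atl$accessibility, peaks_all)
  pc <- promoter_coaccessible(ca, peaks_all, promoters)
  got_pc <- paste(pc$pairs$peak_id, pc$pairs$gene_id)
  expect_gte(mean(want %in% got_pc), 0.9)
})

test_that("anti-correlated and distant peak-gene pairs are excluded", {
  set.seed(4)
  n <- 60
  z <- rnorm(n)
  acc <- rbind(p01 = 10 + 2 * z, p02 = 10 - 2 * z)
  expr <- rbind(g1 = 10 + 2 * z + rnorm(n, 0, 0.1))
  colnames(acc) <- colnames(expr) <- paste0("s", 1:n)
  peaks <- make_peaks(c(10000, 11000))
  genes <- gene_models("g1", "chr1", 10250, "+")
  pg <- peak_gene_links(acc, expr, peaks, genes)
  expect_equal(pg$peak_id, "p01")              # r = -1 never passes

  far_gene <- gene_models("g1", "chr1", 10250 + 251000, "+")
  expect_equal(nrow(peak_gene_links(acc, expr, peaks, far_gene)), 0)

  colnames(expr) <- paste0("x", 1:n)
  expect_error(peak_gene_links(acc, expr, peaks, genes), "sample ids")
})

test_that("loop linking requires target and promoter on opposite anchors", {
  loops <- loop_set(genomic_intervals("chr1", 1000, 2000),
                    genomic_intervals("chr1", 50000, 51000))
  promoters <- make_promoters(gene_models("g1", "chr1", 50500, "+"))
  v_in <- data.frame(target_id = "rs_in", chrom = "chr1", pos = 1500)
  v_same <- data.frame(target_id = "rs_same", chrom = "chr1", pos = 50500)
  expect_equal(loop_overlap(loops, v_in, promoters)$links$gene_id, "g1")
  expect_equal(nrow(loop_overlap(loops, v_same, promoters)$links), 0)
})

test_that("loop overlap matches the brute-force all-pairs scan", {
  set.seed(19)
  for (rep in 1:3) {
    a1 <- random_intervals(30, span = 5e4, width = 300)
    a2 <- random_intervals(30, span = 5e4, width = 300)
    same <- a1$chrom == a2$chrom & a1$start == a2$start
    loops <- loop_set(a1[!same, ], a2[!same, ])
    targets <- data.frame(target_id = paste0("t", 1:40),
                          chrom = sample(c("chr1", "chr2"), 40, TRUE),
                          pos = sample.int(5e4, 40), stringsAsFactors = FALSE)
    genes <- gene_models(paste0("g", 1:10), sample(c("chr1", "chr2"), 10, TRUE),
                         sample.int(45000, 10) + 2000, "+")
    promoters <- make_promoters(genes)
    got <- loop_overlap(loops, targets, promoters)$links[, c("target_id", "gene_id")]
    want <- oracle_loop_links(loops, targets, promoters)
    expect_setequal(paste(got$target_id, got$gene_id),
                    paste(want$target_id, want$gene_id))
  }
})

test_that("anchor-peak overlap fraction counts loops with any overlapping base", {
  loops <- loop_set(genomic_intervals("chr1", c(0, 10000), c(100, 10100)),
                    genomic_intervals("chr1", c(5000, 20000), c(5100, 20100)))
  peaks <- genomic_intervals("chr1", 50, 150)
  promoters <- make_promoters(gene_models("g", "chr1", 3000, "+"))
  r <- loop_overlap(loops, data.frame(target_id = "t", chrom = "chr1", pos = 1),
                    promoters, peaks = peaks)
  expect_equal(r$fraction_anchor_in_peak, 0.5)
})

test_that("ABC scores normalize per gene, respect the TSS gap, and match brute force", {
  # two candidates with activity x contact 3 and 1 -> scores 0.75 / 0.25
  elements <- data.frame(chrom = "chr1", start = c(10000, 20000),
                         end = c(10500, 20500), strand = ".",
                         element_id = c("e1", "e2"), stringsAsFactors = FALSE)
  genes <- gene_models("g1", "chr1", 30000, "+")
  nb <- 10
  m <- matrix(1, nb, nb, dimnames = rep(list(sprintf("chr1:%d", (0:(nb - 1)) * 5000)), 2))
  cmap <- contact_map_from_matrix(m, 5000)
  atac <- c(e1 = 9, e2 = 1); h3k <- c(e1 = 1, e2 = 1)   # A = 3 and 1, C = 1
  r <- abc_scores(elements, atac, h3k, cmap, genes)
  expect_equal(sort(r$all_scores$abc_score), c(0.25, 0.75))
  expect_equal(sum(r$all_scores$abc_score), 1, tolerance = 1e-12)

  # element 300 bp from the TSS is excluded from connections even at score ~1
  close_el <- data.frame(chrom = "chr1", start = 29550, end = 29950, strand = ".",
                         element_id = "e3", stringsAsFactors = FALSE)
  r2 <- abc_scores(close_el, c(e3 = 100), c(e3 = 100), cmap, genes)
  expect_equal(r2$all_scores$abc_score, 1)
  expect_equal(nrow(r2$connections), 0)

  # randomized instance equals the brute-force double loop; per-gene sums are 1
  set.seed(23)
  sim <- sim_contacts(gene_models(paste0("g", 1:8), "chr1",
                                  sample.int(1.8e5, 8) + 1e4, "+"),
                      list(n_loops = 4, fold = 5), gamma = 1.2,
                      resolution_bp = 5000, seed = 2, genome = c(chr1 = 2e5))
  els <- data.frame(chrom = "chr1", start = seq(5000, 190000, by = 4000))
  els$end <- els$start + 500; els$strand <- "."
  els$element_id <- sprintf("e%02d", seq_len(nrow(els)))
  atacs <- setNames(runif(nrow(els), 0.5, 5), els$element_id)
  h3ks <- setNames(runif(nrow(els), 0.5, 5), els$element_id)
  genes8 <- gene_models(paste0("g", 1:8), "chr1", sample.int(1.8e5, 8) + 1e4, "+")
  got <- abc_scores(els, atacs, h3ks, sim$contacts, genes8, candidate_window = 5e6)
  contact_fn <- function(chrom, p1, p2) {
    mm <- sim$contacts$maps[[chrom]]
    mm[floor(p1 / 5000) + 1, floor(p2 / 5000) + 1]
  }
  want <- oracle_abc(els, sqrt(atacs * h3ks), contact_fn, genes8, 5e6)
  merged <- merge(got$all_scores, want, by = c("element_id", "gene_id"))
  expect_equal(nrow(merged), nrow(want))
  expect_equal(merged$abc_score, merged$score, tolerance = 1e-12)
  sums <- tapply(got$all_scores$abc_score, got$all_scores$gene_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("connection summaries report medians and smaller-set overlaps", {
  s1 <- data.frame(peak_id = c("p1", "p2", "p3"), gene_id = c("g1", "g1", "g1"),
                   distance_to_tss = c(1000, 2000, 3000))
  s2 <- s1
  s3 <- data.frame(peak_id = c("p9", "p8"), gene_id = c("g2", "g3"),
                   distance_to_tss = c(10, 20))
  r <- connection_summaries(list(a = s1, b = s2, c = s3))
  expect_equal(r$per_strategy$median_enhancers_per_gene[1], 3)
  expect_equal(r$per_strategy$median_distance_to_tss[1], 2000)
  expect_equal(r$pairwise_overlap["a", "b"], 1)
  expect_equal(r$pairwise_overlap["a", "c"], 0)
})

test_that("marker-gene enrichment fractions behave at the extremes", {
  targets <- paste0("g", 1:100)
  sets <- list(ocular = paste0("g", 1:50),          # subset of targets
               other = paste0("x", 1:50),           # disjoint
               half = c(paste0("g", 1:25), paste0("y", 1:25)))
  r <- marker_gene_enrichment(targets, sets, baseline_tissues = "other",
                              n_sample = 40, n_draws = 20, seed = 2)
  expect_equal(r$fraction[r$tissue == "ocular"], 1)
  expect_equal(r$fraction[r$tissue == "other"], 0)
  expect_equal(r$fraction[r$tissue == "half"], 0.5, tolerance = 0.1)
})
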