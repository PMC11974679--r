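## Synthetic-data generators. Every generator is a pure function of its
## arguments including `seed`, and each returns the planted ground truth
## alongside the data so downstream recovery can be scored.

#' Toy genome used by the generators
#'
#' Two chromosomes of 10 Mb each by default: large enough to exercise
#' cross-chromosome logic, small enough that dense contact maps stay
#' desk-scale.
#'
#' @param n_chrom number of chromosomes
#' @param chrom_size size of each chromosome in bp
#' @return named numeric vector of chromosome sizes
#' @export
toy_genome <- function(n_chrom = 2, chrom_size = 10e6) {
  stats::setNames(rep(chrom_size, n_chrom), paste0("chr", seq_len(n_chrom)))
}

#' Simulate LD-block genotypes
#'
#' Variants are organised in blocks. Within a block, each partner variant's
#' haplotypes are copies of the block's index haplotype with alleles flipped
#' independently at rate `f = (1 - sqrt(r2)) / 2`, which for allele frequency
#' 0.5 gives expected pairwise correlation `sqrt(r2)` and hence R-squared
#' `r2` between dosages. Blocks are generated independently.
#'
#' @param n_individuals number of diploid individuals (>= 20)
#' @param block_spec list of blocks, each `list(n_variants =, r2 =)`;
#'   the first variant of each block is the index
#' @param seed RNG seed
#' @return list with `genotypes` (variants x individuals dosage matrix),
#'   `variants` (data.frame: variant_id, block, is_index), and `truth`
#'   (ledger with `true_ld_partners`: data.frame of index_rsid, rsid,
#'   generating r2)
#' @export
sim_genotypes <- function(n_individuals, block_spec, seed) {
  if (n_individuals < 20) stop("n_individuals must be >= 20")
  for (b in block_spec) {
    if (b$r2 < 0 || b$r2 > 1) stop("within-block r2 must lie in [0,1]")
    if (b$n_variants < 1) stop("block must contain >= 1 variant")
  }
  set.seed(seed)
  n_hap <- 2L * n_individuals
  geno <- list(); vinfo <- list(); partners <- list()
  for (bi in seq_along(block_spec)) {
    b <- block_spec[[bi]]
    index_hap <- rbinom(n_hap, 1L, 0.5)
    if (b$r2 > 0 && length(unique(index_hap)) == 1L) {
      stop(sprintf("block %d: index haplotype is monomorphic; cannot plant r2 > 0", bi))
    }
    f <- (1 - sqrt(b$r2)) / 2
    ids <- sprintf("rs%d_%d", bi, seq_len(b$n_variants))
    block_hap <- matrix(0L, b$n_variants, n_hap)
    block_hap[1, ] <- index_hap
    if (b$n_variants > 1) {
      for (v in 2:b$n_variants) {
        flip <- rbinom(n_hap, 1L, f)
        block_hap[v, ] <- as.integer(xor(index_hap, flip))
      }
    }
    dose <- block_hap[, seq_len(n_individuals), drop = FALSE] +
      block_hap[, n_individuals + seq_len(n_individuals), drop = FALSE]
    rownames(dose) <- ids
    geno[[bi]] <- dose
    vinfo[[bi]] <- data.frame(variant_id = ids, block = bi,
                              is_index = seq_len(b$n_variants) == 1L,
                              stringsAsFactors = FALSE)
    if (b$n_variants > 1) {
      partners[[bi]] <- data.frame(index_rsid = ids[1], rsid = ids[-1],
                                   r2 = b$r2, stringsAsFactors = FALSE)
    }
  }
  genotypes <- do.call(rbind, geno)
  colnames(genotypes) <- sprintf("ind%03d", seq_len(n_individuals))
  truth <- list(true_ld_partners = if (length(partners)) do.call(rbind, partners) else
                  data.frame(index_rsid = character(), rsid = character(), r2 = numeric()),
                seed = seed)
  list(genotypes = genotypes, variants = do.call(rbind, vinfo), truth = truth)
}

#' Simulate a chromatin-accessibility/expression atlas with planted
#' peak-gene regulatory links
#'
#' Gene expression and peak accessibility are generated over shared
#' pseudo-bulk samples from Gaussian latents on a positive baseline. A
#' planted link makes the peak's latent equal
#' `rho * z_gene + sqrt(1 - rho^2) * noise`, so the generating Pearson
#' correlation is exactly `link_corr`. For every linked gene a second peak
#' is placed inside the gene's promoter window carrying the gene's own
#' latent, so promoter co-accessibility is recoverable as well. Non-linked
#' peaks are independent noise.
#'
#' @param n_cell_types number of cell-type peak sets to emit
#' @param n_peaks number of distal peaks
#' @param n_genes number of genes
#' @param n_planted_links number of planted (peak, gene) regulatory links
#' @param link_corr generating correlation of planted links, in (0.3, 1]
#' @param seed RNG seed
#' @param n_samples number of pseudo-bulk samples
#' @param genome toy genome sizes
#' @return list: `peaks` (universe data.frame with peak_id), `peaksets`
#'   (per-cell-type [peak_set()]s), `genes`, `promoter_peaks`,
#'   `accessibility` and `expression` matrices, `truth` (ledger with
#'   `true_peak_gene_links`)
#' @export
sim_atlas <- function(n_cell_types, n_peaks, n_genes, n_planted_links,
                      link_corr, seed, n_samples = 100, genome = toy_genome()) {
  if (link_corr <= 0.3 || link_corr > 1) stop("link_corr must lie in (0.3, 1]")
  if (n_planted_links > min(n_peaks, n_genes)) stop("more planted links than peaks or genes")
  set.seed(seed)
  chroms <- names(genome)
  peak_w <- 500
  ## genes on a regular-ish grid, away from chromosome ends
  g_chrom <- sample(chroms, n_genes, replace = TRUE)
  g_tss <- floor(runif(n_genes, 5e5, genome[g_chrom] - 5e5))
  genes <- gene_models(sprintf("gene%03d", seq_len(n_genes)), g_chrom, g_tss,
                       sample(c("+", "-"), n_genes, replace = TRUE))
  ## planted links: peak i linked to gene i, placed within 250 kb of its TSS
  linked_gene <- sample(n_genes, n_planted_links)
  p_chrom <- character(n_peaks); p_start <- numeric(n_peaks)
  for (i in seq_len(n_peaks)) {
    if (i <= n_planted_links) {
      g <- linked_gene[i]
      p_chrom[i] <- genes$chrom[g]
      off <- sample(c(-1, 1), 1) * floor(runif(1, 5e3, 2e5))
      p_start[i] <- max(0, genes$tss[g] + off - peak_w / 2)
    } else {
      p_chrom[i] <- sample(chroms, 1)
      p_start[i] <- floor(runif(1, 0, genome[p_chrom[i]] - peak_w))
    }
  }
  peaks <- genomic_intervals(p_chrom, p_start, p_start + peak_w)
  peaks$peak_id <- sprintf("peak%04d", seq_len(n_peaks))
  if (n_planted_links > 0) {
    d <- abs(p_start[seq_len(n_planted_links)] + peak_w / 2 -
               genes$tss[linked_gene])
    if (any(d > 250e3)) stop("planted link farther than 250 kb from its TSS")
  }
  ## promoter peaks for linked genes (enable promoter co-accessibility)
  prom <- make_promoters(genes[linked_gene, , drop = FALSE])
  promoter_peaks <- data.frame(chrom = prom$chrom,
                               start = pmax(0, genes$tss[linked_gene] - 250),
                               end = genes$tss[linked_gene] + 250,
                               strand = ".",
                               peak_id = sprintf("prompeak%03d", seq_along(linked_gene)),
                               gene_id = genes$gene_id[linked_gene],
                               stringsAsFactors = FALSE)
  ## latent signals
  zg <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  expression <- pmax(10 + 2 * zg, 0)
  dimnames(expression) <- list(genes$gene_id, sprintf("pb%03d", seq_len(n_samples)))
  zp <- matrix(rnorm(n_peaks * n_samples), n_peaks, n_samples)
  if (n_planted_links > 0) {
    for (i in seq_len(n_planted_links)) {
      zp[i, ] <- link_corr * zg[linked_gene[i], ] +
        sqrt(1 - link_corr^2) * rnorm(n_samples)
    }
  }
  accessibility <- pmax(10 + 2 * zp, 0)
  dimnames(accessibility) <- list(peaks$peak_id, colnames(expression))
  ## promoter-peak rows carry the gene latent exactly
  if (n_planted_links > 0) {
    acc_prom <- pmax(10 + 2 * zg[linked_gene, , drop = FALSE], 0)
    rownames(acc_prom) <- promoter_peaks$peak_id
    accessibility <- rbind(accessibility, acc_prom)
  }
  attr(accessibility, "kind") <- "accessibility"
  attr(expression, "kind") <- "expression"
  ## per-cell-type peak sets: every peak in >= 1 cell type
  all_iv <- rbind(peaks[, c("chrom", "start", "end", "strand")],
                  promoter_peaks[, c("chrom", "start", "end", "strand")])
  all_ids <- c(peaks$peak_id, promoter_peaks$peak_id)
  peaksets <- list()
  ct_names <- sprintf("celltype%02d", seq_len(n_cell_types))
  member <- matrix(FALSE, nrow(all_iv), n_cell_types)
  member[cbind(seq_len(nrow(all_iv)), sample(n_cell_types, nrow(all_iv), replace = TRUE))] <- TRUE
  extra <- matrix(runif(nrow(all_iv) * n_cell_types) < 0.3, nrow(all_iv), n_cell_types)
  member <- member | extra
  for (k in seq_len(n_cell_types)) {
    peaksets[[ct_names[k]]] <- peak_set(all_iv[member[, k], , drop = FALSE],
                                        label = ct_names[k])
  }
  truth <- list(
    true_peak_gene_links = data.frame(
      peak_id = peaks$peak_id[seq_len(n_planted_links)],
      gene_id = genes$gene_id[linked_gene],
      corr = if (n_planted_links) link_corr else numeric(0),
      stringsAsFactors = FALSE),
    seed = seed)
  list(peaks = peaks, promoter_peaks = promoter_peaks, peaksets = peaksets,
       genes = genes, accessibility = accessibility, expression = expression,
       truth = truth)
}

#' Simulate a binned contact map with power-law decay and planted loops
#'
#' Background contact between bins at distance `d` bins is `d^(-gamma)`
#' (off-diagonal); the diagonal is fixed at 2. Each planted loop multiplies
#' its anchor-bin pair by `fold`.
#'
#' @param genes gene-model data.frame (loop second anchors are drawn at gene
#'   TSS bins when `target_genes = TRUE`)
#' @param loop_spec `list(n_loops =, fold =, min_dist_bins =, max_dist_bins =)`
#' @param gamma power-law decay exponent (> 0)
#' @param resolution_bp bin size
#' @param seed RNG seed
#' @param genome toy genome sizes
#' @param target_genes place the second anchor of each loop at a gene TSS bin
#' @param noise_sd sd of multiplicative log-normal noise (0 = deterministic)
#' @return list with `contacts` (contact_map), `loops` (loop set with bin
#'   extents as anchors), `truth`
#' @export
sim_contacts <- function(genes, loop_spec, gamma, resolution_bp = 5000, seed = 1,
                         genome = toy_genome(), target_genes = TRUE,
                         noise_sd = 0) {
  if (gamma <= 0) stop("gamma must be > 0")
  set.seed(seed)
  maps <- list()
  for (chr in names(genome)) {
    nb <- ceiling(genome[[chr]] / resolution_bp)
    d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
    m <- ifelse(d == 0, 2, d^(-gamma))
    if (noise_sd > 0) {
      eps <- matrix(rnorm(nb * nb, 0, noise_sd), nb, nb)
      eps <- (eps + t(eps)) / 2
      m <- m * exp(eps)
    }
    dimnames(m) <- rep(list(sprintf("%s:%d", chr, (seq_len(nb) - 1L) * resolution_bp)), 2)
    maps[[chr]] <- m
  }
  n_loops <- loop_spec$n_loops %||% 0
  fold <- loop_spec$fold %||% 5
  min_d <- loop_spec$min_dist_bins %||% 5
  max_d <- loop_spec$max_dist_bins %||% 40
  a1 <- list(); a2 <- list()
  if (n_loops > 0) {
    for (l in seq_len(n_loops)) {
      if (target_genes && nrow(genes) > 0) {
        g <- genes[sample(nrow(genes), 1), ]
        chr <- g$chrom
        nb <- nrow(maps[[chr]])
        b2 <- floor(g$tss / resolution_bp) + 1L
      } else {
        chr <- sample(names(genome), 1)
        nb <- nrow(maps[[chr]])
        b2 <- sample(nb, 1)
      }
      if (b2 < 1L || b2 > nb) stop("loop anchor falls off the toy genome")
      cand <- c(b2 + seq(min_d, max_d), b2 - seq(min_d, max_d))
      cand <- cand[cand >= 1L & cand <= nb]
      if (!length(cand)) stop("loop anchor falls off the toy genome")
      b1 <- if (length(cand) == 1L) cand else sample(cand, 1)
      maps[[chr]][b1, b2] <- maps[[chr]][b1, b2] * fold
      maps[[chr]][b2, b1] <- maps[[chr]][b1, b2]
      a1[[l]] <- data.frame(chrom = chr, start = (min(b1, b2) - 1) * resolution_bp,
                            end = min(b1, b2) * resolution_bp, strand = ".")
      a2[[l]] <- data.frame(chrom = chr, start = (max(b1, b2) - 1) * resolution_bp,
                            end = max(b1, b2) * resolution_bp, strand = ".")
    }
  }
  loops <- if (n_loops > 0) {
    loop_set(do.call(rbind, a1), do.call(rbind, a2), score = fold)
  } else {
    loop_set(genomic_intervals(character(), numeric(), numeric()),
             genomic_intervals(character(), numeric(), numeric()))
  }
  cm <- structure(list(resolution_bp = resolution_bp, maps = maps),
                  class = "contact_map")
  list(contacts = cm, loops = loops,
       truth = list(true_loops = loops, fold = fold, gamma = gamma, seed = seed))
}

.rnb <- function(n, mu, dispersion) {
  ## NB with variance mu + dispersion * mu^2; Poisson limit at dispersion 0
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate allele-specific STARR-seq barcode counts
#'
#' Unique-barcode counts are negative-binomial with variance
#' `mu + dispersion * mu^2`. A fraction `frac_enhancer` of test SNPs are
#' planted enhancers whose output oligos gain activity
#' `2^enhancer_log2fc`; a fraction `frac_allelic` of those carry an allelic
#' log2 fold change drawn from `effect_grid`, split symmetrically between
#' alleles. Control SNPs have no activity and no allelic effect.
#'
#' @param n_test_snps,n_control_snps numbers of test / control SNPs
#' @param frac_enhancer fraction of test SNPs planted as enhancers
#' @param effect_grid vector of planted allelic log2 fold changes
#' @param bc_mean_input,bc_mean_output mean unique barcodes per oligo
#' @param dispersion NB dispersion (variance mu + dispersion mu^2)
#' @param n_reps replicates per library class (>= 2)
#' @param seed RNG seed
#' @param frac_allelic fraction of planted enhancers carrying an allelic effect
#' @param enhancer_log2fc planted output/input log2 fold change of enhancers
#' @param condition condition label for the output libraries
#' @return list with `counts` (an `oligo_counts` object) and `truth`
#' @export
sim_starrseq <- function(n_test_snps, n_control_snps, frac_enhancer,
                         effect_grid, bc_mean_input, bc_mean_output,
                         dispersion, n_reps, seed, frac_allelic = 0.5,
                         enhancer_log2fc = 1.5, condition = "naive") {
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (frac_enhancer < 0 || frac_enhancer > 1) stop("frac_enhancer must lie in [0,1]")
  if (frac_allelic > 0 && frac_enhancer > 0 && length(effect_grid) == 0) {
    stop("effect_grid is empty but a positive fraction of allelic effects was requested")
  }
  set.seed(seed)
  snp_ids <- c(sprintf("snp%04d", seq_len(n_test_snps)),
               sprintf("ctrl%04d", seq_len(n_control_snps)))
  is_control <- c(rep(FALSE, n_test_snps), rep(TRUE, n_control_snps))
  n_snp <- length(snp_ids)
  n_enh <- round(frac_enhancer * n_test_snps)
  enh <- seq_len(n_snp) %in% sample(which(!is_control), n_enh)
  n_alle <- round(frac_allelic * n_enh)
  alle_idx <- if (n_enh > 0) sample(which(enh), n_alle) else integer(0)
  allelic_fc <- numeric(n_snp)
  if (length(alle_idx)) {
    allelic_fc[alle_idx] <- sample(effect_grid, length(alle_idx), replace = TRUE) *
      sample(c(-1, 1), length(alle_idx), replace = TRUE)
  }
  activity <- ifelse(enh, 2^enhancer_log2fc, 1)
  abundance <- exp(rnorm(n_snp, 0, 0.25))   # oligo-specific library abundance
  oligo_info <- data.frame(
    oligo_id = c(paste0(snp_ids, "|ref"), paste0(snp_ids, "|alt")),
    snp_id = rep(snp_ids, 2),
    allele = rep(c("ref", "alt"), each = n_snp),
    is_control = rep(is_control, 2), stringsAsFactors = FALSE)
  oligo_info <- oligo_info[order(oligo_info$snp_id, oligo_info$allele), ]
  rownames(oligo_info) <- NULL
  samp <- data.frame(
    sample_id = c(sprintf("input_rep%d", seq_len(n_reps)),
                  sprintf("%s_rep%d", condition, seq_len(n_reps))),
    class = rep(c("input", "output"), each = n_reps),
    condition = rep(c(NA, condition), each = n_reps),
    replicate = rep(seq_len(n_reps), 2), stringsAsFactors = FALSE)
  counts <- matrix(0L, nrow(oligo_info), nrow(samp),
                   dimnames = list(oligo_info$oligo_id, samp$sample_id))
  snp_of <- match(oligo_info$snp_id, snp_ids)
  allele_shift <- ifelse(oligo_info$allele == "alt",
                         2^(allelic_fc[snp_of] / 2), 2^(-allelic_fc[snp_of] / 2))
  mu_in <- abundance[snp_of] * bc_mean_input
  mu_out <- abundance[snp_of] * bc_mean_output * activity[snp_of] * allele_shift
  for (j in seq_len(nrow(samp))) {
    mu <- if (samp$class[j] == "input") mu_in else mu_out
    counts[, j] <- .rnb(length(mu), mu, dispersion)
  }
  oc <- oligo_counts(counts, oligo_info, samp)
  truth <- list(
    true_enhancer_oligos = data.frame(snp_id = snp_ids[enh],
                                      log2fc = enhancer_log2fc,
                                      stringsAsFactors = FALSE),
    true_allelic_effects = data.frame(snp_id = snp_ids, log2fc = allelic_fc,
                                      stringsAsFactors = FALSE),
    seed = seed)
  list(counts = oc, truth = truth)
}

#' Simulate per-fold predicted ref/alt accessibility counts
#'
#' Emulates cross-validated sequence-model predictions: each
#' (variant, cell type) gets a base predicted count; high-effect variants
#' carry a planted allelic log2 fold change in at least one cell type;
#' fold-to-fold variation is small multiplicative log-normal jitter.
#'
#' @param variant_ids variant identifiers
#' @param cell_types cell-type names
#' @param n_folds number of model folds (>= 2; the reference analysis uses 5)
#' @param frac_high_effect fraction of variants planted with an effect
#' @param effect_size planted |log2FC| (warning if <= 0.25, the calling
#'   threshold)
#' @param base_count_range range of base predicted counts
#' @param seed RNG seed
#' @param jitter_sd sd of per-fold log-normal jitter (0 = none)
#' @return list with `predictions` (variant, cell_type, fold, ref_count,
#'   alt_count) and `truth` (`true_high_effect`: variant, cell_type, log2fc)
#' @export
sim_predicted_counts <- function(variant_ids, cell_types, n_folds,
                                 frac_high_effect, effect_size,
                                 base_count_range = c(200, 2000), seed = 1,
                                 jitter_sd = 0.03) {
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (frac_high_effect > 0 && effect_size <= 0.25) {
    warning("planted effect_size <= 0.25 sits below the high-effect calling threshold")
  }
  set.seed(seed)
  nv <- length(variant_ids); nct <- length(cell_types)
  n_he <- round(frac_high_effect * nv)
  he_idx <- sample(nv, n_he)
  lfc <- matrix(0, nv, nct, dimnames = list(variant_ids, cell_types))
  truth_rows <- list()
  for (v in he_idx) {
    k <- sample(nct, sample(nct, 1))      # affected in >= 1 cell type
    s <- sample(c(-1, 1), 1)
    lfc[v, k] <- s * effect_size
    truth_rows[[length(truth_rows) + 1L]] <-
      data.frame(variant = variant_ids[v], cell_type = cell_types[k],
                 log2fc = s * effect_size, stringsAsFactors = FALSE)
  }
  grid <- expand.grid(variant = variant_ids, cell_type = cell_types,
                      fold = seq_len(n_folds), stringsAsFactors = FALSE)
  base <- matrix(runif(nv * nct, base_count_range[1], base_count_range[2]),
                 nv, nct, dimnames = list(variant_ids, cell_types))
  idx <- cbind(match(grid$variant, variant_ids), match(grid$cell_type, cell_types))
  jr <- if (jitter_sd > 0) exp(rnorm(nrow(grid), 0, jitter_sd)) else 1
  ja <- if (jitter_sd > 0) exp(rnorm(nrow(grid), 0, jitter_sd)) else 1
  grid$ref_count <- base[idx] * jr
  grid$alt_count <- base[idx] * 2^(lfc[idx]) * ja
  truth <- list(
    true_high_effect = if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(variant = character(), cell_type = character(), log2fc = numeric()),
    seed = seed)
  list(predictions = grid, truth = truth)
}

#' Simulate an eQTL table
#'
#' Exactly `round(frac_significant * n)` variants receive an FDR <= 0.05
#' association in at least one tissue region (macular or non-macular
#' RPE-choroid); the rest are non-significant in both.
#'
#' @param variant_ids variant identifiers
#' @param gene_ids gene identifiers (eGene drawn per variant)
#' @param frac_significant fraction of significant variants, in [0,1]
#' @param seed RNG seed
#' @return data.frame: variant, gene, tissue_region, fdr
#' @export
sim_eqtl_table <- function(variant_ids, gene_ids, frac_significant, seed) {
  if (frac_significant < 0 || frac_significant > 1) stop("frac_significant must lie in [0,1]")
  set.seed(seed)
  n <- length(variant_ids)
  n_sig <- round(frac_significant * n)
  sig <- seq_len(n) %in% sample(n, n_sig)
  regions <- c("macular", "non_macular")
  rows <- lapply(seq_len(n), function(i) {
    g <- sample(gene_ids, 1)
    sig_region <- sample(regions, 1)
    fdr <- stats::setNames(runif(2, 0.0501, 1), regions)
    if (sig[i]) fdr[sig_region] <- runif(1, 0, 0.05)
    data.frame(variant = variant_ids[i], gene = g, tissue_region = regions,
               fdr = as.numeric(fdr[regions]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
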