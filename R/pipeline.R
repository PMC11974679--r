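## End-to-end orchestration: a single config drives synthetic-data
## generation, all analysis stages, and the report directory.

#' Simulate an integration scenario with planted criterion profiles
#'
#' Builds a deterministic-by-construction input set for the 8-criterion
#' integration stage: each accessible variant sits in its own (disjoint)
#' containing peak and is assigned a random boolean profile over the eight
#' criteria; the upstream link tables, loops and membership sets are then
#' constructed to realize exactly that profile. Because peaks, anchors and
#' promoters are spatially separated, recovery of the planted profiles by
#' [build_criteria_matrix()] is exact.
#'
#' @param n_variants number of accessible variants
#' @param criterion_probs length-8 vector of per-criterion planting
#'   probabilities (order: promoter co-accessibility, peak-gene
#'   correlation, HiChIP link, ABC connection, STARR enhancer, functional
#'   SNP, significant eQTL, high effect)
#' @param seed RNG seed
#' @param n_loci number of loci the variants are spread over
#' @param genome toy genome sizes
#' @return list with all inputs for [build_criteria_matrix()] plus
#'   `truth` (`profiles` matrix and `planted_prioritized` at >= 3 criteria)
#' @export
sim_integration <- function(n_variants = 200,
                            criterion_probs = c(0.37, 0.41, 0.05, 0.14,
                                                0.44, 0.07, 0.22, 0.02),
                            seed = 1, n_loci = 34, genome = toy_genome()) {
  stopifnot(length(criterion_probs) == 8)
  set.seed(seed)
  spacing <- 20000
  chroms <- names(genome)
  chrom <- rep(chroms, length.out = n_variants)
  slot <- stats::ave(seq_len(n_variants), chrom, FUN = seq_along)
  pos <- 100000 + (slot - 1) * spacing          # >= 20 kb apart per chromosome
  rsid <- sprintf("rsv%04d", seq_len(n_variants))
  variants <- data.frame(rsid = rsid, chrom = chrom, pos = pos,
                         locus_id = rep(seq_len(n_loci), length.out = n_variants),
                         stringsAsFactors = FALSE)
  ## profile matrix: plant Bernoulli criteria; functional implies enhancer
  prof <- matrix(runif(n_variants * 8) < rep(criterion_probs, each = n_variants),
                 n_variants, 8, dimnames = list(rsid, criteria_names))
  prof[prof[, "functional_snp"], "in_starrseq_enhancer"] <- TRUE
  ## one gene per variant, 5 kb downstream; one containing peak per variant
  genes <- gene_models(sprintf("g_%s", rsid), chrom, pos + 5000,
                       rep("+", n_variants))
  promoters <- make_promoters(genes)
  peaks <- data.frame(chrom = chrom, start = pos - 250, end = pos + 250,
                      strand = ".", peak_id = sprintf("pk_%s", rsid),
                      stringsAsFactors = FALSE)
  pair_tab <- function(col) {
    sel <- prof[, col]
    data.frame(peak_id = peaks$peak_id[sel], gene_id = genes$gene_id[sel],
               stringsAsFactors = FALSE)
  }
  promoter_pairs <- pair_tab("coaccessible_with_promoter")
  peak_gene_pairs <- pair_tab("accessibility_correlated_with_gene")
  abc_pairs <- pair_tab("abc_connected")
  names(abc_pairs)[1] <- "element_id"
  loop_sel <- which(prof[, "hichip_linked"])
  loops <- if (length(loop_sel)) {
    loop_set(genomic_intervals(chrom[loop_sel], pos[loop_sel] - 50, pos[loop_sel] + 50),
             genomic_intervals(chrom[loop_sel], genes$tss[loop_sel] - 100,
                               genes$tss[loop_sel] + 100))
  } else {
    loop_set(genomic_intervals(character(), numeric(), numeric()),
             genomic_intervals(character(), numeric(), numeric()))
  }
  list(variants = variants, peaks = peaks, genes = genes,
       promoters = promoters, promoter_pairs = promoter_pairs,
       peak_gene_pairs = peak_gene_pairs, abc_pairs = abc_pairs,
       loops = loops,
       enhancer_snps = rsid[prof[, "in_starrseq_enhancer"]],
       functional_snps = rsid[prof[, "functional_snp"]],
       eqtl_snps = rsid[prof[, "significant_eqtl"]],
       high_effect_snps = rsid[prof[, "chrombpnet_high_effect"]],
       truth = list(profiles = prof,
                    planted_prioritized = rsid[rowSums(prof) >= 3],
                    seed = seed))
}

#' Default pipeline configuration
#'
#' All analysis thresholds at their reference defaults (LD R-squared 0.5;
#' correlation cutoffs 0.3; peak-gene distance 250 kb; ABC 0.025 and 500
#' bp; STARR fold change 1.5, adjusted p 0.05, control percentile 0.80,
#' min barcodes 5; variant effect |log2FC| 0.25 at FDR 0.01; eQTL FDR
#' 0.05; k_min 3) plus a synthetic-data block sized for a desk-scale run.
#'
#' @param seed master seed; per-stage seeds are derived from it
#' @return nested configuration list
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    thresholds = list(
      r2 = 0.5, correlation = 0.3, max_dist = 250000,
      abc_score = 0.025, abc_min_tss_dist = 500,
      starr_fc = 1.5, starr_padj = 0.05, starr_percentile = 0.80,
      min_barcodes = 5, effect_log2fc = 0.25, effect_fdr = 0.01,
      eqtl_fdr = 0.05, k_min = 3),
    synthetic = list(
      n_individuals = 500, n_blocks = 12, block_size = 8, block_r2 = 0.8,
      n_test_snps = 400, n_control_snps = 150, frac_enhancer = 0.2,
      allelic_effect_grid = c(1, 1.5, 2), bc_mean_input = 3000,
      bc_mean_output = 300, dispersion = 0.05, n_reps = 4,
      n_variants_integration = 200, n_pred_variants = 200,
      cell_types = c("RPE", "endothelial", "fibroblast", "macrophage"),
      n_folds = 5, frac_high_effect = 0.05, pred_effect_size = 1,
      frac_eqtl = 0.2))
}

#' Validate a pipeline configuration
#'
#' @param config configuration list (see [default_config()])
#' @return character vector of problems (empty when valid)
#' @export
validate_config <- function(config) {
  errs <- character(0)
  th <- config$thresholds
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(!is.null(th), "thresholds: block missing")
  if (!is.null(th)) {
    chk(th$r2 >= 0 && th$r2 <= 1, "thresholds$r2: must be in [0,1]")
    chk(th$correlation >= -1 && th$correlation <= 1,
        "thresholds$correlation: must be in [-1,1]")
    chk(th$max_dist > 0, "thresholds$max_dist: must be > 0")
    chk(th$abc_score > 0 && th$abc_score < 1, "thresholds$abc_score: must be in (0,1)")
    chk(th$starr_fc > 1, "thresholds$starr_fc: must exceed 1")
    chk(th$starr_percentile > 0 && th$starr_percentile <= 1,
        "thresholds$starr_percentile: must be in (0,1]")
    chk(th$min_barcodes >= 1, "thresholds$min_barcodes: must be >= 1")
    chk(th$eqtl_fdr > 0 && th$eqtl_fdr <= 1, "thresholds$eqtl_fdr: must be in (0,1]")
    chk(th$k_min >= 0, "thresholds$k_min: must be >= 0")
  }
  chk(!is.null(config$synthetic), "synthetic: block missing (real-data paths not configured)")
  chk(is.numeric(config$seed) && length(config$seed) == 1, "seed: must be a single number")
  errs
}

#' Run the full synthetic pipeline
#'
#' Generates every input from the config's synthetic block, runs all
#' stages (catalog, STARR-seq, variant effect, eQTL, integration) and
#' writes stage outputs, summaries and a log to `out_dir`. Re-running with
#' the same config reproduces the outputs.
#'
#' @param config configuration from [default_config()]
#' @param out_dir output directory (created); `NULL` for no files
#' @return list of stage results, invisibly when writing files
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  errs <- validate_config(config)
  if (length(errs)) stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  th <- config$thresholds; sy <- config$synthetic
  seed <- config$seed
  log_lines <- character(0)
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  ## stage 1: catalog (LD expansion on simulated genotypes)
  blocks <- rep(list(list(n_variants = sy$block_size, r2 = sy$block_r2)), sy$n_blocks)
  gen <- sim_genotypes(sy$n_individuals, blocks, seed = seed)
  index_ids <- gen$variants$variant_id[gen$variants$is_index]
  locus_of <- stats::setNames(gen$variants$block[gen$variants$is_index], index_ids)
  expanded <- ld_expand(index_ids, gen$genotypes, r2_threshold = th$r2,
                        index_locus = locus_of)
  say("catalog: %d index variants expanded to %d variants", length(index_ids),
      nrow(expanded))

  ## stage 2: STARR-seq
  starr <- sim_starrseq(sy$n_test_snps, sy$n_control_snps, sy$frac_enhancer,
                        effect_grid = sy$allelic_effect_grid,
                        bc_mean_input = sy$bc_mean_input,
                        bc_mean_output = sy$bc_mean_output,
                        dispersion = sy$dispersion, n_reps = sy$n_reps,
                        seed = seed + 1)
  qc <- qc_filter_oligos(starr$counts, min_barcodes = th$min_barcodes)
  enh <- call_enhancers(qc$object, "naive", log2fc_min = log2(th$starr_fc),
                        padj_max = th$starr_padj)
  alle <- allelic_activity(qc$object, "naive")
  thr <- empirical_threshold(abs(alle$log2fc[alle$is_control]),
                             q = th$starr_percentile)
  fun <- call_functional_snps(alle, enh$snp_id[enh$enhancer & !enh$is_control],
                              thr, padj_max = th$starr_padj)
  say("starrseq: %d/%d SNPs passed QC (%.1f%%); %d enhancers; %d functional SNPs",
      qc$n_snps_retained, qc$n_snps_total, qc$pct_retained,
      sum(enh$enhancer & !enh$is_control), sum(fun$functional))

  ## stage 3: variant effect on predicted counts
  pred <- sim_predicted_counts(sprintf("pv%04d", seq_len(sy$n_pred_variants)),
                               sy$cell_types, n_folds = sy$n_folds,
                               frac_high_effect = sy$frac_high_effect,
                               effect_size = sy$pred_effect_size,
                               seed = seed + 2)
  veff <- variant_effect_scores(pred$predictions, fc_min = th$effect_log2fc,
                                fdr_max = th$effect_fdr)
  say("variant_effect: %d/%d variants high effect",
      sum(veff$per_variant$high_effect), nrow(veff$per_variant))

  ## stage 4: integration with planted criterion profiles
  integ <- sim_integration(sy$n_variants_integration, seed = seed + 3)
  planted_eqtl <- integ$variants$rsid %in% integ$eqtl_snps
  eqtl <- data.frame(variant = integ$variants$rsid,
                     gene = integ$genes$gene_id,
                     tissue_region = "macular",
                     fdr = ifelse(planted_eqtl, 0.01, 0.5),
                     stringsAsFactors = FALSE)
  eq_set <- eqtl_significant(eqtl, fdr_max = th$eqtl_fdr)
  cm <- build_criteria_matrix(integ$variants, integ$peaks,
                              integ$promoter_pairs, integ$peak_gene_pairs,
                              integ$loops, integ$promoters, integ$abc_pairs,
                              integ$enhancer_snps, integ$functional_snps,
                              eq_set, integ$high_effect_snps)
  pri <- call_prioritized(cm, k_min = th$k_min)
  up <- upset_summary(cm)
  say("integration: %d/%d accessible variants prioritized (%.1f%%)",
      pri$n_prioritized, pri$n_accessible, pri$pct_of_accessible)
  loci <- sort(unique(integ$variants$locus_id))
  reports <- lapply(loci, function(l)
    locus_report(l, transform(integ$variants, is_index = FALSE), cm,
                 pri$prioritized))
  names(reports) <- as.character(loci)

  res <- list(config = config, catalog = expanded,
              starrseq = list(qc = qc[c("n_snps_total", "n_snps_retained", "pct_retained")],
                              enhancers = enh, allelic = alle,
                              control_threshold = thr, functional = fun,
                              truth = starr$truth),
              variant_effect = veff, criteria_matrix = cm,
              prioritized = pri, upset = up, locus_reports = reports,
              integration_truth = integ$truth, log = log_lines)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(expanded, file.path(out_dir, "catalog.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(enh, file.path(out_dir, "starr_enhancers.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(fun, file.path(out_dir, "starr_functional.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(veff$per_variant, file.path(out_dir, "variant_effect.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(cm), file.path(out_dir, "criteria_matrix.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(up$combinations, file.path(out_dir, "upset_combinations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed,
           n_prioritized = pri$n_prioritized,
           n_accessible = pri$n_accessible,
           pct_of_accessible = pri$pct_of_accessible,
           starr_pct_qc = qc$pct_retained,
           n_high_effect = sum(veff$per_variant$high_effect)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "run.log"))
    return(invisible(res))
  }
  res
}
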