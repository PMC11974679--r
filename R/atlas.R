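## Peak-space operations: multiome cell QC, promoter windows, variant-peak
## intersection, unique-base enrichment, and the generic thresholded
## group comparison behind marker/differential feature calling.

#' Filter cells on joint RNA/ATAC quality metrics
#'
#' A cell is kept iff all five conditions hold: 200-10,000 RNA transcripts
#' (inclusive), < 1% mitochondrial reads, < 5% ribosomal reads, TSS
#' enrichment > 4, and > 1,000 ATAC fragments.
#'
#' @param per_cell_metrics data.frame with columns barcode, n_transcripts,
#'   pct_mito, pct_ribo, tss_enrichment, n_fragments
#' @return character vector of kept barcodes
#' @export
qc_filter_cells <- function(per_cell_metrics) {
  req <- c("barcode", "n_transcripts", "pct_mito", "pct_ribo",
           "tss_enrichment", "n_fragments")
  miss <- setdiff(req, names(per_cell_metrics))
  if (length(miss)) stop("missing metric column(s): ", paste(miss, collapse = ", "))
  m <- per_cell_metrics
  keep <- m$n_transcripts >= 200 & m$n_transcripts <= 10000 &
    m$pct_mito < 1 & m$pct_ribo < 5 & m$tss_enrichment > 4 & m$n_fragments > 1000
  m$barcode[keep]
}

#' Promoter windows around gene TSSs
#'
#' 2,000 bp upstream to 100 bp downstream of the TSS in transcription
#' orientation, half-open and clipped at the chromosome start: a + strand
#' gene at TSS t gets `[t-2000, t+101)`, a - strand gene `[t-100, t+2001)`.
#'
#' @param genes gene-model data.frame (gene_id, chrom, tss, strand)
#' @param upstream,downstream window extents in bp
#' @return data.frame of promoter intervals with gene_id
#' @export
make_promoters <- function(genes, upstream = 2000, downstream = 100) {
  if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream + 1, genes$tss + upstream + 1)
  start <- pmax(0, start)
  out <- genomic_intervals(genes$chrom, start, end, genes$strand)
  out$gene_id <- genes$gene_id
  out
}

#' Intersect variant positions with per-cell-type peak sets
#'
#' A variant is accessible in a cell type iff its (single reference)
#' position falls inside at least one of that cell type's peaks, under the
#' half-open convention. Returns per-(variant, cell type) calls, the set of
#' variants accessible in >= 1 cell type, and the per-variant count of
#' accessible cell types.
#'
#' @param variants data.frame with rsid, chrom, pos (0-based)
#' @param peaksets named list of peak interval data.frames
#' @return list: `calls` (rsid, cell_type, accessible, containing peak
#'   coords), `accessible_variants`, `n_cell_types` (named vector)
#' @export
intersect_variants_peaks <- function(variants, peaksets) {
  calls <- list()
  for (ct in names(peaksets)) {
    ps <- peaksets[[ct]]
    rows <- .containing_rows(variants$chrom, variants$pos, ps)
    first <- vapply(rows, function(r) if (length(r)) r[1] else NA_integer_, integer(1))
    acc <- !is.na(first)
    calls[[ct]] <- data.frame(
      rsid = variants$rsid, cell_type = ct, accessible = acc,
      peak_chrom = ifelse(acc, ps$chrom[first], NA_character_),
      peak_start = ifelse(acc, ps$start[first], NA_real_),
      peak_end = ifelse(acc, ps$end[first], NA_real_),
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  n_ct <- tapply(calls$accessible, calls$rsid, sum)
  n_ct <- stats::setNames(as.integer(n_ct[variants$rsid]), variants$rsid)
  list(calls = calls,
       accessible_variants = variants$rsid[n_ct > 0],
       n_cell_types = n_ct)
}

#' Variant enrichment in accessibility peaks, normalized to baseline tissues
#'
#' Per tissue: count variants accessible in the tissue's (merged) peaks,
#' divide by the number of unique bases covered by those peaks, and
#' normalize the resulting rate to the mean rate over baseline tissues.
#'
#' @param variants data.frame with rsid, chrom, pos
#' @param peaksets named list of peak interval data.frames (targets and
#'   baselines together)
#' @param target_tissues,baseline_tissues names into `peaksets`
#' @return data.frame: tissue, n_accessible, unique_bases, raw_rate,
#'   normalized_enrichment, is_baseline
#' @export
variant_enrichment <- function(variants, peaksets, target_tissues, baseline_tissues) {
  if (length(baseline_tissues) < 1) stop("need >= 1 baseline tissue")
  tissues <- unique(c(target_tissues, baseline_tissues))
  rows <- lapply(tissues, function(ts) {
    mb <- merge_unique_bases(peaksets[[ts]])
    n_acc <- sum(points_in_intervals(variants$chrom, variants$pos, mb$merged))
    if (mb$unique_bases <= 0) stop("tissue with zero unique bases: ", ts)
    data.frame(tissue = ts, n_accessible = n_acc, unique_bases = mb$unique_bases,
               raw_rate = n_acc / mb$unique_bases,
               is_baseline = ts %in% baseline_tissues, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  base_mean <- mean(out$raw_rate[out$is_baseline])
  if (base_mean == 0) stop("baseline mean rate is zero; normalization undefined")
  out$normalized_enrichment <- out$raw_rate / base_mean
  out
}

#' Thresholded group comparison for marker / differential features
#'
#' Per feature, a Wilcoxon rank-sum test (mid-ranks, normal approximation
#' with continuity correction) of the target group against the rest (or
#' against a single reference group in pairwise mode), Benjamini-Hochberg
#' FDR across features, and a log2 fold change of pseudocounted group
#' means. A feature is called iff `log2fc >= log2fc_min`, `fdr <= fdr_max`,
#' and, when `min_fraction` is set, the fraction of target-group samples
#' with nonzero signal is `>= min_fraction`.
#'
#' Preset thresholds used in this package: marker peaks (log2FC >= 0.5,
#' FDR <= 0.1), differential accessibility (0.5, 0.25), marker genes
#' (log2FC >= 1, fraction >= 0.6), subpopulation genes (0.5, fraction 0.3).
#'
#' @param feature_matrix features x samples numeric matrix
#' @param group_labels per-sample group labels
#' @param target_group group to test
#' @param reference_group optional single comparison group (pairwise mode);
#'   default is all other samples
#' @param log2fc_min minimum log2 fold change (target over rest)
#' @param fdr_max maximum BH-adjusted p
#' @param min_fraction optional minimum expressing fraction in the target group
#' @param pseudocount added to group means before the log2 ratio
#' @return data.frame of significant features (feature, log2fc, p, fdr,
#'   fraction); the full unfiltered table is in `attr(, "all")`
#' @export
group_differential <- function(feature_matrix, group_labels, target_group,
                               reference_group = NULL, log2fc_min = 0.5,
                               fdr_max = 0.1, min_fraction = NULL,
                               pseudocount = 1) {
  if (length(group_labels) != ncol(feature_matrix)) {
    stop("group_labels length must equal the number of samples")
  }
  if (length(unique(group_labels)) < 2) stop("need >= 2 groups")
  tgt <- which(group_labels == target_group)
  ref <- if (is.null(reference_group)) which(group_labels != target_group)
         else which(group_labels == reference_group)
  if (length(tgt) < 3 || length(ref) < 3) stop("each compared group needs >= 3 samples")
  a <- feature_matrix[, tgt, drop = FALSE]
  b <- feature_matrix[, ref, drop = FALSE]
  p <- vapply(seq_len(nrow(feature_matrix)), function(i) {
    x <- a[i, ]; y <- b[i, ]
    if (stats::sd(c(x, y)) == 0) return(1)
    suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  lfc <- log2((rowMeans(a) + pseudocount) / (rowMeans(b) + pseudocount))
  frac <- rowMeans(a > 0)
  fdr <- p.adjust(p, method = "BH")
  all_tab <- data.frame(feature = rownames(feature_matrix) %||%
                          as.character(seq_len(nrow(feature_matrix))),
                        log2fc = lfc, p = p, fdr = fdr, fraction = frac,
                        stringsAsFactors = FALSE)
  keep <- all_tab$log2fc >= log2fc_min & all_tab$fdr <= fdr_max
  if (!is.null(min_fraction)) keep <- keep & all_tab$fraction >= min_fraction
  sig <- all_tab[keep, , drop = FALSE]
  rownames(sig) <- NULL
  attr(sig, "all") <- all_tab
  sig
}
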