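## Assemble the eight regulatory-evidence criteria for accessible variants,
## apply the >=3-of-8 rule, and produce upset and locus-level reports.

criteria_names <- c("coaccessible_with_promoter", "accessibility_correlated_with_gene",
                    "hichip_linked", "abc_connected", "in_starrseq_enhancer",
                    "functional_snp", "significant_eqtl", "chrombpnet_high_effect")

#' Variants with a significant eQTL
#'
#' A variant qualifies iff it has at least one association with
#' FDR <= 0.05 (inclusive) in either the macular or non-macular tissue
#' region.
#'
#' @param eqtl_table data.frame: variant, tissue_region, fdr
#' @param fdr_max inclusive FDR cutoff (default 0.05)
#' @return character vector of significant-eQTL variant ids
#' @export
eqtl_significant <- function(eqtl_table, fdr_max = 0.05) {
  bad <- setdiff(unique(eqtl_table$tissue_region), c("macular", "non_macular"))
  if (length(bad)) stop("unknown tissue region(s): ", paste(bad, collapse = ", "))
  unique(eqtl_table$variant[eqtl_table$fdr <= fdr_max])
}

#' Build the 8-criterion matrix for accessible variants
#'
#' Rows are the accessible variants; columns the eight criteria. Criteria
#' 1 (promoter co-accessibility), 2 (peak-gene correlation) and 4 (ABC) are
#' inherited from the variant's containing peak(s) -- a variant inside two
#' peaks inherits the union. Criterion 3 requires the variant position to
#' lie in a loop anchor whose partner anchor overlaps a gene promoter.
#' Criteria 5-8 are direct set membership by rsid.
#'
#' @param accessible_variants data.frame: rsid, chrom, pos
#' @param peaks peak universe data.frame (peak_id + coordinates); every
#'   accessible variant must fall in >= 1 peak
#' @param promoter_pairs data.frame (peak_id, gene_id) from
#'   [promoter_coaccessible()]
#' @param peak_gene_pairs data.frame (peak_id, gene_id) from
#'   [peak_gene_links()]
#' @param loops loop-set data.frame
#' @param promoters promoter windows with gene_id
#' @param abc_pairs data.frame (element_id, gene_id) from
#'   [abc_scores()] connections (element ids are peak ids)
#' @param enhancer_snps,functional_snps,eqtl_snps,high_effect_snps
#'   character vectors of variant ids
#' @return data.frame of class `criteria_matrix`: rsid, the eight logical
#'   columns, n_criteria_met
#' @export
build_criteria_matrix <- function(accessible_variants, peaks, promoter_pairs,
                                  peak_gene_pairs, loops, promoters, abc_pairs,
                                  enhancer_snps, functional_snps, eqtl_snps,
                                  high_effect_snps) {
  v <- accessible_variants
  rows <- .containing_rows(v$chrom, v$pos, peaks)
  if (any(vapply(rows, length, integer(1)) == 0)) {
    stop("accessible variant with no containing peak: ",
         paste(v$rsid[vapply(rows, length, integer(1)) == 0], collapse = ", "))
  }
  peak_ids <- lapply(rows, function(r) peaks$peak_id[r])
  in_pairs <- function(pairs, id_col) {
    vapply(peak_ids, function(pk) any(pk %in% pairs[[id_col]]), logical(1))
  }
  c1 <- in_pairs(promoter_pairs, "peak_id")
  c2 <- in_pairs(peak_gene_pairs, "peak_id")
  lo <- loop_overlap(loops,
                     targets = data.frame(target_id = v$rsid, chrom = v$chrom,
                                          pos = v$pos, stringsAsFactors = FALSE),
                     promoters = promoters)
  c3 <- v$rsid %in% lo$links$target_id
  c4 <- in_pairs(abc_pairs, names(abc_pairs)[1])
  m <- data.frame(rsid = v$rsid,
                  coaccessible_with_promoter = c1,
                  accessibility_correlated_with_gene = c2,
                  hichip_linked = c3,
                  abc_connected = c4,
                  in_starrseq_enhancer = v$rsid %in% enhancer_snps,
                  functional_snp = v$rsid %in% functional_snps,
                  significant_eqtl = v$rsid %in% eqtl_snps,
                  chrombpnet_high_effect = v$rsid %in% high_effect_snps,
                  stringsAsFactors = FALSE)
  m$n_criteria_met <- rowSums(m[, criteria_names])
  class(m) <- c("criteria_matrix", "data.frame")
  m
}

#' Call prioritized variants (>= k of 8 criteria)
#'
#' @param matrix a `criteria_matrix`
#' @param k_min minimum number of criteria (inclusive; default 3)
#' @param n_catalog optional size of the full noncoding/synonymous catalog,
#'   for the catalog-level percentage
#' @return list: `prioritized` (rsids), `n_prioritized`, `n_accessible`,
#'   `pct_of_accessible`, `pct_of_catalog` (percentages to one decimal,
#'   halves away from zero)
#' @export
call_prioritized <- function(matrix, k_min = 3, n_catalog = NULL) {
  pri <- matrix$rsid[matrix$n_criteria_met >= k_min]
  out <- list(prioritized = pri, n_prioritized = length(pri),
              n_accessible = nrow(matrix),
              pct_of_accessible = round_half_away(100 * length(pri) / nrow(matrix), 1),
              pct_of_catalog = if (!is.null(n_catalog))
                round_half_away(100 * length(pri) / n_catalog, 1) else NA_real_)
  out
}

#' Criterion-combination (upset) summary
#'
#' Counts of accessible variants per exact criterion combination (they
#' partition the rows, including the all-false combination) plus marginal
#' counts and percentages per criterion.
#'
#' @param matrix a `criteria_matrix`
#' @return list: `combinations` (combination string, count, pct),
#'   `marginals` (criterion, count, pct)
#' @export
upset_summary <- function(matrix) {
  flags <- as.matrix(matrix[, criteria_names])
  combo <- apply(flags, 1, function(r) {
    s <- criteria_names[as.logical(r)]
    if (!length(s)) "(none)" else paste(s, collapse = "+")
  })
  tb <- sort(table(combo), decreasing = TRUE)
  combinations <- data.frame(combination = names(tb), count = as.integer(tb),
                             pct = round_half_away(100 * as.integer(tb) / nrow(matrix), 1),
                             stringsAsFactors = FALSE)
  marginals <- data.frame(criterion = criteria_names,
                          count = colSums(flags),
                          pct = round_half_away(100 * colSums(flags) / nrow(matrix), 1),
                          stringsAsFactors = FALSE, row.names = NULL)
  list(combinations = combinations, marginals = marginals)
}

#' Per-locus report
#'
#' Lists index variants with accessibility status and ranks the locus's
#' accessible variants by criteria met (ties broken by |allelic log2FC|,
#' then rsid). Flags the "index inaccessible, alternative candidate"
#' pattern when the top prioritized variant is not an index variant and no
#' index variant at the locus is accessible.
#'
#' @param locus_id locus identifier present in the catalog
#' @param catalog variant data.frame with rsid, locus_id, is_index
#' @param matrix a `criteria_matrix`
#' @param prioritized character vector from [call_prioritized()]
#' @param allelic optional allelic-activity results (for tie-breaking and
#'   annotation)
#' @param linked_genes optional data.frame (rsid, gene_id, strategy)
#' @return list of class `locus_report`
#' @export
locus_report <- function(locus_id, catalog, matrix, prioritized,
                         allelic = NULL, linked_genes = NULL) {
  loc <- catalog[!is.na(catalog$locus_id) & catalog$locus_id == locus_id, , drop = FALSE]
  if (!nrow(loc)) stop("unknown locus: ", locus_id)
  acc <- matrix[matrix$rsid %in% loc$rsid, , drop = FALSE]
  idx <- loc[loc$is_index, , drop = FALSE]
  idx$accessible <- idx$rsid %in% matrix$rsid
  abs_fc <- stats::setNames(rep(0, nrow(acc)), acc$rsid)
  if (!is.null(allelic)) {
    hit <- match(acc$rsid, allelic$snp_id)
    abs_fc[!is.na(hit)] <- abs(allelic$log2fc[hit[!is.na(hit)]])
  }
  ord <- order(-acc$n_criteria_met, -abs_fc[acc$rsid], acc$rsid)
  acc <- acc[ord, , drop = FALSE]
  rownames(acc) <- NULL
  pri <- intersect(acc$rsid, prioritized)
  alt_candidate <- length(pri) > 0 && !any(idx$accessible) && !pri[1] %in% idx$rsid
  genes <- if (!is.null(linked_genes))
    linked_genes[linked_genes$rsid %in% pri, , drop = FALSE] else NULL
  structure(list(locus_id = locus_id, index_variants = idx,
                 candidates = acc, prioritized = pri,
                 index_inaccessible_alternative = alt_candidate,
                 linked_genes = genes),
            class = "locus_report")
}

#' @export
print.locus_report <- function(x, ...) {
  cat(sprintf("Locus %s: %d index variant(s), %d accessible candidate(s), %d prioritized\n",
              as.character(x$locus_id), nrow(x$index_variants),
              nrow(x$candidates), length(x$prioritized)))
  for (i in seq_len(nrow(x$index_variants))) {
    cat(sprintf("  index %s: %s\n", x$index_variants$rsid[i],
                if (x$index_variants$accessible[i]) "accessible" else "inaccessible"))
  }
  if (x$index_inaccessible_alternative) {
    cat(sprintf("  index inaccessible; alternative candidate: %s\n", x$prioritized[1]))
  }
  invisible(x)
}
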