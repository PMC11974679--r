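## Risk-variant catalog: LD expansion of index variants, merging with a
## credible set, consequence classification, AlphaMissense binning, and the
## catalog summary.

#' Squared correlation (R-squared) between two dosage vectors
#'
#' @param dosages_a,dosages_b equal-length numeric vectors (length >= 3),
#'   neither constant
#' @return R-squared in [0, 1]
#' @export
compute_r2 <- function(dosages_a, dosages_b) {
  if (length(dosages_a) != length(dosages_b)) stop("dosage vectors must have equal length")
  if (length(dosages_a) < 3) stop("need >= 3 individuals to compute R2")
  if (stats::sd(dosages_a) == 0 || stats::sd(dosages_b) == 0) {
    stop("R2 undefined for a constant dosage vector")
  }
  cor(dosages_a, dosages_b)^2
}

#' Linkage-disequilibrium expansion of index variants
#'
#' Returns every variant in the genotype matrix whose R-squared with at
#' least one index variant strictly exceeds `r2_threshold`, annotated with
#' the maximal R-squared and the index variant attaining it. Index variants
#' are always included (R-squared 1 to self) regardless of the threshold.
#' Index variants absent from the matrix are replaced through the caller
#' supplied `substitutions` table (index_rsid -> substitute_rsid), mirroring
#' the substitution of an index by the next-most-probable causal variant;
#' an absent index with no substitute is an error.
#'
#' Monomorphic variants (constant dosage) have undefined correlation and are
#' never returned as partners.
#'
#' @param index_variants character vector of index variant ids
#' @param genotype_matrix variants x individuals dosage matrix with rownames
#' @param r2_threshold strict lower bound on R-squared (default 0.5)
#' @param substitutions optional data.frame(index_rsid, substitute_rsid)
#' @param index_locus optional named vector mapping index rsid -> locus id
#' @return data.frame: rsid, r2_to_index, index_rsid, locus_id, is_index
#' @export
ld_expand <- function(index_variants, genotype_matrix, r2_threshold = 0.5,
                      substitutions = NULL, index_locus = NULL) {
  resolved <- vapply(index_variants, function(iv) {
    if (iv %in% rownames(genotype_matrix)) return(iv)
    if (!is.null(substitutions)) {
      hit <- substitutions$substitute_rsid[substitutions$index_rsid == iv]
      if (length(hit) == 1 && hit %in% rownames(genotype_matrix)) return(hit)
    }
    stop("index variant not in genotype matrix and no substitute available: ", iv)
  }, character(1))
  usable <- apply(genotype_matrix, 1, function(x) stats::sd(x) > 0)
  out <- data.frame(rsid = character(), r2_to_index = numeric(),
                    index_rsid = character(), stringsAsFactors = FALSE)
  best_r2 <- stats::setNames(rep(-Inf, nrow(genotype_matrix)), rownames(genotype_matrix))
  best_idx <- stats::setNames(rep(NA_character_, nrow(genotype_matrix)), rownames(genotype_matrix))
  for (iv in resolved) {
    if (!usable[iv]) next
    r <- rep(NA_real_, nrow(genotype_matrix))
    r[usable] <- as.vector(cor(t(genotype_matrix[usable, , drop = FALSE]),
                               genotype_matrix[iv, ]))^2
    upd <- which(!is.na(r) & r > best_r2)
    best_r2[upd] <- r[upd]
    best_idx[upd] <- iv
  }
  keep <- names(best_r2)[!is.na(best_idx) & best_r2 > r2_threshold]
  keep <- union(keep, resolved)
  res <- data.frame(rsid = keep,
                    r2_to_index = ifelse(keep %in% resolved, 1, best_r2[keep]),
                    index_rsid = ifelse(keep %in% resolved, keep, best_idx[keep]),
                    is_index = keep %in% resolved, stringsAsFactors = FALSE)
  if (!is.null(index_locus)) res$locus_id <- unname(index_locus[res$index_rsid])
  res <- res[order(res$rsid), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge an LD-expanded variant list with a credible set
#'
#' Union keyed on (chrom, pos, ref_allele, alt_allele); on key collisions
#' the expanded list's record wins (including its rsid). A single rsid
#' appearing with two different allele keys is a conflict error.
#'
#' @param expanded,credible_set variant data.frames with columns rsid,
#'   chrom, pos, ref_allele, alt_allele (plus any annotation columns)
#' @return deduplicated union, expanded-list records first
#' @export
merge_credible_set <- function(expanded, credible_set) {
  key <- function(d) paste(d$chrom, d$pos, d$ref_allele, d$alt_allele, sep = "|")
  ka <- key(expanded); kb <- key(credible_set)
  combined_rsid <- c(expanded$rsid, credible_set$rsid)
  combined_key <- c(ka, kb)
  bad <- tapply(combined_key, combined_rsid, function(x) length(unique(x)) > 1)
  if (any(bad)) {
    stop("rsid maps to conflicting allele keys: ",
         paste(names(bad)[bad], collapse = ", "))
  }
  add <- credible_set[!(kb %in% ka), , drop = FALSE]
  common <- intersect(names(expanded), names(add))
  out <- rbind(expanded[, common, drop = FALSE], add[, common, drop = FALSE])
  extra_a <- setdiff(names(expanded), common)
  for (cn in extra_a) out[[cn]] <- c(expanded[[cn]], rep(NA, nrow(add)))
  rownames(out) <- NULL
  out
}

.consequence_map <- c(
  missense = "protein_altering", stop_gained = "protein_altering",
  stop_lost = "protein_altering", start_lost = "protein_altering",
  frameshift = "protein_altering", inframe_insertion = "protein_altering",
  inframe_deletion = "protein_altering", splice = "protein_altering",
  splice_donor = "protein_altering", splice_acceptor = "protein_altering",
  splice_region = "protein_altering",
  synonymous = "synonymous", stop_retained = "synonymous",
  intronic = "noncoding", intron = "noncoding", intergenic = "noncoding",
  UTR = "noncoding", UTR5 = "noncoding", UTR3 = "noncoding",
  `5_prime_UTR` = "noncoding", `3_prime_UTR` = "noncoding",
  upstream = "noncoding", downstream = "noncoding", regulatory = "noncoding",
  promoter = "noncoding", enhancer = "noncoding",
  non_coding_transcript = "noncoding", TF_binding_site = "noncoding",
  ## already-classified labels map to themselves (idempotence)
  protein_altering = "protein_altering", noncoding = "noncoding")

#' Classify a raw consequence label into the three catalog classes
#'
#' Splice-altering labels are routed to `protein_altering` (they change the
#' protein product even though the base change is not in codon space; this
#' is a documented judgment call). Unknown labels are an error, never
#' silently noncoding. The mapping is idempotent over its own output.
#'
#' @param raw_consequence_label character vector of annotation labels
#' @return character vector over {protein_altering, synonymous, noncoding}
#' @export
classify_consequence <- function(raw_consequence_label) {
  out <- .consequence_map[raw_consequence_label]
  if (any(is.na(out))) {
    stop("unknown consequence label(s): ",
         paste(unique(raw_consequence_label[is.na(out)]), collapse = ", "),
         "; known labels: ", paste(names(.consequence_map), collapse = ", "))
  }
  unname(out)
}

#' Bin an AlphaMissense score into pathogenicity classes
#'
#' Likely benign for scores < 0.34, likely pathogenic for scores > 0.565,
#' ambiguous otherwise (boundaries are therefore ambiguous).
#'
#' @param am_score numeric scores in [0, 1]
#' @return character vector over {likely_benign, ambiguous, likely_pathogenic}
#' @export
alphamissense_bin <- function(am_score) {
  if (any(is.na(am_score)) || any(am_score < 0 | am_score > 1)) {
    stop("AlphaMissense scores must lie in [0,1]")
  }
  ifelse(am_score < 0.34, "likely_benign",
         ifelse(am_score > 0.565, "likely_pathogenic", "ambiguous"))
}

#' Summarize a variant catalog
#'
#' Counts and printed-style percentages (one decimal, halves away from
#' zero): noncoding-or-synonymous fraction, SNP fraction (single-base ref
#' and alt), and AlphaMissense class counts among scored variants.
#'
#' @param variants variant data.frame with columns consequence, ref_allele,
#'   alt_allele and optional am_score
#' @return list of class `catalog_summary`
#' @export
summarize_catalog <- function(variants) {
  if (nrow(variants) == 0) stop("empty catalog")
  n_total <- nrow(variants)
  ncs <- sum(variants$consequence %in% c("noncoding", "synonymous"))
  n_snp <- sum(nchar(variants$ref_allele) == 1 & nchar(variants$alt_allele) == 1)
  scored <- variants[!is.na(variants$am_score %||% rep(NA, n_total)), , drop = FALSE]
  am_counts <- c(likely_benign = 0, ambiguous = 0, likely_pathogenic = 0)
  if (nrow(scored) > 0) {
    tb <- table(alphamissense_bin(scored$am_score))
    am_counts[names(tb)] <- as.numeric(tb)
  }
  out <- list(
    n_total = n_total,
    n_noncoding_or_synonymous = ncs,
    pct_noncoding_or_synonymous = round_half_away(100 * ncs / n_total, 1),
    n_protein_altering = n_total - ncs,
    n_snps = n_snp,
    pct_snps = round_half_away(100 * n_snp / n_total, 1),
    n_am_scored = nrow(scored),
    am_class_counts = am_counts,
    pct_am_likely_benign = if (nrow(scored) > 0)
      round_half_away(100 * am_counts[["likely_benign"]] / nrow(scored), 1) else NA_real_)
  class(out) <- "catalog_summary"
  out
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat(sprintf("Variant catalog: %d variants\n", x$n_total))
  cat(sprintf("  noncoding or synonymous: %d (%.1f%%)\n",
              x$n_noncoding_or_synonymous, x$pct_noncoding_or_synonymous))
  cat(sprintf("  protein-altering:        %d\n", x$n_protein_altering))
  cat(sprintf("  SNPs:                    %d (%.1f%%)\n", x$n_snps, x$pct_snps))
  if (x$n_am_scored > 0) {
    cat(sprintf("  AlphaMissense-scored:    %d (likely benign %d = %.1f%%, ambiguous %d, likely pathogenic %d)\n",
                x$n_am_scored, x$am_class_counts[["likely_benign"]],
                x$pct_am_likely_benign, x$am_class_counts[["ambiguous"]],
                x$am_class_counts[["likely_pathogenic"]]))
  }
  invisible(x)
}
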