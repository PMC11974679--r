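## Allele-specific STARR-seq: amplicon parsing, unique-barcode counting,
## oligo QC, median-of-ratios normalization, enhancer calling against the
## input library, allelic-activity testing with empirical-Bayes moderation,
## control-percentile thresholds, functional-SNP calls, and QQ quantiles.

#' The adapter separating the insert from the degenerate barcode
#' @export
starr_adapter <- "GCTAGCCATTGCGTGTAGAG"

#' STARR-seq oligo count container
#'
#' @param counts integer matrix, oligos x samples; rownames `snp|allele`
#' @param oligo_info data.frame: oligo_id, snp_id, allele ("ref"/"alt"),
#'   is_control
#' @param sample_info data.frame: sample_id, class ("input"/"output"),
#'   condition, replicate
#' @return object of class `oligo_counts`
#' @export
oligo_counts <- function(counts, oligo_info, sample_info) {
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (!identical(rownames(counts), oligo_info$oligo_id)) {
    counts <- counts[oligo_info$oligo_id, , drop = FALSE]
  }
  if (!identical(colnames(counts), sample_info$sample_id)) {
    counts <- counts[, sample_info$sample_id, drop = FALSE]
  }
  tab <- table(oligo_info$snp_id)
  if (any(tab != 2)) {
    stop("every SNP needs exactly two allele rows; offending: ",
         paste(names(tab)[tab != 2], collapse = ", "))
  }
  structure(list(counts = counts, oligo_info = oligo_info,
                 sample_info = sample_info), class = "oligo_counts")
}

#' @export
print.oligo_counts <- function(x, ...) {
  cat(sprintf("oligo_counts: %d oligos (%d SNPs, %d controls) x %d samples (%d input, %d output)\n",
              nrow(x$counts), length(unique(x$oligo_info$snp_id)),
              sum(x$oligo_info$is_control) / 2, ncol(x$counts),
              sum(x$sample_info$class == "input"),
              sum(x$sample_info$class == "output")))
  invisible(x)
}

#' Parse one merged STARR-seq amplicon read
#'
#' The read layout is insert + adapter + 10-nt degenerate barcode. The
#' adapter must be present, the trailing barcode exactly 10 nt, and the
#' insert must match an oligo reference sequence exactly (no barcode error
#' correction). Failures return a categorized rejection, never an error.
#'
#' @param read_sequence character scalar (may be empty)
#' @param oligo_lookup named character vector: insert sequence -> oligo_id
#' @param adapter adapter sequence
#' @return list with `status` ("ok", "no_adapter", "bad_barcode_length",
#'   "unknown_insert") and, when ok, `oligo_id` and `barcode`
#' @export
parse_amplicon <- function(read_sequence, oligo_lookup, adapter = starr_adapter) {
  pos <- regexpr(adapter, read_sequence, fixed = TRUE)
  if (is.na(read_sequence) || pos < 0) return(list(status = "no_adapter"))
  barcode <- substring(read_sequence, pos + nchar(adapter))
  if (nchar(barcode) != 10) return(list(status = "bad_barcode_length"))
  insert <- substring(read_sequence, 1, pos - 1)
  oid <- oligo_lookup[insert]
  if (is.na(oid)) return(list(status = "unknown_insert"))
  list(status = "ok", oligo_id = unname(oid), barcode = barcode)
}

#' Parse a vector of amplicon reads
#'
#' @inheritParams parse_amplicon
#' @param reads character vector of merged amplicon sequences
#' @return list: `parsed` data.frame (oligo_id, barcode) of accepted reads,
#'   `rejected` named counts per rejection reason
#' @export
parse_amplicons <- function(reads, oligo_lookup, adapter = starr_adapter) {
  res <- lapply(reads, parse_amplicon, oligo_lookup = oligo_lookup, adapter = adapter)
  status <- vapply(res, `[[`, character(1), "status")
  ok <- status == "ok"
  parsed <- data.frame(
    oligo_id = vapply(res[ok], `[[`, character(1), "oligo_id"),
    barcode = vapply(res[ok], `[[`, character(1), "barcode"),
    stringsAsFactors = FALSE)
  list(parsed = parsed,
       rejected = table(factor(status[!ok],
                               levels = c("no_adapter", "bad_barcode_length",
                                          "unknown_insert"))))
}

#' Count unique barcodes per oligo
#'
#' PCR duplicates (identical oligo + barcode) count once; the result is
#' invariant to read order.
#'
#' @param parsed data.frame with oligo_id, barcode
#' @param oligo_ids oligo universe (zero-count oligos included in output)
#' @return named integer vector of unique-barcode counts
#' @export
count_unique_barcodes <- function(parsed, oligo_ids) {
  dedup <- unique(parsed[, c("oligo_id", "barcode")])
  tb <- table(factor(dedup$oligo_id, levels = oligo_ids))
  stats::setNames(as.integer(tb), oligo_ids)
}

#' QC-filter oligos on minimum barcode support
#'
#' An oligo is retained iff its count is >= `min_barcodes` in every sample
#' (input and output replicates alike); a SNP is retained iff both of its
#' allele oligos are retained.
#'
#' @param oc an `oligo_counts` object
#' @param min_barcodes minimum unique barcodes per replicate (default 5)
#' @return list: `object` (filtered `oligo_counts`), `retained_snps`,
#'   `n_snps_total`, `n_snps_retained`, `pct_retained` (one decimal)
#' @export
qc_filter_oligos <- function(oc, min_barcodes = 5) {
  ok_oligo <- apply(oc$counts >= min_barcodes, 1, all)
  ok_by_snp <- tapply(ok_oligo, oc$oligo_info$snp_id, all)
  retained <- names(ok_by_snp)[ok_by_snp]
  keep_rows <- oc$oligo_info$snp_id %in% retained
  filtered <- oligo_counts(oc$counts[keep_rows, , drop = FALSE],
                           oc$oligo_info[keep_rows, , drop = FALSE],
                           oc$sample_info)
  n_total <- length(ok_by_snp)
  list(object = filtered, retained_snps = retained,
       n_snps_total = n_total, n_snps_retained = length(retained),
       pct_retained = round_half_away(100 * length(retained) / n_total, 1))
}

#' Median-of-ratios size-factor normalization
#'
#' Size factor of sample j is the median over oligos of
#' `count_ij / geometric mean_i(counts)`, taken over oligos with nonzero
#' counts in all samples; normalized counts are `count_ij / s_j`.
#'
#' @param counts nonnegative count matrix (oligos x samples)
#' @return list: `normalized` matrix, `size_factors` named vector
#' @export
size_factor_normalize <- function(counts) {
  if (ncol(counts) < 2) stop("need >= 2 samples")
  usable <- rowSums(counts > 0) == ncol(counts)
  if (!any(usable)) stop("no oligo has nonzero counts in all samples")
  lgm <- rowMeans(log(counts[usable, , drop = FALSE]))
  sf <- apply(counts[usable, , drop = FALSE], 2, function(cj) {
    median(exp(log(cj) - lgm))
  })
  list(normalized = sweep(counts, 2, sf, "/"), size_factors = sf)
}

## internal: limma-moderated one-sample t across rows of a log-ratio matrix
.moderated_one_sample_t <- function(lmat) {
  n <- ncol(lmat)
  if (n < 2) stop("need >= 2 replicates")
  df <- n - 1
  m <- rowMeans(lmat)
  s2 <- apply(lmat, 1, stats::var)
  sq <- limma::squeezeVar(s2, df = df)
  se <- sqrt(sq$var.post / n)
  t <- ifelse(se > 0, m / se, ifelse(m == 0, 0, sign(m) * Inf))
  df_total <- df + sq$df.prior
  p <- 2 * pt(-abs(t), df = df_total)
  p[is.na(p)] <- 1
  data.frame(log2fc = m, t = t, p = pmin(1, p))
}

#' Call STARR-seq enhancers against the input library
#'
#' Reference and alternative allele counts are combined per SNP;
#' replicate-wise log2 ratios of normalized output over the mean normalized
#' input are tested against zero with a moderated one-sample t-test
#' (empirical-Bayes variance shrinkage across SNPs), followed by
#' Benjamini-Hochberg adjustment. An enhancer requires
#' `|log2FC| > log2fc_min` (default log2(1.5) = 0.585) and adjusted
#' p < `padj_max`; with `direction = "up"` only output-enriched oligos
#' qualify, and depleted oligos are flagged separately either way.
#'
#' @param oc QC-filtered `oligo_counts`
#' @param condition output condition to test
#' @param log2fc_min log2 fold-change threshold (strict >)
#' @param padj_max adjusted-p threshold (strict <)
#' @param pseudocount added to normalized counts before the log ratio
#' @param direction `"absolute"` (default) or `"up"`
#' @return data.frame: snp_id, is_control, log2fc, p, padj, enhancer, depleted
#' @export
call_enhancers <- function(oc, condition, log2fc_min = log2(1.5),
                           padj_max = 0.05, pseudocount = 1,
                           direction = c("absolute", "up")) {
  direction <- match.arg(direction)
  si <- oc$sample_info
  out_cols <- which(si$class == "output" & si$condition == condition)
  in_cols <- which(si$class == "input")
  if (length(out_cols) < 2) stop("need >= 2 output replicates for condition ", condition)
  ## combine ref+alt counts per SNP
  snp_ids <- unique(oc$oligo_info$snp_id)
  comb <- rowsum(oc$counts, group = oc$oligo_info$snp_id)[snp_ids, , drop = FALSE]
  norm <- size_factor_normalize(comb)$normalized
  input_mean <- rowMeans(norm[, in_cols, drop = FALSE])
  lmat <- log2(sweep(norm[, out_cols, drop = FALSE] + pseudocount, 1,
                     input_mean + pseudocount, "/"))
  fit <- .moderated_one_sample_t(lmat)
  padj <- p.adjust(fit$p, method = "BH")
  is_ctrl <- oc$oligo_info$is_control[match(snp_ids, oc$oligo_info$snp_id)]
  enh <- if (direction == "absolute") abs(fit$log2fc) > log2fc_min else
    fit$log2fc > log2fc_min
  data.frame(snp_id = snp_ids, is_control = is_ctrl, log2fc = fit$log2fc,
             p = fit$p, padj = padj,
             enhancer = enh & padj < padj_max,
             depleted = fit$log2fc < -log2fc_min & padj < padj_max,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Allelic activity: alternative vs reference allele expression
#'
#' Per output replicate of the condition, the log2 ratio of pseudocounted
#' alt to ref counts (size factors cancel within a replicate); the
#' replicate log-ratios are tested against zero with a moderated one-sample
#' t-test (empirical-Bayes variance shrinkage across SNPs) and BH-adjusted
#' across tested SNPs. Swapping the allele labels negates the estimate
#' exactly.
#'
#' @param oc QC-filtered `oligo_counts`
#' @param condition output condition
#' @param pseudocount added to counts before the ratio
#' @return data.frame: snp_id, condition, is_control, log2fc, p, padj
#' @export
allelic_activity <- function(oc, condition, pseudocount = 1) {
  si <- oc$sample_info
  out_cols <- which(si$class == "output" & si$condition == condition)
  if (length(out_cols) < 2) stop("need >= 2 output replicates for condition ", condition)
  info <- oc$oligo_info
  snp_ids <- unique(info$snp_id)
  ref_rows <- match(paste0(snp_ids, "|ref"), info$oligo_id)
  alt_rows <- match(paste0(snp_ids, "|alt"), info$oligo_id)
  if (any(is.na(ref_rows)) || any(is.na(alt_rows))) {
    stop("allele rows must be named '<snp>|ref' and '<snp>|alt'")
  }
  alt <- oc$counts[alt_rows, out_cols, drop = FALSE]
  ref <- oc$counts[ref_rows, out_cols, drop = FALSE]
  lmat <- log2((alt + pseudocount) / (ref + pseudocount))
  fit <- .moderated_one_sample_t(lmat)
  data.frame(snp_id = snp_ids, condition = condition,
             is_control = info$is_control[match(snp_ids, info$snp_id)],
             log2fc = fit$log2fc, p = fit$p,
             padj = p.adjust(fit$p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Empirical percentile threshold from control SNPs
#'
#' The q-th percentile by linear interpolation between order statistics
#' (index `h = q * (n - 1)`, zero-based), applied to the absolute log2 fold
#' changes of control SNPs.
#'
#' @param control_abs_log2fc absolute log2 fold changes of controls
#' @param q percentile (default 0.80)
#' @return threshold value
#' @export
empirical_threshold <- function(control_abs_log2fc, q = 0.80) {
  n <- length(control_abs_log2fc)
  if (n == 0) stop("no control values supplied")
  if (n < 10) warning("fewer than 10 control SNPs; percentile threshold is unstable")
  unname(quantile(control_abs_log2fc, probs = q, type = 7))
}

#' Call functional SNPs
#'
#' Functional iff (1) located in a STARR-seq enhancer, (2) allelic adjusted
#' p < 0.05, and (3) |allelic log2FC| strictly exceeding the control
#' percentile threshold. Control SNPs are never called functional.
#'
#' @param allelic_results output of [allelic_activity()]
#' @param enhancer_snps character vector of enhancer SNP ids
#' @param threshold control-derived effect-size threshold
#' @param padj_max adjusted-p cutoff (strict <)
#' @return the allelic results restricted to test SNPs, with `in_enhancer`
#'   and `functional` columns
#' @export
call_functional_snps <- function(allelic_results, enhancer_snps, threshold,
                                 padj_max = 0.05) {
  res <- allelic_results[!allelic_results$is_control, , drop = FALSE]
  res$in_enhancer <- res$snp_id %in% enhancer_snps
  res$functional <- res$in_enhancer & res$padj < padj_max &
    abs(res$log2fc) > threshold
  rownames(res) <- NULL
  res
}

#' Paired quantiles of absolute log2 fold changes (QQ table)
#'
#' Quantiles of both groups at probabilities `(k - 0.5) / n_points`;
#' identical distributions lie on the diagonal.
#'
#' @param test_values,control_values numeric vectors (nonempty)
#' @param n_points number of quantile points (default 357)
#' @return data.frame: prob, control_quantile, test_quantile
#' @export
qq_abs_log2fc <- function(test_values, control_values, n_points = 357) {
  if (!length(test_values) || !length(control_values)) stop("empty group")
  p <- (seq_len(n_points) - 0.5) / n_points
  data.frame(prob = p,
             control_quantile = unname(quantile(control_values, p, type = 7)),
             test_quantile = unname(quantile(test_values, p, type = 7)))
}
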