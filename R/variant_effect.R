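## Variant-effect statistics on model-predicted ref/alt accessibility
## counts: fold-averaged log2 fold change, one-sided Poisson test,
## Fisher combination across cell types, BH correction, high-effect calls.

#' Fold-averaged log2 fold change of predicted counts
#'
#' Mean over model folds of log2(alt_count / ref_count), per
#' (variant, cell type).
#'
#' @param predictions data.frame: variant, cell_type, fold, ref_count,
#'   alt_count (all counts strictly positive; >= 2 folds)
#' @return data.frame: variant, cell_type, log2fc, ref_mean, alt_mean
#' @export
fold_average_log2fc <- function(predictions) {
  if (any(predictions$ref_count <= 0) || any(predictions$alt_count <= 0)) {
    stop("predicted counts must be strictly positive")
  }
  key <- interaction(predictions$variant, predictions$cell_type, drop = TRUE)
  if (min(table(key)) < 2) stop("need >= 2 folds per (variant, cell type)")
  lfc <- log2(predictions$alt_count / predictions$ref_count)
  agg <- aggregate(cbind(log2fc = lfc, ref_mean = predictions$ref_count,
                         alt_mean = predictions$alt_count),
                   by = list(variant = predictions$variant,
                             cell_type = predictions$cell_type), FUN = mean)
  agg[order(agg$variant, agg$cell_type), , drop = FALSE]
}

#' One-sided Poisson test of an observed count against a rate
#'
#' For X ~ Poisson(ref_rate): upper tail P(X >= alt) when alt >= ref_rate,
#' lower tail P(X <= alt) otherwise, so the tail follows the direction of
#' the observed change. With `method = "integer"` (default) the count is
#' rounded to the nearest integer; `method = "continuous"` evaluates the
#' same tails through the regularized incomplete gamma function at the
#' continuous count.
#'
#' @param alt_count observed (predicted alternative-allele) count, >= 0
#' @param ref_rate Poisson rate (predicted reference-allele count), > 0
#' @param method `"integer"` or `"continuous"`
#' @return p-value(s), vectorized over inputs
#' @export
poisson_one_sided <- function(alt_count, ref_rate, method = c("integer", "continuous")) {
  method <- match.arg(method)
  if (any(ref_rate <= 0)) stop("ref_rate must be > 0")
  if (any(alt_count < 0)) stop("alt_count must be >= 0")
  n <- max(length(alt_count), length(ref_rate))
  alt <- rep_len(alt_count, n); rate <- rep_len(ref_rate, n)
  upper <- alt >= rate
  p <- numeric(n)
  if (method == "integer") {
    a <- round(alt)
    p[upper] <- ppois(a[upper] - 1, rate[upper], lower.tail = FALSE)
    p[!upper] <- ppois(a[!upper], rate[!upper])
  } else {
    ## P(X >= a) = P(Gamma(a) <= rate); P(X <= a) = 1 - P(Gamma(a+1) <= rate)
    p[upper] <- stats::pgamma(rate[upper], shape = pmax(alt[upper], 1e-12))
    p[!upper] <- stats::pgamma(rate[!upper], shape = alt[!upper] + 1,
                               lower.tail = FALSE)
  }
  pmin(1, p)
}

#' Combine p-values with Fisher's method
#'
#' `X2 = -2 * sum(log(p))` referred to a chi-square with `2k` degrees of
#' freedom. Zero p-values are clipped to `floor` with a warning.
#'
#' @param p_values p-values in (0, 1]
#' @param floor clip value for p = 0
#' @return combined p-value
#' @export
fisher_combine <- function(p_values, floor = 1e-300) {
  if (!length(p_values)) stop("no p-values to combine")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0,1]")
  if (any(p_values == 0)) {
    warning("zero p-value(s) clipped to ", floor)
    p_values <- pmax(p_values, floor)
  }
  x2 <- -2 * sum(log(p_values))
  pchisq(x2, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment returned in input order (delegates to
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p_values p-values in [0,1]
#' @return adjusted p-values
#' @export
bh_adjust <- function(p_values) {
  p.adjust(p_values, method = "BH")
}

#' Score variants from per-fold predicted ref/alt counts
#'
#' Per (variant, cell type): fold-averaged log2 fold change and a
#' one-sided Poisson test of the fold-averaged alternative count with rate
#' the fold-averaged reference count. Per variant: Fisher combination of
#' the per-cell-type p-values and BH correction across all scored
#' variants. High effect iff max |log2FC| over cell types > `fc_min` and
#' FDR < `fdr_max` (both strict).
#'
#' @param predictions data.frame: variant, cell_type, fold, ref_count, alt_count
#' @param fc_min log2 fold-change threshold (default 0.25)
#' @param fdr_max FDR threshold (default 0.01)
#' @param method Poisson-tail method, see [poisson_one_sided()]
#' @return list: `per_cell_type` (variant, cell_type, log2fc, p),
#'   `per_variant` (variant, max_abs_log2fc, fisher_p, fdr, high_effect)
#' @export
variant_effect_scores <- function(predictions, fc_min = 0.25, fdr_max = 0.01,
                                  method = "integer") {
  agg <- fold_average_log2fc(predictions)
  agg$p <- poisson_one_sided(agg$alt_mean, agg$ref_mean, method = method)
  variants <- unique(agg$variant)
  fisher_p <- vapply(variants, function(v)
    fisher_combine(agg$p[agg$variant == v]), numeric(1))
  max_lfc <- vapply(variants, function(v)
    max(abs(agg$log2fc[agg$variant == v])), numeric(1))
  fdr <- bh_adjust(fisher_p)
  per_variant <- data.frame(variant = variants, max_abs_log2fc = max_lfc,
                            fisher_p = fisher_p, fdr = fdr,
                            high_effect = max_lfc > fc_min & fdr < fdr_max,
                            stringsAsFactors = FALSE, row.names = NULL)
  list(per_cell_type = agg[, c("variant", "cell_type", "log2fc", "p")],
       per_variant = per_variant)
}

#' Extract the high-effect variant set
#'
#' @param results output of [variant_effect_scores()]
#' @param fc_min,fdr_max strict thresholds (defaults 0.25 and 0.01)
#' @return character vector of high-effect variant ids
#' @export
call_high_effect <- function(results, fc_min = 0.25, fdr_max = 0.01) {
  pv <- results$per_variant
  pv$variant[pv$max_abs_log2fc > fc_min & pv$fdr < fdr_max]
}
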