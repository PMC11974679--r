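## The four enhancer-gene linking strategies: peak-peak co-accessibility,
## peak-gene correlation, HiChIP loop overlap, and Activity-by-Contact, plus
## their cross-strategy summaries and marker-gene enrichment of targets.

.peak_mid <- function(iv) (iv$start + iv$end) / 2

#' Peak-peak co-accessibility links
#'
#' Pearson correlation of pseudo-bulk accessibility profiles for every
#' same-chromosome peak pair whose midpoints are within `window_bp`;
#' retained iff the signed correlation exceeds `cutoff`. Constant profiles
#' cannot be correlated and their pairs are skipped with one warning.
#'
#' @param accessibility_matrix peaks x pseudo-bulk samples matrix (rownames
#'   are peak ids)
#' @param peaks data.frame with peak_id, chrom, start, end for every row of
#'   the matrix
#' @param window_bp maximum midpoint distance between tested peaks
#' @param cutoff signed correlation cutoff (strict >)
#' @return data.frame: peak_a, peak_b, correlation (one row per unordered pair)
#' @export
coaccessibility_links <- function(accessibility_matrix, peaks,
                                  window_bp = 250e3, cutoff = 0.3) {
  if (ncol(accessibility_matrix) < 10) stop("need >= 10 pseudo-bulk samples")
  peaks <- peaks[match(rownames(accessibility_matrix), peaks$peak_id), , drop = FALSE]
  if (any(is.na(peaks$peak_id))) stop("every matrix row needs coordinates in `peaks`")
  sds <- apply(accessibility_matrix, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant peak profile(s) skipped")
  }
  mid <- .peak_mid(peaks)
  out <- list()
  for (chr in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == chr & sds > 0)
    if (length(idx) < 2) next
    idx <- idx[order(mid[idx])]
    cm <- suppressWarnings(cor(t(accessibility_matrix[idx, , drop = FALSE])))
    for (i in seq_along(idx)[-length(idx)]) {
      for (j in (i + 1):length(idx)) {
        if (mid[idx[j]] - mid[idx[i]] > window_bp) break
        if (cm[i, j] > cutoff) {
          out[[length(out) + 1L]] <- data.frame(
            peak_a = peaks$peak_id[idx[i]], peak_b = peaks$peak_id[idx[j]],
            correlation = cm[i, j], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(peak_a = character(), peak_b = character(),
                      correlation = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Peaks co-accessible with gene promoters
#'
#' A peak is linked to a gene iff it has a co-accessibility link to at
#' least one peak overlapping that gene's promoter window (any shared
#' base). Also reports the fraction of peaks with >= 1 co-accessible
#' promoter.
#'
#' @param links output of [coaccessibility_links()]
#' @param peaks peak universe data.frame (peak_id + coordinates)
#' @param promoters promoter windows from [make_promoters()] (with gene_id)
#' @return list: `pairs` (peak_id, gene_id), `fraction_linked`,
#'   `n_peaks_linked`
#' @export
promoter_coaccessible <- function(links, peaks, promoters) {
  ## peaks overlapping each promoter
  pk_in_prom <- list()
  for (g in seq_len(nrow(promoters))) {
    ov <- intervals_overlap_any(peaks, promoters[g, , drop = FALSE])
    pk_in_prom[[promoters$gene_id[g]]] <- peaks$peak_id[ov]
  }
  pairs <- list()
  for (g in names(pk_in_prom)) {
    promo_peaks <- pk_in_prom[[g]]
    if (!length(promo_peaks)) next
    hit_a <- links$peak_a[links$peak_b %in% promo_peaks]
    hit_b <- links$peak_b[links$peak_a %in% promo_peaks]
    linked <- setdiff(unique(c(hit_a, hit_b)), promo_peaks)
    if (length(linked)) {
      pairs[[g]] <- data.frame(peak_id = linked, gene_id = g,
                               stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(peak_id = character(), gene_id = character(), stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  n_linked <- length(unique(pairs$peak_id))
  list(pairs = pairs,
       n_peaks_linked = n_linked,
       fraction_linked = n_linked / nrow(peaks))
}

#' Peak-gene correlation links
#'
#' Pearson correlation of a peak's accessibility with a gene's expression
#' over shared samples, tested for every pair whose peak midpoint lies
#' within `max_dist` of the gene TSS; retained iff the signed correlation
#' exceeds `cutoff`.
#'
#' @param accessibility_matrix peaks x samples
#' @param expression_matrix genes x samples (same sample ids)
#' @param peaks peak universe data.frame
#' @param genes gene-model data.frame
#' @param max_dist maximum midpoint-TSS distance in bp
#' @param cutoff signed correlation cutoff (strict >)
#' @return data.frame: peak_id, gene_id, correlation, distance_to_tss
#' @export
peak_gene_links <- function(accessibility_matrix, expression_matrix, peaks,
                            genes, max_dist = 250e3, cutoff = 0.3) {
  if (!identical(colnames(accessibility_matrix), colnames(expression_matrix))) {
    stop("accessibility and expression matrices must share sample ids (same order)")
  }
  peaks <- peaks[match(rownames(accessibility_matrix), peaks$peak_id), , drop = FALSE]
  mid <- .peak_mid(peaks)
  out <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    cand <- which(peaks$chrom == g$chrom & abs(mid - g$tss) <= max_dist)
    if (!length(cand)) next
    expr <- expression_matrix[g$gene_id, ]
    if (stats::sd(expr) == 0) next
    for (i in cand) {
      acc <- accessibility_matrix[i, ]
      if (stats::sd(acc) == 0) next
      r <- cor(acc, expr)
      if (r > cutoff) {
        out[[length(out) + 1L]] <- data.frame(
          peak_id = peaks$peak_id[i], gene_id = g$gene_id, correlation = r,
          distance_to_tss = abs(mid[i] - g$tss), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(peak_id = character(), gene_id = character(),
                      correlation = numeric(), distance_to_tss = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Loop overlap: link targets to genes through loop anchors
#'
#' A target is loop-linked to a gene iff the target overlaps one anchor and
#' the gene's promoter overlaps the *other* anchor of the same loop (anchor
#' overlap = any shared base; a target and promoter inside the same single
#' anchor are not linked). Point targets (variants) are treated as 1-bp
#' intervals. When `peaks` is supplied, also reports the fraction of loops
#' with >= 1 anchor overlapping a peak.
#'
#' @param loops loop-set data.frame
#' @param targets data.frame with target_id and either (chrom, start, end)
#'   or (chrom, pos)
#' @param promoters promoter windows with gene_id
#' @param peaks optional peak intervals for the anchor-overlap fraction
#' @return list: `links` (target_id, gene_id, loop), `fraction_anchor_in_peak`
#' @export
loop_overlap <- function(loops, targets, promoters, peaks = NULL) {
  if (!"start" %in% names(targets)) {
    targets <- data.frame(target_id = targets$target_id, chrom = targets$chrom,
                          start = targets$pos, end = targets$pos + 1,
                          stringsAsFactors = FALSE)
  }
  an1 <- data.frame(chrom = loops$anchor1_chrom, start = loops$anchor1_start,
                    end = loops$anchor1_end, stringsAsFactors = FALSE)
  an2 <- data.frame(chrom = loops$anchor2_chrom, start = loops$anchor2_start,
                    end = loops$anchor2_end, stringsAsFactors = FALSE)
  hits <- function(q, anchors) {
    ## list over rows of q: indices of anchors overlapped
    lapply(seq_len(nrow(q)), function(i) {
      which(anchors$chrom == q$chrom[i] &
              anchors$start < q$end[i] & q$start[i] < anchors$end)
    })
  }
  t1 <- hits(targets, an1); t2 <- hits(targets, an2)
  p1 <- hits(promoters, an1); p2 <- hits(promoters, an2)
  prom_in_1 <- lapply(seq_len(nrow(loops)), function(l)
    promoters$gene_id[vapply(p1, function(h) l %in% h, logical(1))])
  prom_in_2 <- lapply(seq_len(nrow(loops)), function(l)
    promoters$gene_id[vapply(p2, function(h) l %in% h, logical(1))])
  out <- list()
  for (i in seq_len(nrow(targets))) {
    genes <- character(0); loop_idx <- integer(0)
    for (l in t1[[i]]) {
      g <- prom_in_2[[l]]
      genes <- c(genes, g); loop_idx <- c(loop_idx, rep(l, length(g)))
    }
    for (l in t2[[i]]) {
      g <- prom_in_1[[l]]
      genes <- c(genes, g); loop_idx <- c(loop_idx, rep(l, length(g)))
    }
    if (length(genes)) {
      out[[length(out) + 1L]] <- data.frame(
        target_id = targets$target_id[i], gene_id = genes, loop = loop_idx,
        stringsAsFactors = FALSE)
    }
  }
  links <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(target_id = character(), gene_id = character(), loop = integer(),
               stringsAsFactors = FALSE)
  rownames(links) <- NULL
  frac <- NA_real_
  if (!is.null(peaks) && nrow(loops) > 0) {
    o1 <- intervals_overlap_any(an1, peaks)
    o2 <- intervals_overlap_any(an2, peaks)
    frac <- mean(o1 | o2)
  }
  list(links = links, fraction_anchor_in_peak = frac)
}

## internal: contact between two positions on a chromosome, with power-law
## fallback for bins outside the stored map
.contact_lookup <- function(cm, chrom, pos1, pos2) {
  m <- cm$maps[[chrom]]
  if (is.null(m)) return(0)
  res <- cm$resolution_bp
  b1 <- floor(pos1 / res) + 1L
  b2 <- floor(pos2 / res) + 1L
  nb <- nrow(m)
  if (b1 <= nb && b2 <= nb) return(m[b1, b2])
  ## fallback: expected contact at this bin distance from a power-law fit
  d <- abs(b1 - b2)
  if (d == 0) return(max(diag(m)))
  dd <- seq_len(min(30L, nb - 1L))
  md <- vapply(dd, function(k) mean(m[cbind(seq_len(nb - k), seq_len(nb - k) + k)]), numeric(1))
  ok <- md > 0
  if (sum(ok) < 2) return(0)
  fit <- stats::lm(log(md[ok]) ~ log(dd[ok]))
  exp(sum(coef(fit) * c(1, log(d))))
}

#' Activity-by-Contact enhancer-gene scores
#'
#' Activity of an element is the geometric mean of its ATAC and H3K27ac
#' signals; contact is the (binned) contact-map entry between the element's
#' midpoint bin and the gene's TSS bin (same-bin pairs use the diagonal).
#' The ABC score of element e for gene g is `A_e C_eg / sum_e' A_e' C_e'g`
#' over the gene's candidate elements (same chromosome, within
#' `candidate_window` of the TSS). Connections are reported iff the score
#' strictly exceeds `score_min` and the element midpoint is at least
#' `min_tss_dist` from the TSS.
#'
#' @param elements data.frame with element_id, chrom, start, end
#' @param atac_signal,h3k27ac_signal named nonnegative vectors over element_id
#' @param contact_map a `contact_map`
#' @param genes gene-model data.frame
#' @param score_min reporting threshold on the ABC score (strict >)
#' @param min_tss_dist minimum element-TSS distance in bp
#' @param candidate_window window defining each gene's candidate set
#' @return list: `connections` (thresholded) and `all_scores` (per-gene
#'   unthresholded scores, which sum to 1 per gene)
#' @export
abc_scores <- function(elements, atac_signal, h3k27ac_signal, contact_map,
                       genes, score_min = 0.025, min_tss_dist = 500,
                       candidate_window = 5e6) {
  if (any(atac_signal < 0) || any(h3k27ac_signal < 0)) stop("signals must be nonnegative")
  act <- sqrt(atac_signal[elements$element_id] * h3k27ac_signal[elements$element_id])
  mid <- .peak_mid(elements)
  all_rows <- list(); conn_rows <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    cand <- which(elements$chrom == g$chrom & abs(mid - g$tss) <= candidate_window)
    if (!length(cand)) next
    contact <- vapply(cand, function(i)
      .contact_lookup(contact_map, g$chrom, mid[i], g$tss), numeric(1))
    ac <- act[cand] * contact
    denom <- sum(ac)
    if (denom <= 0) {
      warning("gene skipped (no candidate with positive activity x contact): ", g$gene_id)
      next
    }
    sc <- ac / denom
    dist <- abs(mid[cand] - g$tss)
    rows <- data.frame(element_id = elements$element_id[cand], gene_id = g$gene_id,
                       activity = unname(act[cand]), contact = contact,
                       abc_score = unname(sc), distance_to_tss = dist,
                       stringsAsFactors = FALSE)
    all_rows[[length(all_rows) + 1L]] <- rows
    keep <- rows$abc_score > score_min & rows$distance_to_tss >= min_tss_dist
    if (any(keep)) conn_rows[[length(conn_rows) + 1L]] <- rows[keep, , drop = FALSE]
  }
  empty <- data.frame(element_id = character(), gene_id = character(),
                      activity = numeric(), contact = numeric(),
                      abc_score = numeric(), distance_to_tss = numeric(),
                      stringsAsFactors = FALSE)
  all_scores <- if (length(all_rows)) do.call(rbind, all_rows) else empty
  connections <- if (length(conn_rows)) do.call(rbind, conn_rows) else empty
  rownames(all_scores) <- rownames(connections) <- NULL
  list(connections = connections, all_scores = all_scores)
}

#' Cross-strategy link summaries
#'
#' For each linking strategy: number of links, the enhancers-per-gene
#' distribution with its median, the element-TSS distance distribution with
#' its median (when distances are available), and pairwise overlap between
#' strategies computed on (element, gene) pair keys with the smaller set as
#' denominator.
#'
#' @param link_collections named list of data.frames; each needs an element
#'   column (`peak_id`, `element_id` or `target_id`), `gene_id`, and
#'   optionally `distance_to_tss`
#' @return list with `per_strategy` data.frame and `pairwise_overlap` matrix
#' @export
connection_summaries <- function(link_collections) {
  if (!length(link_collections)) stop("supply >= 1 strategy's links")
  elem_col <- function(d) {
    for (cn in c("peak_id", "element_id", "target_id")) if (cn %in% names(d)) return(d[[cn]])
    stop("link table lacks an element column")
  }
  keys <- lapply(link_collections, function(d) unique(paste(elem_col(d), d$gene_id, sep = "->")))
  per <- lapply(names(link_collections), function(nm) {
    d <- link_collections[[nm]]
    epg <- if (nrow(d)) as.numeric(table(d$gene_id)) else numeric(0)
    data.frame(strategy = nm, n_links = length(keys[[nm]]),
               n_genes = length(unique(d$gene_id)),
               median_enhancers_per_gene = if (length(epg)) median(epg) else NA_real_,
               median_distance_to_tss = if ("distance_to_tss" %in% names(d) && nrow(d))
                 median(d$distance_to_tss) else NA_real_,
               stringsAsFactors = FALSE)
  })
  n <- length(keys)
  ov <- matrix(NA_real_, n, n, dimnames = list(names(keys), names(keys)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    denom <- min(length(keys[[i]]), length(keys[[j]]))
    ov[i, j] <- if (denom == 0) NA_real_ else
      length(intersect(keys[[i]], keys[[j]])) / denom
  }
  list(per_strategy = do.call(rbind, per), pairwise_overlap = ov)
}

#' Marker-gene enrichment among enhancer target genes
#'
#' For each tissue's marker-gene set, draws `n_sample` markers without
#' replacement (or the whole set if smaller), computes the fraction present
#' among the enhancer target genes, averages over `n_draws` draws, and
#' normalizes to the mean fraction over baseline tissues.
#'
#' @param target_genes character vector of enhancer target genes
#' @param marker_gene_sets named list of marker-gene character vectors
#' @param baseline_tissues names into `marker_gene_sets` used as baseline
#' @param n_sample markers sampled per draw (default 457)
#' @param n_draws number of random draws
#' @param seed RNG seed
#' @return data.frame: tissue, fraction, normalized_enrichment, is_baseline
#' @export
marker_gene_enrichment <- function(target_genes, marker_gene_sets,
                                   baseline_tissues, n_sample = 457,
                                   n_draws = 100, seed = 1) {
  if (!length(target_genes)) warning("empty target gene set; fractions are 0")
  set.seed(seed)
  frac <- vapply(names(marker_gene_sets), function(ts) {
    mg <- marker_gene_sets[[ts]]
    k <- min(n_sample, length(mg))
    mean(vapply(seq_len(n_draws), function(d) {
      s <- sample(mg, k)
      mean(s %in% target_genes)
    }, numeric(1)))
  }, numeric(1))
  base_mean <- mean(frac[baseline_tissues])
  data.frame(tissue = names(frac), fraction = unname(frac),
             normalized_enrichment = if (base_mean > 0) unname(frac) / base_mean else NA_real_,
             is_baseline = names(frac) %in% baseline_tissues,
             stringsAsFactors = FALSE)
}
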