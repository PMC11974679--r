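# Brute-force oracles, independent of the package's implementation paths.

# bitmap oracle: unique bases covered by intervals (small coordinate spans)
oracle_unique_bases <- function(iv) {
  total <- 0
  for (chr in unique(iv$chrom)) {
    d <- iv[iv$chrom == chr, ]
    mask <- logical(max(d$end))
    for (i in seq_len(nrow(d))) mask[(d$start[i] + 1):d$end[i]] <- TRUE
    total <- total + sum(mask)
  }
  total
}

# double-loop oracle: is point (chrom, pos) inside any half-open interval?
oracle_point_in <- function(chrom, pos, iv) {
  vapply(seq_along(pos), function(k) {
    any(iv$chrom == chrom[k] & iv$start <= pos[k] & pos[k] < iv$end)
  }, logical(1))
}

# all-pairs R^2 scan for LD expansion
oracle_ld_expand <- function(index_ids, geno, thr) {
  keep <- character(0); best <- list()
  for (v in rownames(geno)) {
    if (sd(geno[v, ]) == 0) next
    r2s <- vapply(index_ids, function(iv) {
      if (sd(geno[iv, ]) == 0) return(NA_real_)
      cor(geno[v, ], geno[iv, ])^2
    }, numeric(1))
    if (all(is.na(r2s))) next
    b <- which.max(r2s)
    if (r2s[b] > thr) {
      keep <- c(keep, v)
      best[[v]] <- c(r2 = unname(r2s[b]), idx = names(r2s)[b])
    }
  }
  list(keep = union(keep, index_ids), best = best)
}

# BH step-up from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  run <- sorted * m / seq_len(m)
  adj_sorted <- rev(cummin(rev(run)))
  adj[o] <- pmin(1, adj_sorted)
  adj
}

# Poisson tails by direct pmf summation (log-space pmf to avoid overflow)
oracle_pois_pmf <- function(k, rate) exp(-rate + k * log(rate) - lgamma(k + 1))
oracle_pois_upper <- function(a, rate) {
  if (a <= 0) return(1)
  # sum the upper tail directly (avoids cancellation for tiny tails);
  # truncate once terms are negligible
  kmax <- ceiling(a + 20 * sqrt(rate) + 20 * max(rate, 1))
  min(1, sum(oracle_pois_pmf(a:kmax, rate)))
}
oracle_pois_lower <- function(a, rate) {
  sum(oracle_pois_pmf(0:a, rate))
}

# brute-force ABC scores: full double loop over elements x genes
oracle_abc <- function(elements, act, contact_fn, genes, window) {
  res <- list()
  mid <- (elements$start + elements$end) / 2
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    cand <- which(elements$chrom == g$chrom & abs(mid - g$tss) <= window)
    if (!length(cand)) next
    ac <- vapply(cand, function(i) act[elements$element_id[i]] *
                   contact_fn(g$chrom, mid[i], g$tss), numeric(1))
    if (sum(ac) <= 0) next
    res[[g$gene_id]] <- data.frame(element_id = elements$element_id[cand],
                                   gene_id = g$gene_id, score = ac / sum(ac))
  }
  do.call(rbind, res)
}

# brute-force loop-link scan
oracle_loop_links <- function(loops, targets, promoters) {
  ov <- function(c1, s1, e1, c2, s2, e2) c1 == c2 && s1 < e2 && s2 < e1
  out <- list()
  for (i in seq_len(nrow(targets))) {
    for (l in seq_len(nrow(loops))) {
      t_in_1 <- ov(targets$chrom[i], targets$pos[i], targets$pos[i] + 1,
                   loops$anchor1_chrom[l], loops$anchor1_start[l], loops$anchor1_end[l])
      t_in_2 <- ov(targets$chrom[i], targets$pos[i], targets$pos[i] + 1,
                   loops$anchor2_chrom[l], loops$anchor2_start[l], loops$anchor2_end[l])
      for (p in seq_len(nrow(promoters))) {
        p_in_1 <- ov(promoters$chrom[p], promoters$start[p], promoters$end[p],
                     loops$anchor1_chrom[l], loops$anchor1_start[l], loops$anchor1_end[l])
        p_in_2 <- ov(promoters$chrom[p], promoters$start[p], promoters$end[p],
                     loops$anchor2_chrom[l], loops$anchor2_start[l], loops$anchor2_end[l])
        if ((t_in_1 && p_in_2) || (t_in_2 && p_in_1)) {
          out[[length(out) + 1]] <- data.frame(
            target_id = targets$target_id[i], gene_id = promoters$gene_id[p])
        }
      }
    }
  }
  if (!length(out)) return(data.frame(target_id = character(), gene_id = character()))
  unique(do.call(rbind, out))
}

# median-of-ratios size factors from the definition
oracle_size_factors <- function(counts) {
  ok <- apply(counts > 0, 1, all)
  gm <- exp(rowMeans(log(counts[ok, , drop = FALSE])))
  apply(counts[ok, , drop = FALSE], 2, function(cj) median(cj / gm))
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), span = 1e4, width = 50) {
  start <- sample.int(span - width, n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE), start,
                    start + sample.int(width, n, replace = TRUE))
}
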