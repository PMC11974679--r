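#' @importFrom stats cor median quantile rnorm rpois rnbinom rbinom runif
#'   setNames p.adjust ppois pchisq pt sd var wilcox.test aggregate coef lm
#'   pgamma
#' @importFrom utils read.table write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves moving away from zero, the
#' convention used for all printed percentages in this package (base R's
#' `round()` rounds halves to even).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Construct a table of genomic intervals
#'
#' Intervals are 0-based half-open `[start, end)` everywhere in this package;
#' readers for 1-based formats convert at the boundary.
#'
#' @param chrom chromosome names (non-empty strings)
#' @param start 0-based inclusive start positions
#' @param end 0-based exclusive end positions (must exceed `start`)
#' @param strand strand, one of `"+"`, `"-"`, `"."`
#' @return a `data.frame` with columns chrom, start, end, strand
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  if ((length(start) != n && length(start) != 1) ||
      (length(end) != n && length(end) != 1) ||
      (length(chrom) != n && length(chrom) != 1)) {
    stop("chrom, start, end must have equal length (scalars recycle)")
  }
  chrom <- rep_len(chrom, n)
  start <- rep_len(start, n)
  end <- rep_len(end, n)
  strand <- rep_len(as.character(strand), n)
  if (n > 0) {
    if (any(is.na(start)) || any(is.na(end))) stop("interval coordinates must be non-missing")
    if (any(!nzchar(chrom))) stop("chrom names must be non-empty")
    if (any(start < 0)) stop("interval start must be >= 0")
    if (any(end <= start)) stop("interval end must exceed start (half-open, zero-length forbidden)")
    if (!all(strand %in% c("+", "-", "."))) stop("strand must be one of '+', '-', '.'")
  }
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Construct a peak set
#'
#' A named collection of accessibility peaks for one cell type or tissue.
#' Intervals are sorted by (chrom, start).
#'
#' @param intervals a data.frame from [genomic_intervals()]
#' @param label cell type / tissue name
#' @return an object of class `peak_set`: the sorted interval data.frame with
#'   a `label` attribute
#' @export
peak_set <- function(intervals, label = "peaks") {
  iv <- genomic_intervals(intervals$chrom, intervals$start, intervals$end,
                          intervals$strand %||% ".")
  iv <- iv[order(iv$chrom, iv$start, iv$end), , drop = FALSE]
  rownames(iv) <- NULL
  attr(iv, "label") <- label
  class(iv) <- c("peak_set", "data.frame")
  iv
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set '%s': %d intervals on %d chromosome(s)\n",
              attr(x, "label"), nrow(x), length(unique(x$chrom))))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

peak_label <- function(ps) attr(ps, "label") %||% "peaks"

## internal: intervals -> IRanges, per chromosome (1-based closed for IRanges)
.split_iranges <- function(iv) {
  lapply(split(iv, iv$chrom), function(d) {
    IRanges::IRanges(start = d$start + 1L, end = d$end, names = rownames(d))
  })
}

#' Test whether points fall inside any interval (half-open)
#'
#' Position `p` is inside `[s, e)` iff `s <= p < e`.
#'
#' @param chrom,pos point coordinates (0-based)
#' @param intervals interval data.frame
#' @return logical vector, one per point
#' @export
points_in_intervals <- function(chrom, pos, intervals) {
  n <- length(pos)
  hit <- logical(n)
  if (n == 0 || nrow(intervals) == 0) return(hit)
  by_chr <- split(seq_len(n), chrom)
  ir_by_chr <- .split_iranges(intervals)
  for (chr in names(by_chr)) {
    ir <- ir_by_chr[[chr]]
    if (is.null(ir)) next
    idx <- by_chr[[chr]]
    q <- IRanges::IRanges(start = pos[idx] + 1L, width = 1L)
    hit[idx] <- IRanges::overlapsAny(q, ir)
  }
  hit
}

## internal: for each point, row indices of containing intervals
.containing_rows <- function(chrom, pos, intervals) {
  out <- vector("list", length(pos))
  if (length(pos) == 0 || nrow(intervals) == 0) return(out)
  by_chr <- split(seq_along(pos), chrom)
  for (chr in names(by_chr)) {
    rows <- which(intervals$chrom == chr)
    if (!length(rows)) next
    ir <- IRanges::IRanges(start = intervals$start[rows] + 1L, end = intervals$end[rows])
    idx <- by_chr[[chr]]
    q <- IRanges::IRanges(start = pos[idx] + 1L, width = 1L)
    ov <- IRanges::findOverlaps(q, ir)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    for (k in seq_along(qh)) {
      i <- idx[qh[k]]
      out[[i]] <- c(out[[i]], rows[sh[k]])
    }
  }
  out
}

#' Merge a peak set into disjoint intervals and count unique bases
#'
#' Overlapping intervals are merged; the unique-base total is the summed
#' width of the merged set. Used as the denominator of variant-enrichment
#' rates.
#'
#' @param peakset interval data.frame (e.g. a [peak_set()])
#' @return list with `merged` (interval data.frame) and `unique_bases`
#' @export
merge_unique_bases <- function(peakset) {
  if (nrow(peakset) == 0) {
    return(list(merged = genomic_intervals(character(), numeric(), numeric()),
                unique_bases = 0))
  }
  pieces <- lapply(split(peakset, peakset$chrom), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    data.frame(chrom = d$chrom[1],
               start = IRanges::start(r) - 1,
               end = IRanges::end(r),
               strand = ".",
               stringsAsFactors = FALSE)
  })
  merged <- do.call(rbind, pieces)
  merged <- merged[order(merged$chrom, merged$start), , drop = FALSE]
  rownames(merged) <- NULL
  list(merged = merged, unique_bases = sum(merged$end - merged$start))
}

#' Test interval-interval overlap (any shared base)
#'
#' @param a,b interval data.frames; returns for each row of `a` whether it
#'   shares at least one base with any row of `b`
#' @return logical vector of length `nrow(a)`
#' @export
intervals_overlap_any <- function(a, b) {
  hit <- logical(nrow(a))
  if (nrow(a) == 0 || nrow(b) == 0) return(hit)
  for (chr in unique(a$chrom)) {
    ai <- which(a$chrom == chr)
    bi <- which(b$chrom == chr)
    if (!length(bi)) next
    qa <- IRanges::IRanges(start = a$start[ai] + 1L, end = a$end[ai])
    qb <- IRanges::IRanges(start = b$start[bi] + 1L, end = b$end[bi])
    hit[ai] <- IRanges::overlapsAny(qa, qb)
  }
  hit
}

#' Gene models
#'
#' @param gene_id gene identifiers
#' @param chrom chromosome names
#' @param tss 0-based TSS positions
#' @param strand `"+"` or `"-"` (promoter windows and the ABC distance rule
#'   are strand-aware)
#' @return data.frame with one row per gene
#' @export
gene_models <- function(gene_id, chrom, tss, strand) {
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (any(tss < 0)) stop("tss must be >= 0")
  data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
             tss = as.numeric(tss), strand = strand, stringsAsFactors = FALSE)
}

#' Loop set
#'
#' Chromatin loops with two anchors; anchors are stored canonically with
#' anchor1 ordered before anchor2 by (chrom, start).
#'
#' @param a1,a2 interval data.frames of equal row count (anchor pairs)
#' @param score optional numeric loop scores
#' @return data.frame with anchor1_*/anchor2_* columns and score
#' @export
loop_set <- function(a1, a2, score = NA_real_) {
  stopifnot(nrow(a1) == nrow(a2))
  n <- nrow(a1)
  score <- rep_len(score, n)
  swap <- (a2$chrom < a1$chrom) | (a2$chrom == a1$chrom & a2$start < a1$start)
  if (any(swap)) {
    tmp <- a1[swap, , drop = FALSE]
    a1[swap, ] <- a2[swap, , drop = FALSE]
    a2[swap, ] <- tmp
  }
  out <- data.frame(
    anchor1_chrom = a1$chrom, anchor1_start = a1$start, anchor1_end = a1$end,
    anchor2_chrom = a2$chrom, anchor2_start = a2$start, anchor2_end = a2$end,
    score = score, stringsAsFactors = FALSE)
  key <- paste(out$anchor1_chrom, out$anchor1_start, out$anchor1_end,
               out$anchor2_chrom, out$anchor2_start, out$anchor2_end)
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
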