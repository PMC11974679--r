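## Readers/writers for the plain-text formats every stage touches.
## All coordinates are 0-based half-open internally; BED/BEDPE already use
## that convention, variant tables carry 0-based positions by contract.

.stop_parse <- function(path, lineno, msg) {
  stop(sprintf("%s: line %d: %s", path, lineno, msg), call. = FALSE)
}

.is_skippable <- function(line) {
  grepl("^(#|track\\b|browser\\b)", line) || !nzchar(trimws(line))
}

#' Read a BED file into a peak set
#'
#' Accepts >= 3 tab-separated columns; track/comment/empty lines are skipped.
#' Coordinates are taken as 0-based half-open (BED convention).
#'
#' @param path file path
#' @param label peak-set label (defaults to the file name)
#' @return a [peak_set()]
#' @export
read_bed <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !vapply(lines, .is_skippable, logical(1))
  chrom <- character(); start <- numeric(); end <- numeric(); strand <- character()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) .stop_parse(path, i, "expected >= 3 tab-separated columns")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s != floor(s) || e != floor(e)) {
      .stop_parse(path, i, "non-integer coordinates")
    }
    if (e <= s) .stop_parse(path, i, sprintf("end (%s) <= start (%s)", f[3], f[2]))
    chrom <- c(chrom, f[1]); start <- c(start, s); end <- c(end, e)
    strand <- c(strand, if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else ".")
  }
  peak_set(genomic_intervals(chrom, start, end, strand), label = label)
}

#' Write intervals as BED
#'
#' @param intervals interval data.frame
#' @param path output path
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(intervals$chrom, format(intervals$start, scientific = FALSE, trim = TRUE),
                   format(intervals$end, scientific = FALSE, trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE file into a loop set
#'
#' Requires >= 6 columns; column 7 is taken as a name (ignored), column 8 as
#' a numeric score when present. Anchors are ordered canonically and
#' duplicate loops removed.
#'
#' @param path file path
#' @return a [loop_set()] data.frame
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- which(!vapply(lines, .is_skippable, logical(1)))
  rows <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6) .stop_parse(path, i, "expected >= 6 tab-separated columns")
    co <- suppressWarnings(as.numeric(f[c(2, 3, 5, 6)]))
    if (any(is.na(co)) || any(co != floor(co))) .stop_parse(path, i, "non-integer anchor coordinates")
    if (co[2] <= co[1] || co[4] <= co[3]) .stop_parse(path, i, "anchor end <= start")
    rows[[k]] <- data.frame(
      c1 = f[1], s1 = co[1], e1 = co[2], c2 = f[4], s2 = co[3], e2 = co[4],
      score = if (length(f) >= 8) suppressWarnings(as.numeric(f[8])) else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(loop_set(genomic_intervals(character(), numeric(), numeric()),
                                     genomic_intervals(character(), numeric(), numeric())))
  d <- do.call(rbind, rows)
  loop_set(genomic_intervals(d$c1, d$s1, d$e1),
           genomic_intervals(d$c2, d$s2, d$e2), score = d$score)
}

#' Write a loop set as BEDPE
#' @param loops loop-set data.frame
#' @param path output path
#' @export
write_bedpe <- function(loops, path) {
  df <- loops[, c("anchor1_chrom", "anchor1_start", "anchor1_end",
                  "anchor2_chrom", "anchor2_start", "anchor2_end")]
  df$name <- "."
  df$score <- ifelse(is.na(loops$score), ".", as.character(loops$score))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.consequence_vocab <- c("protein_altering", "synonymous", "noncoding")

#' Read a variant table
#'
#' Tab-separated with header. Required columns: rsid, chrom, pos (0-based),
#' ref_allele, alt_allele, consequence. Optional: locus_id, is_index,
#' am_score, r2_to_index. `consequence` must already be one of the
#' controlled classes (use [classify_consequence()] to map raw annotation
#' labels first).
#'
#' @param path file path
#' @return data.frame of variant records
#' @export
read_variant_table <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                  colClasses = NA, check.names = FALSE)
  req <- c("rsid", "chrom", "pos", "ref_allele", "alt_allele", "consequence")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("variant table missing required column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(d$consequence), .consequence_vocab)
  if (length(bad)) {
    stop("unknown consequence value(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(.consequence_vocab, collapse = ", "))
  }
  if (any(d$ref_allele == d$alt_allele)) stop("ref_allele must differ from alt_allele")
  for (opt in c("locus_id", "is_index", "am_score", "r2_to_index")) {
    if (!opt %in% names(d)) d[[opt]] <- NA
  }
  d$is_index <- as.logical(d$is_index)
  d$is_index[is.na(d$is_index)] <- FALSE
  ok <- is.na(d$r2_to_index) | (d$r2_to_index >= 0 & d$r2_to_index <= 1)
  if (!all(ok)) stop("r2_to_index must lie in [0,1]; offending rsid(s): ",
                     paste(d$rsid[!ok], collapse = ", "))
  ok <- is.na(d$am_score) | (d$am_score >= 0 & d$am_score <= 1)
  if (!all(ok)) stop("am_score must lie in [0,1]")
  d
}

#' Write a variant table
#' @param variants variant data.frame
#' @param path output path
#' @export
write_variant_table <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-model table
#'
#' Tab-separated with header; columns gene_id, chrom, tss (0-based), strand.
#'
#' @param path file path
#' @return gene-model data.frame
#' @export
read_gene_models <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  gene_models(d$gene_id, d$chrom, d$tss, d$strand)
}

#' Read a labelled numeric matrix (features x samples)
#'
#' Whitespace-delimited with row and column labels, as written by
#' [write_feature_matrix()]. Negative values are rejected.
#'
#' @param path file path
#' @param kind `"accessibility"` or `"expression"` (stored as an attribute)
#' @return numeric matrix with dimnames and a `kind` attribute
#' @export
read_feature_matrix <- function(path, kind = c("accessibility", "expression")) {
  kind <- match.arg(kind)
  m <- as.matrix(read.table(path, header = TRUE, row.names = 1, check.names = FALSE))
  if (any(m < 0)) stop("feature matrix contains negative values")
  attr(m, "kind") <- kind
  m
}

#' Write a labelled numeric matrix
#' @param m matrix with dimnames
#' @param path output path
#' @export
write_feature_matrix <- function(m, path) {
  write.table(as.data.frame(m), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a binned contact map
#'
#' Square whitespace-delimited matrix with bin labels `chrom:start` on rows
#' and columns. The matrix is symmetrized by averaging entries (i,j) and
#' (j,i); negative entries are rejected.
#'
#' @param path file path
#' @param resolution_bp bin size in bp
#' @return a `contact_map`: list with `resolution_bp` and per-chromosome
#'   dense matrices under `maps`
#' @export
read_contact_map <- function(path, resolution_bp) {
  m <- as.matrix(read.table(path, header = TRUE, row.names = 1, check.names = FALSE))
  if (nrow(m) != ncol(m)) stop("contact map must be square; got ",
                               nrow(m), " x ", ncol(m))
  if (!identical(rownames(m), colnames(m))) stop("contact map row/column labels differ")
  if (any(m < 0)) stop("contact map contains negative values")
  m <- (m + t(m)) / 2
  contact_map_from_matrix(m, resolution_bp)
}

#' Assemble a contact map from a labelled square matrix
#'
#' @param m symmetric nonnegative matrix; dimnames `chrom:start`
#' @param resolution_bp bin size in bp
#' @return a `contact_map` object
#' @export
contact_map_from_matrix <- function(m, resolution_bp) {
  if (resolution_bp <= 0) stop("resolution_bp must be > 0")
  lab <- strsplit(rownames(m), ":", fixed = TRUE)
  chroms <- vapply(lab, `[`, character(1), 1)
  starts <- as.numeric(vapply(lab, `[`, character(1), 2))
  maps <- list()
  for (chr in unique(chroms)) {
    idx <- which(chroms == chr)
    idx <- idx[order(starts[idx])]
    maps[[chr]] <- m[idx, idx, drop = FALSE]
  }
  structure(list(resolution_bp = resolution_bp, maps = maps), class = "contact_map")
}

#' Write a contact map
#' @param cm contact_map object
#' @param path output path
#' @export
write_contact_map <- function(cm, path) {
  blocks <- cm$maps
  n <- sum(vapply(blocks, nrow, integer(1)))
  full <- matrix(0, n, n)
  labs <- unlist(lapply(blocks, rownames), use.names = FALSE)
  dimnames(full) <- list(labs, labs)
  off <- 0
  for (b in blocks) {
    i <- off + seq_len(nrow(b))
    full[i, i] <- b
    off <- off + nrow(b)
  }
  write.table(as.data.frame(full), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d chromosome(s) at %g bp resolution\n",
              length(x$maps), x$resolution_bp))
  for (chr in names(x$maps)) cat(sprintf("  %s: %d bins\n", chr, nrow(x$maps[[chr]])))
  invisible(x)
}
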