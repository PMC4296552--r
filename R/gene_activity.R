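# Gene activity from expression counts, and TSS-region occupancy
# similarity between samples.
#
# The activity rule is deliberately blunt: a gene is silent iff its read
# count is zero (in every replicate, when replicates are supplied - any
# nonzero evidence contradicts silence); every other gene is active.

#' Classify genes as active or silent from read counts
#'
#' @param counts data.frame with `gene_id` and one or more numeric count
#'   columns (replicates). Counts must be non-negative integers.
#' @return `data.table` with `gene_id` and `status` ("active"/"silent");
#'   the partition is exhaustive and exclusive.
#' @export
classify_genes <- function(counts) {
  dt <- as.data.table(counts)
  if (nrow(dt) == 0L) stop_nucorg("count table is empty")
  cc <- setdiff(names(dt), "gene_id")
  if (length(cc) == 0L) stop_nucorg("count table has no count columns")
  m <- as.matrix(dt[, cc, with = FALSE])
  if (any(is.na(m))) stop_nucorg("count table contains missing values")
  if (any(m < 0)) stop_nucorg("negative read count")
  if (any(m != floor(m))) stop_nucorg("read counts must be integers")
  data.table(gene_id = dt$gene_id,
             status = ifelse(rowSums(m) == 0, "silent", "active"))
}

#' Reads per kilobase per million mapped reads
#'
#' `count / ((exon_length/1000) * (library_total/1e6))`; zero iff the
#' count is zero, and invariant to jointly scaling count and library size.
#'
#' @param count read count (vectorized).
#' @param exon_length exonic length in bp, > 0.
#' @param library_total total mapped reads in the library, > 0.
#' @return numeric RPKM.
#' @export
rpkm_value <- function(count, exon_length, library_total) {
  if (any(exon_length <= 0)) stop_nucorg("exon_length must be > 0")
  if (any(library_total <= 0)) stop_nucorg("library_total must be > 0")
  count / ((exon_length / 1000) * (library_total / 1e6))
}

#' Spearman correlation of two gene-level RPKM tables
#'
#' Tables are inner-joined on `gene_id`; at least 3 shared genes are
#' required.
#'
#' @param a,b data.frames with `gene_id` and `rpkm`.
#' @return Spearman rho.
#' @export
expression_correlation <- function(a, b) {
  a <- as.data.table(a)[, .(gene_id, rpkm_a = rpkm)]
  b <- as.data.table(b)[, .(gene_id, rpkm_b = rpkm)]
  m <- merge(a, b, by = "gene_id")
  if (nrow(m) < 3L) stop_nucorg("fewer than 3 shared genes between expression tables")
  spearman_rho(m$rpkm_a, m$rpkm_b)
}

# Per-gene strand-oriented window counts of midpoints around the TSS.
# Window j (0-based) covers oriented distances [-flank + j*win, -flank + (j+1)*win).
tss_window_counts <- function(track, genes, flank, window) {
  anchors <- data.table(chrom = genes$chrom, pos = genes$tss, strand = genes$strand)
  pairs <- anchor_midpoint_distances(track, anchors, flank)
  nwin <- 2 * flank / window
  m <- matrix(0, nrow(genes), nwin)
  pairs <- pairs[dist >= -flank & dist < flank]
  if (nrow(pairs) > 0L) {
    j <- floor((pairs$dist + flank) / window) + 1L
    idx <- (pairs$anchor - 1L) * nwin + j
    m <- matrix(tabulate(idx, nbins = nrow(genes) * nwin), ncol = nwin, byrow = TRUE)
  }
  m
}

#' Between-sample correlation of TSS-region nucleosome occupancy
#'
#' For each gene of the subset, `2*flank/window` non-overlapping windows
#' tile `[-flank, +flank)` in strand-oriented coordinates around the TSS.
#' Window occupancy is RPKM-normalized per sample and the correlation is
#' computed across all gene-by-window cells.
#'
#' @param track_a,track_b `midpoint_track` objects.
#' @param genes non-empty gene subset (`chrom`, `tss`, `strand`).
#' @param flank bp on each side of the TSS (default 2000).
#' @param window scan window in bp (default 250); must divide `2*flank`.
#' @param method "pearson" (default) or "spearman".
#' @return correlation coefficient.
#' @export
tss_window_correlation <- function(track_a, track_b, genes, flank = 2000, window = 250,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  genes <- as.data.table(genes)
  if (nrow(genes) == 0L) stop_nucorg("gene subset is empty")
  if ((2 * flank) %% window != 0) stop_nucorg("window must divide 2*flank")
  ca <- tss_window_counts(track_a, genes, flank, window)
  cb <- tss_window_counts(track_b, genes, flank, window)
  norm <- function(m, total) m / ((window / 1000) * (total / 1e6))
  xa <- as.vector(norm(ca, track_a$total_reads))
  xb <- as.vector(norm(cb, track_b$total_reads))
  if (method == "pearson") pearson_r(xa, xb) else spearman_rho(xa, xb)
}

#' Pick one TSS per gene: the most upstream in gene orientation
#'
#' For multi-isoform annotations sharing a `gene_id`, keeps a single
#' deterministic TSS: the smallest for plus-strand genes, the largest for
#' minus-strand genes.
#'
#' @param genes gene table with possibly repeated `gene_id`.
#' @return one row per `gene_id`.
#' @export
collapse_gene_tss <- function(genes) {
  dt <- as.data.table(genes)
  dt[, {
    pick <- if (strand[1] == "+") which.min(tss) else which.max(tss)
    .SD[pick]
  }, by = gene_id]
}
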