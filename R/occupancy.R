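# From reads to nucleosome midpoints and genome-window occupancy.
#
# The dyad (midpoint) of the ~147-bp nucleosomal particle is estimated as
# 73 bp downstream of the read's 5' end, *in read orientation*: a
# plus-strand read at [start, end) gives start + 73, a minus-strand read
# gives (end - 1) - 73. Reading "downstream" in read orientation makes
# both strands estimate the same dyad; a plus-only reading would shear the
# two strands' estimates apart by ~100 bp.

MIDPOINT_OFFSET <- 73

#' Nucleosome midpoint (dyad) position of a read
#'
#' @param start,end 0-based half-open read coordinates (vectorized).
#' @param strand "+" or "-" (vectorized).
#' @param offset bp from the 5' end to the dyad (default 73).
#' @return numeric midpoint positions; may fall outside the chromosome,
#'   which is handled (dropped with a count) at track-build time.
#' @export
read_midpoint <- function(start, end, strand, offset = MIDPOINT_OFFSET) {
  bad <- !(strand %in% c("+", "-"))
  if (any(bad)) stop_nucorg("invalid strand symbol '%s'", strand[which(bad)[1]])
  ifelse(strand == "+", start + offset, (end - 1) - offset)
}

#' Build a per-chromosome sorted midpoint track
#'
#' `total_reads` (the RPKM denominator everywhere downstream) counts every
#' retained uniquely mapped read, including reads whose midpoint falls off
#' the chromosome end and is therefore not stored. Reads on chromosomes
#' absent from `chrom_sizes` are an error, never silently dropped.
#'
#' @param reads table with `chrom`, `start`, `end`, `strand`.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param sample_id label for the sample.
#' @param midpoint_offset bp from 5' end to dyad (default 73).
#' @return object of class `midpoint_track`: list with `sample_id`,
#'   `midpoints` (named list of sorted positions per chromosome),
#'   `total_reads`, `n_dropped`, `chrom_sizes`.
#' @export
build_midpoint_track <- function(reads, chrom_sizes, sample_id = "sample",
                                 midpoint_offset = MIDPOINT_OFFSET) {
  dt <- as.data.table(reads)
  if (nrow(dt) > 0L) check_chroms_known(dt$chrom, chrom_sizes, "read")
  mids <- setNames(vector("list", length(chrom_sizes)), names(chrom_sizes))
  n_dropped <- 0L
  if (nrow(dt) > 0L) {
    dt <- dt[, .(chrom, mid = read_midpoint(start, end, strand, midpoint_offset))]
    for (cn in unique(dt$chrom)) {
      m <- dt$mid[dt$chrom == cn]
      keep <- m >= 0 & m < chrom_sizes[[cn]]
      n_dropped <- n_dropped + sum(!keep)
      mids[[cn]] <- sort(m[keep])
    }
  }
  for (cn in names(mids)) if (is.null(mids[[cn]])) mids[[cn]] <- numeric(0)
  structure(list(sample_id = sample_id, midpoints = mids,
                 total_reads = nrow(dt), n_dropped = n_dropped,
                 chrom_sizes = chrom_sizes),
            class = "midpoint_track")
}

#' @export
print.midpoint_track <- function(x, ...) {
  cat(sprintf("<midpoint_track> %s: %d reads (%d midpoints dropped at edges), %d chromosome(s)\n",
              x$sample_id, x$total_reads, x$n_dropped, length(x$chrom_sizes)))
  invisible(x)
}

window_breaks <- function(chrom_len, window_size, offset) {
  stopifnot(window_size > 0, offset >= 0, offset < window_size)
  inner <- seq(from = offset, to = chrom_len, by = window_size)
  sort(unique(c(0, inner[inner > 0 & inner < chrom_len], chrom_len)))
}

#' Genome-window nucleosome occupancy (RPKM)
#'
#' Tiles every chromosome with `window_size`-bp windows (optionally
#' shifted by `offset`; the first window is then the partial
#' `[0, offset)`), counts nucleosome midpoints per window, and normalizes
#' to RPKM: `count / ((width/1000) * (total_reads/1e6))`. Terminal partial
#' windows are kept and normalized by their true width, so the RPKM
#' definition stays exact at chromosome ends.
#'
#' @param track a `midpoint_track`.
#' @param window_size window width in bp (default 10000).
#' @param offset scan offset in bp, `0 <= offset < window_size`.
#' @return object of class `occupancy_track`: `data.table` with columns
#'   `chrom`, `start`, `end`, `count`, `rpkm`; attributes `sample_id`,
#'   `window_size`, `offset`, `total_reads`.
#' @export
window_occupancy <- function(track, window_size = 10000, offset = 0) {
  stopifnot(inherits(track, "midpoint_track"))
  if (track$total_reads <= 0) stop_nucorg("occupancy normalization undefined: total_reads = 0")
  if (offset < 0 || offset >= window_size) stop_nucorg("offset must satisfy 0 <= offset < window_size")
  res <- vector("list", length(track$chrom_sizes))
  i <- 0L
  for (cn in names(track$chrom_sizes)) {
    i <- i + 1L
    brk <- window_breaks(track$chrom_sizes[[cn]], window_size, offset)
    m <- track$midpoints[[cn]]
    cnt <- if (length(m) == 0L) integer(length(brk) - 1L) else {
      idx <- findInterval(m, brk, rightmost.closed = FALSE, left.open = FALSE)
      tabulate(idx, nbins = length(brk) - 1L)
    }
    res[[i]] <- data.table(chrom = cn, start = brk[-length(brk)], end = brk[-1], count = cnt)
  }
  occ <- rbindlist(res)
  occ[, rpkm := count / (((end - start) / 1000) * (track$total_reads / 1e6))]
  structure(occ[], class = c("occupancy_track", class(occ)),
            sample_id = track$sample_id, window_size = window_size,
            offset = offset, total_reads = track$total_reads)
}

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) stop_nucorg("correlation inputs differ in length (%d vs %d)", length(x), length(y))
  if (length(x) < 3L) stop_nucorg("correlation needs at least 3 paired values")
  if (sd(x) == 0 || sd(y) == 0) stop_nucorg("correlation undefined for constant input")
  invisible(TRUE)
}

#' Spearman rank correlation with guards
#'
#' Average ranks are used for ties (the `stats::cor` convention).
#'
#' @param x,y equal-length numeric vectors, length >= 3, not constant.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  check_cor_input(x, y)
  stats::cor(x, y, method = "spearman")
}

#' Pearson product-moment correlation with guards
#'
#' @param x,y equal-length numeric vectors, length >= 3, not constant.
#' @return r in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  check_cor_input(x, y)
  stats::cor(x, y, method = "pearson")
}

#' Pairwise occupancy correlation matrix across samples
#'
#' All tracks must share window parameters and tiling. Windows on
#' chromosomes missing from any sample are excluded for every pair alike
#' (no zero-imputation, which would inflate correlation).
#'
#' @param tracks list of `occupancy_track` objects.
#' @param method "spearman" or "pearson".
#' @return symmetric labelled matrix with unit diagonal.
#' @export
correlation_matrix <- function(tracks, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(tracks) >= 2L)
  ws <- vapply(tracks, attr, numeric(1), which = "window_size")
  off <- vapply(tracks, attr, numeric(1), which = "offset")
  if (length(unique(ws)) != 1L || length(unique(off)) != 1L) {
    stop_nucorg("occupancy tracks have mismatched window parameters")
  }
  shared <- Reduce(intersect, lapply(tracks, function(t) unique(t$chrom)))
  if (length(shared) == 0L) stop_nucorg("occupancy tracks share no chromosomes")
  keys <- lapply(tracks, function(t) {
    s <- t[t$chrom %in% shared]
    setorder(s, chrom, start)
    s
  })
  ref <- keys[[1]][, .(chrom, start, end)]
  for (k in keys[-1]) {
    if (!identical(ref, k[, .(chrom, start, end)])) stop_nucorg("occupancy tracks have mismatched tilings")
  }
  m <- vapply(keys, function(k) k$rpkm, numeric(nrow(ref)))
  labels <- vapply(tracks, attr, character(1), which = "sample_id")
  colnames(m) <- labels
  out <- stats::cor(m, method = method)
  diag(out) <- 1
  out
}

#' Windows with large between-sample occupancy fold changes
#'
#' Flags windows where the pseudocount-stabilized RPKM ratio exceeds
#' `threshold` in either direction, then merges adjacent flagged windows
#' of a chromosome into regions.
#'
#' @param a,b `occupancy_track` objects on the same tiling.
#' @param threshold fold-change threshold, must be > 1 (default 2).
#' @param pseudocount RPKM pseudocount (default 1) so empty windows never
#'   produce infinite folds.
#' @return list with `windows` (per flagged window: chrom, start, end,
#'   rpkm_a, rpkm_b, fold) and `regions` (merged: chrom, start, end,
#'   n_windows, max_fold).
#' @export
fold_change_regions <- function(a, b, threshold = 2, pseudocount = 1) {
  if (threshold <= 1) stop_nucorg("fold-change threshold must be > 1")
  dt_a <- as.data.table(a)[, .(chrom, start, end, rpkm_a = rpkm)]
  dt_b <- as.data.table(b)[, .(chrom, start, end, rpkm_b = rpkm)]
  if (!identical(dt_a[, .(chrom, start, end)], dt_b[, .(chrom, start, end)])) {
    stop_nucorg("fold change requires a shared window tiling")
  }
  dt <- dt_a
  dt[, rpkm_b := dt_b$rpkm_b]
  dt[, fold := pmax((rpkm_a + pseudocount) / (rpkm_b + pseudocount),
                    (rpkm_b + pseudocount) / (rpkm_a + pseudocount))]
  dt[, flagged := fold > threshold]
  win <- dt[flagged == TRUE, .(chrom, start, end, rpkm_a, rpkm_b, fold)]
  if (nrow(win) == 0L) {
    regions <- data.table(chrom = character(), start = numeric(), end = numeric(),
                          n_windows = integer(), max_fold = numeric())
  } else {
    n <- nrow(dt)
    adjacent <- c(FALSE, dt$chrom[-1] == dt$chrom[-n] & dt$start[-1] == dt$end[-n])
    continues <- adjacent & c(FALSE, dt$flagged[-n])
    dt[, region_id := cumsum(flagged & !continues)]
    regions <- dt[flagged == TRUE,
                  .(start = min(start), end = max(end), n_windows = .N, max_fold = max(fold)),
                  by = .(chrom, region_id)][, .(chrom, start, end, n_windows, max_fold)]
  }
  list(windows = win, regions = regions)
}
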