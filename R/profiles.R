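# Anchor-centered nucleosome distribution profiles.
#
# Signed distance of a midpoint m to an anchor a is (m - a) for plus /
# unstranded anchors and (a - m) for minus anchors, so "downstream" always
# means in anchor orientation. Distances are binned into
# [k*bin, (k+1)*bin) for k = -flank/bin .. flank/bin - 1: no special
# zero-centered bin, 2*flank/bin bins in total.

#' Profile parameters
#'
#' @param flank bp collected on each side of the anchor (default 3000).
#' @param bin_width bin width in bp (default 10); must divide `flank`.
#' @param smooth_bins moving-average width in bins, odd (default 5).
#' @param smooth_step moving-average step in bins (default 1).
#' @return list of validated parameters.
#' @export
profile_params <- function(flank = 3000, bin_width = 10, smooth_bins = 5, smooth_step = 1) {
  if (flank %% bin_width != 0) stop_nucorg("flank must be a multiple of bin_width")
  if (smooth_bins %% 2 != 1 || smooth_bins < 1) stop_nucorg("smooth_bins must be odd and >= 1")
  if (smooth_step < 1) stop_nucorg("smooth_step must be >= 1")
  list(flank = flank, bin_width = bin_width, smooth_bins = smooth_bins, smooth_step = smooth_step)
}

# Gather (anchor, midpoint) pairs within +-flank and return signed
# distances with their anchor index. Shared by profiles and the per-gene
# TSS window scan.
anchor_midpoint_distances <- function(track, anchors, flank) {
  res <- vector("list", nrow(anchors))
  for (cn in unique(anchors$chrom)) {
    m <- track$midpoints[[cn]]
    if (is.null(m)) stop_nucorg("anchor on chromosome '%s' absent from track", cn)
    rows <- which(anchors$chrom == cn)
    if (length(m) == 0L) next
    a <- anchors$pos[rows]
    lo <- findInterval(a - flank - 0.5, m) + 1L
    hi <- findInterval(a + flank + 0.5, m)
    n <- pmax(hi - lo + 1L, 0L)
    keep <- n > 0L
    if (!any(keep)) next
    midx <- sequence(n[keep], from = lo[keep])
    aidx <- rep(rows[keep], n[keep])
    d <- m[midx] - anchors$pos[aidx]
    neg <- anchors$strand[aidx] == "-"
    d[neg] <- -d[neg]
    res[[rows[1]]] <- data.table(anchor = aidx, dist = d)
  }
  out <- rbindlist(res)
  if (nrow(out) == 0L) data.table(anchor = integer(), dist = numeric()) else out
}

# Per anchor, the range of bin indices k whose genomic span lies fully
# inside the chromosome; returns regions_per_bin over all anchors.
regions_per_bin <- function(anchors, chrom_sizes, flank, bin_width) {
  kmin_all <- -flank / bin_width
  kmax_all <- flank / bin_width - 1
  nbins <- kmax_all - kmin_all + 1
  counts <- numeric(nbins)
  L <- chrom_sizes[anchors$chrom]
  a <- anchors$pos
  plus <- anchors$strand != "-"
  # + / unstranded: bin k spans [a + k*b, a + (k+1)*b) => k >= -a/b, k <= (L - a)/b - 1
  # -            : bin k spans [a - (k+1)*b + 1, a - k*b + 1) => k >= (a + 1 - L)/b, k <= (a + 1)/b - 1
  kmin <- ifelse(plus, ceiling(-a / bin_width), ceiling((a + 1 - L) / bin_width))
  kmax <- ifelse(plus, floor((L - a) / bin_width) - 1, floor((a + 1) / bin_width) - 1)
  kmin <- pmax(kmin, kmin_all)
  kmax <- pmin(kmax, kmax_all)
  ok <- kmax >= kmin
  if (any(ok)) {
    i1 <- kmin[ok] - kmin_all + 1
    i2 <- kmax[ok] - kmin_all + 1
    inc <- numeric(nbins + 1)
    for (j in seq_along(i1)) {
      inc[i1[j]] <- inc[i1[j]] + 1
      inc[i2[j] + 1] <- inc[i2[j] + 1] - 1
    }
    counts <- cumsum(inc[seq_len(nbins)])
  }
  counts
}

#' Anchor-centered nucleosome distribution profile
#'
#' Midpoints within `flank` bp of each anchor are binned by signed
#' distance in `bin_width`-bp intervals. Raw bin counts are normalized to
#' the number of regions represented in each bin (anchors whose clipped
#' flanking window genomically covers the bin's span) and to the total
#' number of retained reads per million; bins represented by no region are
#' missing (`NA`), not zero. The normalized profile is then smoothed by a
#' centered moving average.
#'
#' @param track a `midpoint_track`.
#' @param anchors data.frame with `chrom`, `pos` and optionally `strand`
#'   ("+", "-"; anything else is treated as unstranded).
#' @param params result of [profile_params()].
#' @param anchor_set_id label carried on the result.
#' @return object of class `nuc_profile`: `data.table` with `bin_start`
#'   (signed distance of the bin's left edge), `bin_mid`, `raw_count`,
#'   `regions`, `normalized`, `smoothed`; attributes `params`,
#'   `n_anchors`, `total_reads`, `anchor_set_id`.
#' @export
anchored_profile <- function(track, anchors, params = profile_params(), anchor_set_id = "anchors") {
  stopifnot(inherits(track, "midpoint_track"))
  anchors <- as.data.table(anchors)
  if (nrow(anchors) == 0L) stop_nucorg("anchor set is empty")
  if (track$total_reads <= 0) stop_nucorg("profile normalization undefined: total_reads = 0")
  if (!"strand" %in% names(anchors)) anchors[, strand := "*"]
  check_chroms_known(anchors$chrom, track$chrom_sizes, "anchor")
  flank <- params$flank; bw <- params$bin_width
  nbins <- 2 * flank / bw
  bin_start <- seq(-flank, flank - bw, by = bw)

  pairs <- anchor_midpoint_distances(track, anchors, flank)
  pairs <- pairs[dist >= -flank & dist < flank]
  k <- floor(pairs$dist / bw)
  raw <- tabulate(k + flank / bw + 1L, nbins = nbins)

  regions <- regions_per_bin(anchors, track$chrom_sizes, flank, bw)
  normalized <- ifelse(regions > 0, raw / (regions * (track$total_reads / 1e6)), NA_real_)
  smoothed_vals <- smooth_profile(normalized, params$smooth_bins, params$smooth_step)
  smoothed <- rep(NA_real_, nbins)
  smoothed[seq(1, nbins, by = params$smooth_step)] <- smoothed_vals

  out <- data.table(bin_start = bin_start, bin_mid = bin_start + bw / 2,
                    raw_count = raw, regions = regions,
                    normalized = normalized, smoothed = smoothed)
  structure(out[], class = c("nuc_profile", class(out)),
            params = params, n_anchors = nrow(anchors),
            total_reads = track$total_reads, anchor_set_id = anchor_set_id)
}

utils::globalVariables(c("dist", "bin_mid", "raw_count", "regions", "normalized", "smoothed"))

#' @export
print.nuc_profile <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<nuc_profile> %s: %d anchors, flank %d bp, %d-bp bins, smooth %d\n",
              attr(x, "anchor_set_id"), attr(x, "n_anchors"), p$flank, p$bin_width, p$smooth_bins))
  invisible(x)
}

#' Centered moving average with shrink-to-fit edges
#'
#' At the edges of the series the window shrinks symmetrically to what
#' fits, so no values are fabricated beyond the range. Missing (`NA`)
#' entries are excluded from their neighbors' averages; a window with no
#' observed value yields `NA`.
#'
#' @param values numeric vector (may contain `NA`).
#' @param window odd window width in bins.
#' @param step step size in bins; the result has values at indices
#'   `seq(1, length(values), by = step)`.
#' @return numeric vector of length `ceiling(length(values)/step)`.
#' @export
smooth_profile <- function(values, window = 5, step = 1) {
  if (window %% 2 != 1) stop_nucorg("smoothing window must be odd")
  n <- length(values)
  centers <- seq(1, n, by = step)
  half <- (window - 1) / 2
  vapply(centers, function(i) {
    h <- min(half, i - 1, n - i)
    w <- values[(i - h):(i + h)]
    w <- w[!is.na(w)]
    if (length(w) == 0L) NA_real_ else mean(w)
  }, numeric(1))
}

#' Strand-separated read coverage heatmap around TSSs
#'
#' Every read contributes its full footprint `[start, end)` to each
#' overlapped bp-offset column of each gene row within `flank`. Gene
#' strand flips both the offset axis and the sense/antisense layer
#' assignment, so "sense" always means the read maps to the gene's coding
#' strand. Values are scaled per million total reads.
#'
#' @param reads table with `chrom`, `start`, `end`, `strand`.
#' @param genes table with `gene_id`, `chrom`, `strand`, `tss`.
#' @param total_reads RPKM denominator (retained uniquely mapped reads).
#' @param flank bp on each side of the TSS (> 0).
#' @return object of class `tss_heatmap`: list with matrices `sense` and
#'   `antisense` (genes x offsets `-flank..flank`) and `offsets`.
#' @export
tss_heatmap <- function(reads, genes, total_reads, flank = 1000) {
  if (flank <= 0) stop_nucorg("flank must be > 0")
  if (total_reads <= 0) stop_nucorg("total_reads must be > 0")
  reads <- as.data.table(reads)
  genes <- as.data.table(genes)
  offs <- seq(-flank, flank)
  ncol_ <- length(offs)
  sense <- matrix(0, nrow(genes), ncol_, dimnames = list(genes$gene_id, offs))
  anti <- matrix(0, nrow(genes), ncol_, dimnames = list(genes$gene_id, offs))
  scale <- 1 / (total_reads / 1e6)
  setorder(reads, chrom, start)
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi]
    r <- reads[chrom == g$chrom & end > g$tss - flank & start <= g$tss + flank]
    if (nrow(r) == 0L) next
    for (ri in seq_len(nrow(r))) {
      lo <- max(r$start[ri], g$tss - flank)
      hi <- min(r$end[ri] - 1, g$tss + flank)
      if (lo > hi) next
      cols <- if (g$strand == "+") (lo:hi - g$tss) else (g$tss - (lo:hi))
      cols <- cols + flank + 1
      is_sense <- r$strand[ri] == g$strand
      if (is_sense) sense[gi, cols] <- sense[gi, cols] + scale
      else anti[gi, cols] <- anti[gi, cols] + scale
    }
  }
  structure(list(sense = sense, antisense = anti, offsets = offs, flank = flank),
            class = "tss_heatmap")
}

#' @export
print.tss_heatmap <- function(x, ...) {
  cat(sprintf("<tss_heatmap> %d genes x %d offsets (+-%d bp), sense/antisense layers\n",
              nrow(x$sense), length(x$offsets), x$flank))
  invisible(x)
}

#' Summarize nucleosome-depleted-region architecture of a profile
#'
#' Works on the smoothed profile. The NDR center is the center of the
#' near-minimal plateau (bins within 5% of the depth range above the
#' global minimum) inside `+-search` bp of the anchor; reporting the
#' plateau center rather than the raw argmin keeps the estimate stable
#' when the depleted region is flat. The +1/-1 nucleosomes are the nearest
#' local maxima downstream/upstream of the NDR center. Depth is
#' `1 - min / baseline`, with the baseline taken as the mean of the outer
#' third of the profile on both sides. A profile whose anchor-proximal
#' occupancy is above baseline is reported `anchor_occupied` (the
#' single-positioned-nucleosome architecture of silent promoters).
#'
#' @param profile a `nuc_profile` covering at least +-1000 bp.
#' @param search bp around the anchor searched for the NDR (default 300).
#' @return list with `ndr_center`, `ndr_depth`, `plus1_position`,
#'   `minus1_position`, `anchor_occupied`.
#' @export
ndr_summary <- function(profile, search = 300) {
  stopifnot(inherits(profile, "nuc_profile"))
  p <- attr(profile, "params")
  if (p$flank < 1000) stop_nucorg("ndr_summary needs a profile covering at least +-1000 bp")
  x <- profile$smoothed
  mid <- profile$bin_mid
  central <- which(abs(mid) <= search)
  if (any(is.na(x[central]))) stop_nucorg("profile has missing central bins")
  tail_idx <- which(abs(mid) >= p$flank * 2 / 3)
  baseline <- mean(x[tail_idx], na.rm = TRUE)
  if (!is.finite(baseline) || baseline <= 0) stop_nucorg("profile baseline is empty")

  minv <- min(x[central])
  tolv <- minv + 0.05 * max(baseline - minv, 0)
  plateau <- central[x[central] <= tolv]
  runs <- split(plateau, cumsum(c(1, diff(plateau) != 1)))
  run <- runs[[which.max(lengths(runs))]]
  ndr_center <- mean(mid[run])
  ndr_depth <- 1 - minv / baseline

  peaks <- local_maxima(x, halfwidth = 2L)
  if (length(peaks) == 0L) stop_nucorg("no canonical structure: profile has no local maxima")
  down <- peaks[mid[peaks] > ndr_center]
  up <- peaks[mid[peaks] < ndr_center]
  plus1 <- if (length(down)) mid[down[1]] else NA_real_
  minus1 <- if (length(up)) mid[up[length(up)]] else NA_real_
  anchor_bin <- which.min(abs(mid))
  occupied <- x[anchor_bin] > 1.5 * baseline
  list(ndr_center = ndr_center, ndr_depth = ndr_depth,
       plus1_position = plus1, minus1_position = minus1,
       anchor_occupied = occupied)
}
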