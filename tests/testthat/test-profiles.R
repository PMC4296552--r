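test_that("profile parameters are validated", {
  expect_error(profile_params(flank = 3005), "multiple")
  expect_error(profile_params(smooth_bins = 4), "odd")
  expect_error(profile_params(smooth_step = 0), "step")
})

test_that("a single midpoint lands in the hand-computed signed-distance bin", {
  tr <- track_from_midpoints(5005, len = 20000)
  prof <- anchored_profile(tr, data.frame(chrom = "chr1", pos = 5000, strand = "+"))
  expect_equal(sum(prof$raw_count), 1L)
  expect_equal(prof$bin_start[prof$raw_count == 1], 0)  # distance +5 -> bin [0,10)
  # a minus-strand anchor flips the sign: distance becomes -5 -> bin [-10,0)
  prof_m <- anchored_profile(tr, data.frame(chrom = "chr1", pos = 5000, strand = "-"))
  expect_equal(prof_m$bin_start[prof_m$raw_count == 1], -10)
})

test_that("profiles are invariant under genome mirroring", {
  set.seed(13)
  L <- 50000
  mids <- sort(sample.int(L - 8000, 500) + 4000)
  tr <- track_from_midpoints(mids, len = L)
  anchor <- data.frame(chrom = "chr1", pos = 25000, strand = "+")
  # mirror: position p -> L - 1 - p, anchor strand flips
  tr_mir <- track_from_midpoints(sort(L - 1 - mids), len = L)
  anchor_mir <- data.frame(chrom = "chr1", pos = L - 1 - 25000, strand = "-")
  p1 <- anchored_profile(tr, anchor)
  p2 <- anchored_profile(tr_mir, anchor_mir)
  expect_equal(p1$raw_count, p2$raw_count)
  expect_equal(p1$regions, p2$regions)
  expect_equal(p1$normalized, p2$normalized)
})

test_that("bins beyond the chromosome edge are missing, not zero", {
  tr <- track_from_midpoints(c(500, 900), len = 100000)
  prof <- anchored_profile(tr, data.frame(chrom = "chr1", pos = 50, strand = "+"),
                           profile_params(flank = 1000, bin_width = 10))
  up <- prof$bin_start < -50
  expect_true(all(prof$regions[up] == 0))
  expect_true(all(is.na(prof$normalized[up])))
  expect_true(all(prof$regions[prof$bin_start >= -50] == 1))
})

test_that("the vectorized profile equals a brute-force double loop", {
  set.seed(17)
  L <- 200000
  n_anchor <- 60
  mids <- sort(sample.int(L, 8000, replace = TRUE))
  tr <- track_from_midpoints(mids, len = L)
  anchors <- data.frame(chrom = "chr1",
                        pos = sample.int(L, n_anchor),
                        strand = sample(c("+", "-", "*"), n_anchor, replace = TRUE))
  params <- profile_params(flank = 2000, bin_width = 10)
  prof <- anchored_profile(tr, anchors, params)

  raw_bf <- numeric(nrow(prof))
  reg_bf <- numeric(nrow(prof))
  for (ai in seq_len(n_anchor)) {
    a <- anchors$pos[ai]
    sgn <- if (anchors$strand[ai] == "-") -1 else 1
    d <- sgn * (mids - a)
    d <- d[d >= -2000 & d < 2000]
    for (v in d) {
      k <- floor(v / 10) + 200 + 1
      raw_bf[k] <- raw_bf[k] + 1
    }
    for (k in seq_len(nrow(prof))) {
      lo_d <- prof$bin_start[k]
      g <- if (sgn == 1) c(a + lo_d, a + lo_d + 10 - 1) else c(a - lo_d - 10 + 1, a - lo_d)
      if (g[1] >= 0 && g[2] <= L - 1) reg_bf[k] <- reg_bf[k] + 1
    }
  }
  expect_equal(prof$raw_count, as.integer(raw_bf))
  expect_equal(prof$regions, reg_bf)
  norm_bf <- ifelse(reg_bf > 0, raw_bf / (reg_bf * (tr$total_reads / 1e6)), NA_real_)
  expect_equal(prof$normalized, norm_bf)
  # mass conservation
  expect_equal(sum(prof$raw_count), sum(raw_bf))
})

test_that("halving the reads leaves the expected normalized profile unchanged", {
  spec <- small_landscape(seed = 2, n_genes = 120, chrom_mb = 3)
  land <- simulate_landscape(spec)
  reads <- simulate_reads(land, 2e5, seed = 7)
  cs <- spec$chrom_sizes
  act <- land$genes[land$genes$active == TRUE]
  anchors <- data.frame(chrom = act$chrom, pos = act$tss, strand = act$strand)
  full <- anchored_profile(build_midpoint_track(reads, cs), anchors)
  half <- anchored_profile(build_midpoint_track(reads[1:1e5], cs), anchors)
  ok <- !is.na(full$smoothed) & !is.na(half$smoothed) & full$smoothed > 0.5 * mean(full$smoothed, na.rm = TRUE)
  rel <- abs(half$smoothed[ok] - full$smoothed[ok]) / full$smoothed[ok]
  expect_lt(stats::median(rel), 0.15)
  expect_gt(pearson_r(full$smoothed[ok], half$smoothed[ok]), 0.95)
})

test_that("smoothing is a shrink-to-fit centered moving average", {
  expect_equal(smooth_profile(rep(2, 9), 5), rep(2, 9))        # mean preservation
  expect_equal(smooth_profile(c(0, 0, 5, 0, 0), 5)[3], 1)      # 5/5 at the center
  expect_equal(smooth_profile(c(1, 5, 9), 1), c(1, 5, 9))      # window 1 is identity
  expect_error(smooth_profile(1:5, 4), "odd")
  # NA bins are excluded from their neighbors' averages
  expect_equal(smooth_profile(c(NA, 4, 6), 3)[2], 5)
  expect_true(is.na(smooth_profile(c(NA, NA, NA), 3)[1]))
  # step subsamples the output grid
  expect_equal(length(smooth_profile(1:10, 3, step = 2)), 5L)
})

test_that("the TSS heatmap assigns footprints to strand layers and offsets", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+", tss = 500)
  reads <- data.frame(chrom = "chr1", start = 527, end = 576, strand = "+")
  hm <- tss_heatmap(reads, genes, total_reads = 1e6, flank = 200)
  hit <- which(hm$sense["g1", ] > 0)
  expect_equal(hm$offsets[hit], 27:75)       # full 49-bp footprint
  expect_equal(unname(hm$sense["g1", hit]), rep(1, 49))  # per-million scaling
  expect_equal(sum(hm$antisense), 0)

  # re-annotating the gene as minus flips both the layer and the axis
  genes_m <- transform(genes, strand = "-")
  hm_m <- tss_heatmap(reads, genes_m, total_reads = 1e6, flank = 200)
  expect_equal(sum(hm_m$sense), 0)
  hit_m <- which(hm_m$antisense["g1", ] > 0)
  expect_equal(hm_m$offsets[hit_m], -75:-27)

  hm0 <- tss_heatmap(reads[0, ], genes, total_reads = 1e6, flank = 200)
  expect_equal(sum(hm0$sense) + sum(hm0$antisense), 0)
  expect_error(tss_heatmap(reads, genes, 1e6, flank = 0), "flank")
})

test_that("phased-array spacing is recovered within 10 bp of the repeat", {
  spec <- small_landscape(seed = 6, n_genes = 150, chrom_mb = 4, active_fraction = 1)
  land <- simulate_landscape(spec)
  tr <- build_midpoint_track(simulate_reads(land, 3e5, seed = 61), spec$chrom_sizes, "a")
  g <- land$genes
  prof <- anchored_profile(tr, data.frame(chrom = g$chrom, pos = g$tss, strand = g$strand))
  x <- prof$smoothed
  sel <- prof$bin_mid > 0 & prof$bin_mid < 1100
  pk <- local_maxima(ifelse(sel, x, NA), halfwidth = 3)
  pk <- pk[x[pk] > 2 * mean(x[abs(prof$bin_mid) > 2000], na.rm = TRUE)]
  spacing <- diff(prof$bin_mid[pk])
  expect_gte(length(spacing), 3L)
  expect_true(all(abs(spacing - 190) <= 10))
})

test_that("NDR summaries recover the planted promoter architecture", {
  spec <- small_landscape(seed = 8, n_genes = 240, chrom_mb = c(3, 3))
  land <- simulate_landscape(spec)
  tr <- build_midpoint_track(simulate_reads(land, 4e5, seed = 81), spec$chrom_sizes, "a")
  g <- land$genes
  act <- g[g$active == TRUE]
  sil <- g[g$active == FALSE]
  pa <- anchored_profile(tr, data.frame(chrom = act$chrom, pos = act$tss, strand = act$strand))
  na <- ndr_summary(pa)
  expect_lt(abs(na$ndr_center - (-60)), 10 + 1e-9)
  expect_lt(abs(na$plus1_position - 100), 10 + 1e-9)
  expect_lt(abs(na$minus1_position - (-180)), 15 + 1e-9)
  expect_gt(na$ndr_depth, 0.8)
  expect_false(na$anchor_occupied)

  ps <- anchored_profile(tr, data.frame(chrom = sil$chrom, pos = sil$tss, strand = sil$strand))
  ns <- ndr_summary(ps)
  expect_true(ns$anchor_occupied)   # one positioned nucleosome on the TSS

  # a profile with no signal at all has no usable baseline
  far <- track_from_midpoints(c(100, 200), len = 1e6)
  pf <- anchored_profile(far, data.frame(chrom = "chr1", pos = 5e5, strand = "+"))
  expect_error(ndr_summary(pf), "baseline|structure")
})
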