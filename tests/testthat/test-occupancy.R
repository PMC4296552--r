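test_that("the midpoint rule offsets 73 bp downstream of the 5' end", {
  expect_equal(read_midpoint(1000, 1049, "+"), 1073)
  expect_equal(read_midpoint(1000, 1049, "-"), 975)   # (end-1) - 73
  expect_equal(read_midpoint(0, 49, "+"), 73)
  expect_error(read_midpoint(0, 49, "?"), "strand")
})

test_that("midpoint tracks are sorted, order-invariant, and count edge drops", {
  cs <- c(chr1 = 10000)
  reads <- data.frame(chrom = "chr1",
                      start = c(500, 100, 900, 300, 700),
                      end = c(549, 149, 949, 349, 749),
                      strand = c("+", "+", "-", "+", "-"))
  tr <- build_midpoint_track(reads, cs)
  expect_equal(tr$midpoints$chr1, sort(c(573, 173, 875, 373, 675)))
  expect_equal(tr$total_reads, 5L)
  shuf <- reads[c(3, 1, 5, 2, 4), ]
  expect_equal(build_midpoint_track(shuf, cs)$midpoints, tr$midpoints)

  # a minus read whose midpoint lands before the chromosome start is
  # dropped from the track but kept in the denominator
  edge <- rbind(reads, data.frame(chrom = "chr1", start = 1, end = 50, strand = "-"))
  tre <- build_midpoint_track(edge, cs)
  expect_equal(tre$total_reads, 6L)
  expect_equal(length(tre$midpoints$chr1), 5L)
  expect_equal(tre$n_dropped, 1L)

  expect_error(build_midpoint_track(data.frame(chrom = "chrZ", start = 0, end = 49, strand = "+"), cs),
               "chrZ")
  empty <- build_midpoint_track(reads[0, ], cs)
  expect_equal(empty$total_reads, 0L)
  expect_equal(empty$midpoints$chr1, numeric(0))
})

test_that("window occupancy reproduces the hand-computed RPKM tiling", {
  tr <- track_from_midpoints(c(500, 10500), len = 20000)
  occ <- window_occupancy(tr, window_size = 10000)
  # rpkm = 1 / ((10000/1000) * (2/1e6)) = 50000
  expect_equal(occ$count, c(1L, 1L))
  expect_equal(occ$rpkm, c(50000, 50000))

  occ5 <- window_occupancy(tr, window_size = 10000, offset = 5000)
  expect_equal(occ5$start, c(0, 5000, 15000))
  expect_equal(occ5$end, c(5000, 15000, 20000))
  expect_equal(occ5$count, c(1L, 1L, 0L))
  # partial windows are width-corrected: 1 / ((5000/1000) * (2/1e6))
  expect_equal(occ5$rpkm, c(100000, 50000, 0))

  expect_error(window_occupancy(build_midpoint_track(
    data.frame(chrom = character(), start = numeric(), end = numeric(), strand = character()),
    c(chr1 = 20000))), "total_reads = 0")
})

test_that("window counts conserve midpoints for every offset", {
  set.seed(11)
  cs <- c(chr1 = 43217, chr2 = 25111)
  reads <- data.frame(chrom = sample(names(cs), 400, replace = TRUE))
  reads$start <- floor(runif(400, 0, cs[reads$chrom] - 49))
  reads$end <- reads$start + 49
  reads$strand <- sample(c("+", "-"), 400, replace = TRUE)
  tr <- build_midpoint_track(reads, cs)
  n_mid <- sum(lengths(tr$midpoints))
  for (off in c(0, 1, 2500, 9999)) {
    occ <- window_occupancy(tr, window_size = 10000, offset = off)
    expect_equal(sum(occ$count), n_mid)
    expect_true(all(occ$end > occ$start))
  }
})

test_that("RPKM is invariant to doubling counts and depth together", {
  set.seed(3)
  mids <- sort(sample.int(50000, 200))
  tr1 <- track_from_midpoints(mids, len = 60000)
  tr2 <- track_from_midpoints(rep(mids, each = 2), len = 60000)
  o1 <- window_occupancy(tr1, 10000)
  o2 <- window_occupancy(tr2, 10000)
  expect_equal(o1$rpkm, o2$rpkm)
})

test_that("window occupancy equals a naive per-midpoint loop", {
  set.seed(5)
  cs <- c(chr1 = 33333)
  mids <- sort(sample.int(cs[["chr1"]] - 200, 5000, replace = TRUE)) + 80
  tr <- track_from_midpoints(mids, len = cs[["chr1"]])
  for (off in c(0, 4000)) {
    occ <- window_occupancy(tr, window_size = 10000, offset = off)
    naive <- sapply(seq_len(nrow(occ)), function(i) {
      sum(mids >= occ$start[i] & mids < occ$end[i])
    })
    expect_equal(occ$count, naive)
  }
})

test_that("spearman and pearson satisfy their identities and guards", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(x, -x), -1)
  expect_equal(spearman_rho(c(1, 2, 3), c(1, 4, 9)), 1)
  expect_equal(pearson_r(x, 2 * x + 3), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(spearman_rho(x, x[-1]), "length")
  expect_error(spearman_rho(rep(1, 5), x[1:5]), "constant")
  expect_error(pearson_r(c(1, 2), c(3, 4)), "at least 3")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(21)
  transforms <- list(function(v) exp(v), function(v) v^3, function(v) rank(v),
                     function(v) 5 * v - 2)
  for (i in 1:10) {
    x <- rnorm(50)
    y <- rnorm(50)
    base <- spearman_rho(x, y)
    f <- transforms[[(i %% length(transforms)) + 1]]
    expect_equal(spearman_rho(f(x), y), base)
    expect_equal(spearman_rho(x, f(y)), base)
  }
})

test_that("the correlation matrix is consistent with pairwise calls", {
  set.seed(9)
  o1 <- occ_from_rpkm(runif(50), sample_id = "a")
  o2 <- occ_from_rpkm(runif(50), sample_id = "b")
  o3 <- occ_from_rpkm(o1$rpkm + rnorm(50, 0, 0.01), sample_id = "c")
  m <- correlation_matrix(list(o1, o2, o3), method = "spearman")
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m, t(m))
  expect_equal(m["a", "b"], spearman_rho(o1$rpkm, o2$rpkm))
  expect_equal(m["a", "c"], spearman_rho(o1$rpkm, o3$rpkm))
  # identical samples correlate at exactly 1
  m2 <- correlation_matrix(list(o1, occ_from_rpkm(o1$rpkm, sample_id = "a2")))
  expect_equal(unname(m2[1, 2]), 1)
  # mismatched tilings are an error
  bad <- occ_from_rpkm(runif(40), sample_id = "short")
  expect_error(correlation_matrix(list(o1, bad)), "tiling")
})

test_that("fold-change windows match hand computations and merge adjacently", {
  a <- occ_from_rpkm(c(10, 10), sample_id = "a")
  b <- occ_from_rpkm(c(10, 25), sample_id = "b")
  fc <- fold_change_regions(a, b, threshold = 2, pseudocount = 0)
  expect_equal(nrow(fc$windows), 1L)
  expect_equal(fc$windows$start, 10000)
  expect_equal(fc$windows$fold, 2.5)

  expect_equal(nrow(fold_change_regions(a, a, threshold = 2, pseudocount = 0)$windows), 0L)

  a2 <- occ_from_rpkm(c(0, 10), sample_id = "a")
  b2 <- occ_from_rpkm(c(5, 10), sample_id = "b")
  fc2 <- fold_change_regions(a2, b2, threshold = 2, pseudocount = 1)
  expect_equal(fc2$windows$start, 0)
  expect_equal(fc2$windows$fold, 6)

  # adjacent flagged windows merge into one region
  a3 <- occ_from_rpkm(c(30, 30, 10, 30), sample_id = "a")
  b3 <- occ_from_rpkm(c(10, 10, 10, 10), sample_id = "b")
  fc3 <- fold_change_regions(a3, b3, threshold = 2, pseudocount = 0)
  expect_equal(nrow(fc3$regions), 2L)
  expect_equal(fc3$regions$start, c(0, 30000))
  expect_equal(fc3$regions$n_windows, c(2L, 1L))

  expect_error(fold_change_regions(a, b, threshold = 1), "> 1")
})

test_that("between-sample correlations are robust to the scan offset", {
  spec <- small_landscape(seed = 4, n_genes = 150, chrom_mb = c(3, 3))
  land <- simulate_landscape(spec)
  cs <- spec$chrom_sizes
  tr_a <- build_midpoint_track(simulate_reads(land, 2e5, seed = 41), cs, "a")
  tr_b <- build_midpoint_track(simulate_reads(land, 2e5, seed = 42), cs, "b")
  land_c <- simulate_landscape(small_landscape(seed = 99, n_genes = 150, chrom_mb = c(3, 3)))
  tr_c <- build_midpoint_track(simulate_reads(land_c, 2e5, seed = 43), cs, "c")
  # scanning with different offsets returns the same verdict: replicates
  # stay highly correlated, divergent samples do not
  rep_rho <- div_rho <- numeric(0)
  for (off in c(0, 2500, 5000)) {
    oa <- window_occupancy(tr_a, 10000, offset = off)
    ob <- window_occupancy(tr_b, 10000, offset = off)
    oc <- window_occupancy(tr_c, 10000, offset = off)
    rep_rho <- c(rep_rho, spearman_rho(oa$rpkm, ob$rpkm))
    div_rho <- c(div_rho, spearman_rho(oa$rpkm, oc$rpkm))
  }
  expect_true(all(rep_rho > 0.9))
  expect_true(all(rep_rho > div_rho))
  expect_lt(max(rep_rho) - min(rep_rho), 0.05)
})
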