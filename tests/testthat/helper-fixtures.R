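# Shared fixture builders. Everything is generated in code; the only
# files touched are per-test tempfiles.

write_lines_tmp <- function(lines, ext = ".bed") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# A track whose midpoints are exactly `mids` on one chromosome: plus-strand
# reads with start = mid - 73 (midpoint rule inverted by hand).
track_from_midpoints <- function(mids, chrom = "chr1", len = max(mids) + 1000,
                                 sample_id = "t", extra_reads = 0) {
  reads <- data.frame(chrom = chrom, start = mids - 73, end = mids - 73 + 49,
                      strand = "+")
  build_midpoint_track(reads, stats::setNames(len, chrom), sample_id = sample_id)
}

# Fabricated occupancy track with given RPKM values on one chromosome.
occ_from_rpkm <- function(rpkm, window = 10000, chrom = "chr1", sample_id = "x") {
  n <- length(rpkm)
  dt <- data.table::data.table(chrom = chrom, start = (0:(n - 1)) * window,
                               end = (1:n) * window, count = NA_integer_, rpkm = rpkm)
  structure(dt, class = c("occupancy_track", class(dt)),
            sample_id = sample_id, window_size = window, offset = 0,
            total_reads = 1e6)
}

# Small landscape shared by several heavier tests.
small_landscape <- function(seed = 1, n_genes = 200, n_sites = 0,
                            chrom_mb = c(3, 3), active_fraction = 0.7) {
  cs <- stats::setNames(chrom_mb * 1e6, paste0("chr", seq_along(chrom_mb)))
  landscape_spec(chrom_sizes = cs, n_genes = n_genes, active_fraction = active_fraction,
                 n_sites_per_class = n_sites, seed = seed)
}
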