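# Coordinate convention, fixed once for the whole package:
# 0-based half-open [start, end), BED-native. The minus-strand TSS is end - 1
# (the last covered base). No other file re-interprets BED columns.

#' Read aligned MNase-seq reads from a BED6 file
#'
#' Each line must carry at least six tab-separated fields
#' (chrom, start, end, name, score, strand). Coordinates are kept 0-based
#' half-open; input order is preserved. Gzipped files are accepted
#' transparently.
#'
#' @param path path to a BED6 file (optionally gzipped).
#' @return `data.table` with columns `chrom`, `start`, `end`, `strand`.
#' @export
read_bed_alignments <- function(path) {
  if (!file.exists(path)) stop_nucorg("alignment file does not exist: %s", path)
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE, colClasses = list(character = 1))
  if (nrow(dt) == 0L) {
    return(data.table(chrom = character(), start = numeric(), end = numeric(), strand = character()))
  }
  if (ncol(dt) < 6L) {
    bad <- which(rowSums(!is.na(as.matrix(dt))) < 6L)
    stop_nucorg("malformed BED6 line %d in %s: fewer than 6 fields", if (length(bad)) bad[1] else 1L, path)
  }
  out <- dt[, .(chrom = as.character(V1), start = as.numeric(V2), end = as.numeric(V3),
                strand = as.character(V6))]
  bad <- which(is.na(out$start) | is.na(out$end))
  if (length(bad) > 0L) stop_nucorg("malformed BED6 line %d in %s: non-numeric coordinates", bad[1], path)
  bad <- which(!(out$strand %in% c("+", "-")))
  if (length(bad) > 0L) {
    stop_nucorg("malformed BED6 line %d in %s: unknown strand symbol '%s'", bad[1], path, out$strand[bad[1]])
  }
  bad <- which(out$end <= out$start)
  if (length(bad) > 0L) {
    stop_nucorg("malformed BED6 line %d in %s: end <= start (%d <= %d)",
                bad[1], path, as.integer(out$end[bad[1]]), as.integer(out$start[bad[1]]))
  }
  out[]
}

#' Read a minimal SAM subset as alignments
#'
#' Supports single-segment, ungapped records: mandatory columns 1-6 are
#' used, the strand comes from FLAG bit 0x10 and the alignment length from
#' a CIGAR of the form `<n>M` (or the SEQ length when CIGAR is `*`).
#' Unmapped records (FLAG bit 0x4) are skipped. POS is converted from
#' 1-based to the package's 0-based half-open convention.
#'
#' @param path path to a SAM text file.
#' @return `data.table` with columns `chrom`, `start`, `end`, `strand`.
#' @export
read_sam_alignments <- function(path) {
  if (!file.exists(path)) stop_nucorg("alignment file does not exist: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(data.table(chrom = character(), start = numeric(), end = numeric(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parse_one <- function(f, i) {
    if (length(f) < 10L) stop_nucorg("malformed SAM line %d: fewer than 10 fields", i)
    flag <- suppressWarnings(as.integer(f[2]))
    if (is.na(flag)) stop_nucorg("malformed SAM line %d: non-integer FLAG", i)
    if (bitwAnd(flag, 4L) != 0L) return(NULL)
    pos <- suppressWarnings(as.numeric(f[4]))
    if (is.na(pos) || pos < 1) stop_nucorg("malformed SAM line %d: bad POS", i)
    cigar <- f[6]
    len <- if (cigar == "*") nchar(f[10]) else {
      m <- regmatches(cigar, regexec("^([0-9]+)M$", cigar))[[1]]
      if (length(m) != 2L) stop_nucorg("unsupported CIGAR '%s' on SAM line %d (only ungapped <n>M)", cigar, i)
      as.numeric(m[2])
    }
    list(chrom = f[3], start = pos - 1, end = pos - 1 + len,
         strand = if (bitwAnd(flag, 16L) != 0L) "-" else "+")
  }
  recs <- Filter(Negate(is.null), Map(parse_one, fields, seq_along(fields)))
  if (length(recs) == 0L) {
    return(data.table(chrom = character(), start = numeric(), end = numeric(), strand = character()))
  }
  rbindlist(recs)[]
}

#' Read a BED-like gene annotation table
#'
#' Expects tab-separated columns chrom, start, end, gene_id, score, strand
#' (no header). The TSS is derived once here: `start` for plus-strand
#' genes, `end - 1` for minus-strand genes (the last covered base under
#' the half-open convention).
#'
#' @param path path to the gene table.
#' @return `data.table` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop_nucorg("gene table does not exist: %s", path)
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = list(character = 1))
  if (ncol(dt) < 6L) stop_nucorg("gene table %s must have >= 6 columns", path)
  out <- dt[, .(gene_id = as.character(V4), chrom = as.character(V1),
                start = as.numeric(V2), end = as.numeric(V3), strand = as.character(V6))]
  if (any(!(out$strand %in% c("+", "-")))) stop_nucorg("gene table %s: strand must be + or -", path)
  if (any(out$end <= out$start)) stop_nucorg("gene table %s: end <= start", path)
  dup <- unique(out$gene_id[duplicated(out$gene_id)])
  if (length(dup) > 0L) stop_nucorg("duplicate gene_id(s): %s", paste(dup, collapse = ", "))
  out[, tss := gene_tss(start, end, strand)]
  out[]
}

#' TSS position under the package coordinate convention
#'
#' @param start,end 0-based half-open gene interval.
#' @param strand "+" or "-".
#' @return numeric TSS position (`start` on +, `end - 1` on -).
#' @export
gene_tss <- function(start, end, strand) {
  ifelse(strand == "+", start, end - 1)
}

#' Read transcription-factor binding sites from BED
#'
#' Requires at least chrom, start, end. The site center is
#' `floor((start + end - 1) / 2)`, i.e. the left-middle covered base.
#'
#' @param path path to a BED file.
#' @return `data.table` with columns `chrom`, `start`, `end`, `center`.
#' @export
read_bed_sites <- function(path) {
  if (!file.exists(path)) stop_nucorg("site file does not exist: %s", path)
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = list(character = 1))
  if (nrow(dt) == 0L) {
    return(data.table(chrom = character(), start = numeric(), end = numeric(), center = numeric()))
  }
  if (ncol(dt) < 3L) stop_nucorg("site BED %s must have >= 3 columns", path)
  out <- dt[, .(chrom = as.character(V1), start = as.numeric(V2), end = as.numeric(V3))]
  if (any(out$end <= out$start)) stop_nucorg("site BED %s: end <= start", path)
  out[, center := site_center(start, end)]
  out[]
}

#' Binding-site center position
#' @param start,end 0-based half-open interval.
#' @return `floor((start + end - 1)/2)`, always inside `[start, end)`.
#' @export
site_center <- function(start, end) {
  floor((start + end - 1) / 2)
}

#' Read a two-column chromosome-size table
#'
#' @param path TSV with columns chromosome name and length (bp), no header.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop_nucorg("chrom sizes file does not exist: %s", path)
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = list(character = 1))
  if (ncol(dt) < 2L) stop_nucorg("chrom sizes %s must have 2 columns", path)
  len <- as.numeric(dt[[2]])
  if (any(is.na(len) | len <= 0)) stop_nucorg("chrom sizes %s: lengths must be positive numbers", path)
  setNames(len, as.character(dt[[1]]))
}

#' Write a table as deterministic TSV
#'
#' Columns keep their input order; non-integer numeric columns are
#' formatted to 6 significant digits so that write -> read -> write is
#' byte-identical. An empty table writes a header-only file.
#'
#' @param rows data.frame-like object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  dt <- as.data.table(rows)
  for (j in names(dt)) {
    v <- dt[[j]]
    if (is.double(v) && !all(is.na(v) | v == floor(v))) {
      dt[, (j) := ifelse(is.na(v), NA_character_, sprintf("%.6g", v))]
    }
  }
  ok <- tryCatch({
    fwrite(dt, path, sep = "\t", quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_nucorg("cannot write table to %s: %s", path, conditionMessage(ok))
  invisible(path)
}

#' Write alignments back to BED6
#'
#' @param reads table with `chrom`, `start`, `end`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_alignments <- function(reads, path) {
  dt <- as.data.table(reads)
  out <- data.table(dt$chrom, as.integer(dt$start), as.integer(dt$end),
                    sprintf("r%d", seq_len(nrow(dt))), 0L, dt$strand)
  fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}
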