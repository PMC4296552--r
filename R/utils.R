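#' @importFrom data.table data.table as.data.table setorder := fread fwrite rbindlist setnames copy
#' @importFrom stats cor rnorm rbinom rlnorm rnbinom rpois runif setNames sd acf complete.cases
#' @importFrom utils head tail
NULL

# data.table NSE columns
utils::globalVariables(c(
  ".", ".N", "chrom", "start", "end", "strand", "pos", "weight", "count",
  "rpkm", "gene_id", "tss", "width", "fold", "flagged", "region_id",
  "bin_start", "center", "label", "exon_length", "active", "perturbed"
))

#' Derive a reproducible child seed from a base seed and a stream name
#'
#' All randomness in the simulator flows from one user seed; independent
#' stages (landscape, reads, perturbation, expression) draw from named
#' substreams so that, e.g., regenerating reads does not disturb the
#' landscape. The mix is a small deterministic integer hash kept below
#' 2^31 - 1 so it is always a valid R seed.
#'
#' @param seed integer base seed.
#' @param stream character stream name.
#' @param index optional integer distinguishing repeated draws of one stream.
#' @return integer seed.
#' @export
substream_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(seed) %% 65521) * 32003 + h * 7 + (index %% 1009) * 11) %% 2147483647L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stop_nucorg <- function(...) stop(sprintf(...), call. = FALSE)

check_chroms_known <- function(chroms, chrom_sizes, what = "record") {
  unknown <- setdiff(unique(as.character(chroms)), names(chrom_sizes))
  if (length(unknown) > 0L) {
    stop_nucorg("%s(s) on chromosome(s) absent from chrom sizes: %s",
                what, paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

#' Locate local maxima in a numeric series
#'
#' A local maximum is a position strictly greater than its `halfwidth`
#' neighbors on each side (the comparison window shrinks at the edges of
#' the series). `NA` values never qualify and never block a neighbor.
#' On exact plateaus no position qualifies, which keeps peak calls
#' deterministic.
#'
#' @param x numeric vector (may contain `NA`).
#' @param halfwidth integer, neighbors compared on each side (default 2).
#' @return integer vector of indices of local maxima, ascending.
#' @export
local_maxima <- function(x, halfwidth = 2L) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  out <- logical(n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    lo <- max(1L, i - halfwidth)
    hi <- min(n, i + halfwidth)
    nb <- x[setdiff(lo:hi, i)]
    nb <- nb[!is.na(nb)]
    out[i] <- length(nb) > 0L && all(x[i] > nb)
  }
  which(out)
}
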