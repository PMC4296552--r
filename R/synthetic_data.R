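# Synthetic nucleosome landscapes, MNase-seq reads and expression tables.
#
# A landscape is a weighted catalogue of dyad (nucleosome-center)
# positions. Reads are sampled by drawing a dyad proportionally to its
# weight, jittering it with Gaussian positional fuzziness, drawing a
# strand fairly, and inverting the 73-bp midpoint rule, so
# midpoint(read) == jittered dyad exactly, on both strands.
#
# On top of positioned dyads and a uniform background grid, every 10-kb
# domain carries a lognormal weight multiplier. This emulates the smooth
# chromatin-domain-scale occupancy variation (digestion accessibility,
# compaction) that real MNase-seq coverage shows and that makes genome
# windows distinguishable; without it, windows away from genes would be
# statistically exchangeable and window-rank correlations meaningless.

#' Specification of a synthetic nucleosome landscape
#'
#' Defaults encode the canonical promoter and binding-site geometries:
#' active promoters carry a -1 nucleosome at TSS-180, a nucleosome-free
#' region (zero dyad weight over `[TSS-130, TSS+10]`, centered at
#' TSS-60), and a phased array of five dyads from TSS+100 at the repeat
#' length; silent promoters carry a single positioned dyad on the TSS.
#' Binding sites come in four geometries matching the four topology
#' classes (see [simulate_landscape()]).
#'
#' @param chrom_sizes named numeric vector (default two 5-Mb chromosomes).
#' @param nrl nucleosome repeat length in bp (default 190).
#' @param fuzz_sd positional fuzziness sd in bp (default 20).
#' @param background_weight weight of each background-grid dyad relative
#'   to a positioned dyad of weight 1 (default 0.1; grid spacing `nrl`).
#' @param domain_size bp per occupancy domain (default 10000).
#' @param domain_sdlog sdlog of the lognormal domain multiplier
#'   (default 0.5).
#' @param n_genes number of genes (default 400).
#' @param active_fraction fraction of active genes (default 0.7).
#' @param n_sites_per_class binding sites per topology class
#'   (default 100).
#' @param read_length sequenced read length in bp (default 49).
#' @param midpoint_offset bp from read 5' end to dyad (default 73).
#' @param periodic_central_weight weight of the small central dyad of the
#'   periodic-linker geometry (default 0.01).
#' @param seed integer master seed; all stages draw from named substreams
#'   of it.
#' @return object of class `landscape_spec`.
#' @export
landscape_spec <- function(chrom_sizes = c(chr1 = 5e6, chr2 = 5e6),
                           nrl = 190, fuzz_sd = 20, background_weight = 0.1,
                           domain_size = 10000, domain_sdlog = 0.5,
                           n_genes = 400, active_fraction = 0.7,
                           n_sites_per_class = 100,
                           read_length = 49, midpoint_offset = 73,
                           periodic_central_weight = 0.01,
                           seed = 1) {
  stopifnot(all(chrom_sizes > 0), nrl > 0, fuzz_sd >= 0,
            active_fraction >= 0, active_fraction <= 1,
            n_genes >= 0, n_sites_per_class >= 0, read_length > 0)
  structure(list(chrom_sizes = chrom_sizes, nrl = nrl, fuzz_sd = fuzz_sd,
                 background_weight = background_weight,
                 domain_size = domain_size, domain_sdlog = domain_sdlog,
                 n_genes = n_genes, active_fraction = active_fraction,
                 n_sites_per_class = n_sites_per_class,
                 read_length = read_length, midpoint_offset = midpoint_offset,
                 periodic_central_weight = periodic_central_weight,
                 seed = seed),
            class = "landscape_spec")
}

TOPOLOGY_CLASSES <- c("linker", "nucleosomal", "periodic_linker", "border")

# Non-overlapping anchor placement: slot grid with uniform in-slot jitter,
# guaranteeing >= sep - jitter separation between any two anchors.
place_anchors <- function(chrom_sizes, n, margin = 3100, sep = 2600, jitter = 400) {
  slots <- lapply(names(chrom_sizes), function(cn) {
    L <- chrom_sizes[[cn]]
    k <- floor((L - 2 * margin) / sep)
    if (k < 1) return(NULL)
    data.table(chrom = cn, slot = margin + (0:(k - 1)) * sep)
  })
  slots <- rbindlist(Filter(Negate(is.null), slots))
  if (nrow(slots) < n) {
    stop_nucorg("geometry exceeds chromosomes: %d anchors requested, %d slots available", n, nrow(slots))
  }
  pick <- slots[sample.int(nrow(slots), n)]
  pick[, pos := slot + floor(runif(.N, 0, jitter))]
  pick[, .(chrom, pos)]
}

utils::globalVariables(c("slot", "kind", "mult", "segment", "base_weight", "mid"))

#' Simulate a nucleosome landscape
#'
#' Builds the weighted dyad catalogue (background grid + promoter and
#' binding-site geometries, scaled by per-domain multipliers), the gene
#' table with planted activity labels, and the four binding-site tables
#' with planted topology labels. Deterministic given `spec$seed`.
#'
#' Site geometries (oriented around the site center, weights relative to
#' a positioned dyad):
#' * `linker`: dyads at +-95 bp; background suppressed within +-250 bp.
#' * `nucleosomal`: one dyad on the center.
#' * `periodic_linker`: dyads at +-(95 + 190k), k = 0..3, a small central
#'   dyad, background suppressed within +-810 bp.
#' * `border`: one dyad at +73 or -73 bp (fair coin per site).
#'
#' @param spec a [landscape_spec()].
#' @return object of class `nuc_landscape`: list with `dyads`
#'   (`chrom`, `pos`, `base_weight`, `weight`, `kind`), `domains`,
#'   `genes`, `sites` (named list by class), `spec`.
#' @export
simulate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  with_seed(substream_seed(spec$seed, "landscape"), {
    cs <- spec$chrom_sizes
    n_sites_total <- spec$n_sites_per_class * length(TOPOLOGY_CLASSES)
    anchors <- if (spec$n_genes + n_sites_total > 0) {
      place_anchors(cs, spec$n_genes + n_sites_total)
    } else data.table(chrom = character(), pos = numeric())

    # genes
    genes <- if (spec$n_genes > 0) {
      g <- anchors[seq_len(spec$n_genes)]
      g[, gene_id := sprintf("g%04d", .I)]
      g[, strand := sample(c("+", "-"), .N, replace = TRUE)]
      g[, tss := pos]
      glen <- pmax(round(rlnorm(nrow(g), log(10000), 0.5)), 1000)
      g[, start := ifelse(strand == "+", tss, pmax(tss - glen + 1, 0))]
      g[, end := ifelse(strand == "+", pmin(tss + glen, cs[chrom]), tss + 1)]
      g[, exon_length := pmax(round(rlnorm(.N, log(1500), 0.5)), 200)]
      g[, active := runif(.N) < spec$active_fraction]
      g[, perturbed := FALSE]
      g[, .(gene_id, chrom, start, end, strand, tss, exon_length, active, perturbed)]
    } else {
      data.table(gene_id = character(), chrom = character(), start = numeric(),
                 end = numeric(), strand = character(), tss = numeric(),
                 exon_length = numeric(), active = logical(), perturbed = logical())
    }

    # binding sites, one block per class
    sites <- list()
    if (spec$n_sites_per_class > 0) {
      offset0 <- spec$n_genes
      for (ci in seq_along(TOPOLOGY_CLASSES)) {
        cls <- TOPOLOGY_CLASSES[ci]
        s <- anchors[offset0 + (ci - 1) * spec$n_sites_per_class + seq_len(spec$n_sites_per_class)]
        s <- s[, .(chrom, center = pos)]
        s[, start := center - 5]
        s[, end := center + 7]
        s[, label := cls]
        s[, perturbed := FALSE]
        sites[[cls]] <- s[, .(chrom, start, end, center, label, perturbed)]
      }
    }

    # dyad catalogue: background grid first
    half <- floor(spec$nrl / 2)
    bg <- rbindlist(lapply(names(cs), function(cn) {
      data.table(chrom = cn, pos = seq(half, cs[[cn]] - 1, by = spec$nrl),
                 base_weight = spec$background_weight, kind = "bg")
    }))

    suppress <- list()  # genomic intervals where background is removed
    pos_dyads <- list()
    dir_of <- function(strand) ifelse(strand == "+", 1, -1)

    if (nrow(genes) > 0) {
      act <- genes[active == TRUE]
      if (nrow(act) > 0) {
        d <- dir_of(act$strand)
        array_off <- c(-180, 100 + spec$nrl * (0:4))
        pos_dyads[["gene_act"]] <- rbindlist(lapply(array_off, function(o) {
          data.table(chrom = act$chrom, pos = act$tss + d * o, base_weight = 1, kind = "pos")
        }))
        suppress[["ndr"]] <- data.table(
          chrom = act$chrom,
          lo = ifelse(act$strand == "+", act$tss - 130, act$tss - 10),
          hi = ifelse(act$strand == "+", act$tss + 10, act$tss + 130))
      }
      sil <- genes[active == FALSE]
      if (nrow(sil) > 0) {
        pos_dyads[["gene_sil"]] <- data.table(chrom = sil$chrom, pos = sil$tss,
                                              base_weight = 1, kind = "pos")
      }
    }

    if (length(sites) > 0) {
      s <- sites[["linker"]]
      pos_dyads[["linker"]] <- data.table(
        chrom = rep(s$chrom, 2), pos = c(s$center - 95, s$center + 95),
        base_weight = 1, kind = "pos")
      suppress[["linker"]] <- data.table(chrom = s$chrom, lo = s$center - 250, hi = s$center + 250)

      s <- sites[["nucleosomal"]]
      pos_dyads[["nucleosomal"]] <- data.table(chrom = s$chrom, pos = s$center,
                                               base_weight = 1, kind = "pos")

      s <- sites[["periodic_linker"]]
      per_off <- c(-(95 + spec$nrl * (3:0)), 95 + spec$nrl * (0:3))
      pos_dyads[["periodic"]] <- rbindlist(c(
        lapply(per_off, function(o) data.table(chrom = s$chrom, pos = s$center + o,
                                               base_weight = 1, kind = "pos")),
        list(data.table(chrom = s$chrom, pos = s$center,
                        base_weight = spec$periodic_central_weight, kind = "pos"))))
      suppress[["periodic"]] <- data.table(chrom = s$chrom, lo = s$center - 810, hi = s$center + 810)

      s <- sites[["border"]]
      sgn <- sample(c(-1, 1), nrow(s), replace = TRUE)
      pos_dyads[["border"]] <- data.table(chrom = s$chrom, pos = s$center + sgn * 73,
                                          base_weight = 1, kind = "pos")
    }

    dyads <- rbindlist(c(list(bg), pos_dyads), use.names = TRUE)
    if (any(dyads$pos < 0 | dyads$pos >= cs[dyads$chrom])) {
      stop_nucorg("geometry places a dyad outside its chromosome")
    }

    # remove background dyads inside suppressed intervals
    if (length(suppress) > 0) {
      sup <- rbindlist(suppress)
      for (cn in unique(sup$chrom)) {
        iv <- sup[chrom == cn]
        bgi <- which(dyads$chrom == cn & dyads$kind == "bg")
        if (length(bgi) == 0L) next
        p <- dyads$pos[bgi]
        lo <- sort(iv$lo)
        hi <- iv$hi[order(iv$lo)]
        j <- findInterval(p, lo)
        drop <- j >= 1 & p <= hi[pmax(j, 1)]
        if (any(drop)) dyads <- dyads[-bgi[drop]]
      }
    }

    # per-domain lognormal multipliers
    domains <- lapply(names(cs), function(cn) {
      rlnorm(ceiling(cs[[cn]] / spec$domain_size), 0, spec$domain_sdlog)
    })
    names(domains) <- names(cs)
    dyads[, weight := base_weight * domains[[chrom[1]]][floor(pos / spec$domain_size) + 1], by = chrom]
    setorder(dyads, chrom, pos)

    structure(list(dyads = dyads[], domains = domains, genes = genes,
                   sites = sites, spec = spec),
              class = "nuc_landscape")
  })
}

#' @export
print.nuc_landscape <- function(x, ...) {
  cat(sprintf("<nuc_landscape> %d chromosome(s), %d dyads, %d genes, %d site classes\n",
              length(x$spec$chrom_sizes), nrow(x$dyads), nrow(x$genes), length(x$sites)))
  invisible(x)
}

#' Simulate MNase-seq reads from a landscape
#'
#' Per read: a dyad is drawn proportionally to its weight, jittered by
#' `Normal(0, fuzz_sd)` (rounded), a strand is drawn fairly, and the
#' midpoint rule is inverted: plus reads start at `dyad - 73`, minus reads
#' end at `dyad + 73 + 1`; reads falling off the chromosome are redrawn.
#' So `midpoint(read) == jittered dyad` exactly, on both strands.
#'
#' @param landscape a `nuc_landscape`.
#' @param n_reads number of reads (> 0).
#' @param seed integer seed for the read substream.
#' @return `data.table` with `chrom`, `start`, `end`, `strand`.
#' @export
simulate_reads <- function(landscape, n_reads, seed = 1) {
  stopifnot(inherits(landscape, "nuc_landscape"), n_reads > 0)
  dy <- landscape$dyads
  if (nrow(dy) == 0L || sum(dy$weight) <= 0) stop_nucorg("landscape has zero total dyad weight")
  spec <- landscape$spec
  cs <- spec$chrom_sizes
  off <- spec$midpoint_offset
  rl <- spec$read_length
  with_seed(substream_seed(seed, "reads"), {
    draw <- function(n) {
      i <- sample.int(nrow(dy), n, replace = TRUE, prob = dy$weight)
      d <- dy$pos[i] + round(rnorm(n, 0, spec$fuzz_sd))
      plus <- runif(n) < 0.5
      start <- ifelse(plus, d - off, d + off + 1 - rl)
      data.table(chrom = dy$chrom[i], start = start, end = start + rl,
                 strand = ifelse(plus, "+", "-"))
    }
    out <- draw(n_reads)
    bad <- which(out$start < 0 | out$end > cs[out$chrom])
    while (length(bad) > 0L) {
      repl <- draw(length(bad))
      for (j in names(out)) data.table::set(out, i = bad, j = j, value = repl[[j]])
      bad <- which(out$start < 0 | out$end > cs[out$chrom])
    }
    out[]
  })
}

#' Perturb a fraction of a landscape's occupancy domains
#'
#' A `fraction` of the 10-kb (i.e. `domain_size`) segments is selected at
#' random; each selected segment receives a fresh domain multiplier and
#' its positioned dyads are replaced by a fresh Poisson number (at the
#' genome-average positioned-dyad density) of uniformly placed unit-weight
#' dyads. The background grid is untouched. At fraction 1 the segment
#' occupancy totals are therefore independent of the original; at
#' fraction 0 the landscape is returned unchanged. Genes and sites whose
#' analysis footprint intersects a perturbed segment are flagged
#' `perturbed` in the returned tables (their planted labels no longer
#' describe the local dyad geometry).
#'
#' @param landscape a `nuc_landscape`.
#' @param fraction fraction of segments to redraw, in `[0, 1]`.
#' @param seed integer seed for the perturbation substream.
#' @return a new `nuc_landscape`.
#' @export
perturb_landscape <- function(landscape, fraction, seed = 1) {
  stopifnot(inherits(landscape, "nuc_landscape"), fraction >= 0, fraction <= 1)
  if (fraction == 0) return(landscape)
  spec <- landscape$spec
  cs <- spec$chrom_sizes
  ds <- spec$domain_size
  with_seed(substream_seed(seed, "perturb"), {
    seg <- rbindlist(lapply(names(cs), function(cn) {
      n <- ceiling(cs[[cn]] / ds)
      data.table(chrom = cn, segment = seq_len(n) - 1L)
    }))
    n_sel <- round(fraction * nrow(seg))
    sel <- seg[sample.int(nrow(seg), n_sel)]
    sel_key <- paste(sel$chrom, sel$segment)

    dy <- copy(landscape$dyads)
    dy[, segment := floor(pos / ds)]
    in_sel <- paste(dy$chrom, dy$segment) %in% sel_key
    n_pos_total <- sum(dy$kind == "pos")
    mean_pos <- n_pos_total / nrow(seg)

    kept <- dy[!(in_sel & dy$kind == "pos")]
    domains <- lapply(landscape$domains, identity)
    new_dyads <- list()
    for (r in seq_len(nrow(sel))) {
      cn <- sel$chrom[r]; sg <- sel$segment[r]
      domains[[cn]][sg + 1] <- rlnorm(1, 0, spec$domain_sdlog)
      k <- rpois(1, mean_pos)
      if (k > 0) {
        lo <- sg * ds
        hi <- min((sg + 1) * ds, cs[[cn]]) - 1
        new_dyads[[length(new_dyads) + 1]] <- data.table(
          chrom = cn, pos = floor(runif(k, lo, hi + 1)),
          base_weight = 1, kind = "pos", segment = sg)
      }
    }
    dy2 <- rbindlist(c(list(kept), new_dyads), use.names = TRUE, fill = TRUE)
    dy2[, weight := base_weight * domains[[chrom[1]]][floor(pos / ds) + 1], by = chrom]
    dy2[, segment := NULL]
    setorder(dy2, chrom, pos)

    touches <- function(chrom_v, lo, hi) {
      s1 <- floor(lo / ds); s2 <- floor(hi / ds)
      mapply(function(cn, a, b) any(paste(cn, a:b) %in% sel_key), chrom_v, s1, s2)
    }
    genes <- copy(landscape$genes)
    if (nrow(genes) > 0) {
      genes[, perturbed := perturbed | touches(chrom, pmax(tss - 3000, 0), tss + 3000)]
    }
    sites <- lapply(landscape$sites, function(s) {
      s <- copy(s)
      if (nrow(s) > 0) s[, perturbed := perturbed | touches(chrom, pmax(center - 1000, 0), center + 1000)]
      s
    })
    structure(list(dyads = dy2[], domains = domains, genes = genes,
                   sites = sites, spec = spec),
              class = "nuc_landscape")
  })
}

#' Simulate replicate expression count tables
#'
#' Active genes receive a shared lognormal mean expression (scaled by
#' exonic length so RPKM, not raw count, is lognormal) and per-replicate
#' negative-binomial counts at the given dispersion (`dispersion = 0`
#' gives Poisson counts). Silent genes are 0 in every replicate. An
#' active gene that draws zero in all replicates is redrawn, so the
#' planted activity partition is identifiable from the counts by
#' construction.
#'
#' @param genes gene table with `gene_id`, `active` and `exon_length`.
#' @param n_replicates replicates per sample (default 2).
#' @param depth expected total read count per replicate (default 5e6).
#' @param dispersion negative-binomial dispersion (default 0.05).
#' @param seed integer seed for the expression substream.
#' @param sdlog sdlog of the lognormal expression level (default 1.5).
#' @return list with `counts` (`gene_id`, `count_1`..), `exon_length`,
#'   `library_sizes`.
#' @export
simulate_expression <- function(genes, n_replicates = 2, depth = 5e6,
                                dispersion = 0.05, seed = 1, sdlog = 1.5) {
  genes <- as.data.table(genes)
  stopifnot(nrow(genes) > 0, depth > 0, n_replicates >= 1, dispersion >= 0)
  if (!"exon_length" %in% names(genes)) genes[, exon_length := 1500]
  with_seed(substream_seed(seed, "expression"), {
    n <- nrow(genes)
    level <- ifelse(genes$active, rlnorm(n, 0, sdlog), 0)
    w <- level * genes$exon_length / 1000
    mu <- if (sum(w) > 0) depth * w / sum(w) else rep(0, n)
    draw_counts <- function(mu_i, n_i) {
      if (dispersion > 0) matrix(rnbinom(n_i * n_replicates, mu = rep(mu_i, n_replicates),
                                         size = 1 / dispersion), nrow = n_i)
      else matrix(rpois(n_i * n_replicates, rep(mu_i, n_replicates)), nrow = n_i)
    }
    cm <- draw_counts(mu, n)
    cm[!genes$active, ] <- 0
    stuck <- which(genes$active & rowSums(cm) == 0)
    while (length(stuck) > 0L) {
      cm[stuck, ] <- draw_counts(mu[stuck], length(stuck))
      stuck <- stuck[rowSums(cm[stuck, , drop = FALSE]) == 0]
    }
    counts <- data.table(gene_id = genes$gene_id)
    for (r in seq_len(n_replicates)) counts[, (sprintf("count_%d", r)) := cm[, r]]
    list(counts = counts[], exon_length = setNames(genes$exon_length, genes$gene_id),
         library_sizes = colSums(cm))
  })
}

#' RPKM table for one replicate of a simulated expression experiment
#'
#' @param sim result of [simulate_expression()].
#' @param replicate replicate index.
#' @return `data.table` with `gene_id` and `rpkm`.
#' @export
expression_rpkm_table <- function(sim, replicate = 1) {
  col <- sprintf("count_%d", replicate)
  stopifnot(col %in% names(sim$counts))
  cnt <- sim$counts[[col]]
  lib <- sum(cnt)
  data.table(gene_id = sim$counts$gene_id,
             rpkm = rpkm_value(cnt, sim$exon_length[sim$counts$gene_id], lib))
}
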