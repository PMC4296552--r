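---
title: "Nucleosome organization analysis with nucorg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleosome organization analysis with nucorg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis model

`nucorg` characterizes nucleosome organization from aligned single-end
MNase-seq reads. The package works entirely in 0-based half-open (BED)
coordinates; the minus-strand TSS is `end - 1`, and these conventions are
applied once, at the I/O layer.

## From reads to dyads

MNase digestion leaves ~147 bp of nucleosome-protected DNA, of which a
fixed-length fragment (49 bp in the data this package targets) is
sequenced from either end. The nucleosome midpoint (dyad) is estimated as
**73 bp downstream of the read's 5' end, in read orientation**:
`start + 73` on the plus strand, `(end - 1) - 73` on the minus strand.
Reading "downstream" in read orientation makes both strands estimate the
same dyad of the particle; interpreting the offset on the reference
strand instead would split the two strands' estimates by roughly a
particle width, which contradicts the mirrored sense/antisense coverage
bands MNase data show around TSSs. Midpoints that fall off the
chromosome end are dropped from the track but kept in the read total, so
normalization still refers to all retained uniquely mapped reads.

## Genome-window occupancy

`window_occupancy()` tiles each chromosome with fixed windows (default
10 kb, optional scan offset) and normalizes midpoint counts to RPKM,

$$\mathrm{RPKM}(w) = \frac{n_w}{(\ell_w/10^3)\,(N/10^6)},$$

with $n_w$ the midpoint count, $\ell_w$ the true window width and $N$
the total retained reads. Terminal partial windows are kept with
width-corrected normalization: dropping them would bias chromosome ends,
while zero-padding would distort the RPKM definition. Between-sample
similarity is quantified with Spearman's rank correlation (robust to the
heavy right tail of occupancy), Pearson's $r$ where a linear comparison
is wanted, and `fold_change_regions()` flags windows whose
pseudocount-stabilized ratio exceeds a threshold (default 2-fold,
pseudocount 1 RPKM so empty windows cannot produce infinite folds) and
merges adjacent flagged windows. Correlation across more than two
samples excludes windows on chromosomes missing from any sample rather
than imputing zeros, which would inflate agreement.

## Anchor-centered profiles

`anchored_profile()` collects midpoints within a flank (default
3,000 bp) of a set of anchors (TSSs or binding-site centers), bins the
signed anchor-oriented distance in 10-bp intervals
(`[10k, 10(k+1))`, no special zero bin), normalizes each bin by the
number of regions represented in it and by total reads per million, and
smooths with a 5-bin centered moving average advancing one bin.
Three choices deserve comment:

* *Regions per bin* counts anchors whose clipped flanking window
  genomically covers the bin's span, not anchors with at least one
  midpoint in the bin. This makes the normalizer independent of
  occupancy, so sparsely covered bins are not inflated.
* Bins covered by no region are **missing**, not zero, and missing bins
  are excluded from their neighbors' smoothing windows.
* At the edges of the profile the smoothing window shrinks symmetrically
  to what fits; no values are fabricated beyond the profiled range.

`tss_heatmap()` keeps the two read strands separate and spreads each
read's full 49-bp footprint over the bp-offset columns it overlaps;
gene strand flips both the offset axis and the sense/antisense layer.

## NDR summaries

`ndr_summary()` reports, from the smoothed profile: the NDR center, the
flanking -1/+1 nucleosome positions (nearest prominent local maxima on
each side), the depletion depth `1 - min/baseline` (baseline = mean of
the outer third of the profile), and whether the anchor itself is
occupied (anchor-bin occupancy above 1.5x baseline, the
single-positioned-nucleosome architecture of silent promoters). Since a
genuinely depleted region is a near-flat valley, the raw argmin would
land anywhere inside it under shot noise; the NDR center is therefore
the center of the *near-minimal plateau* (bins within 5% of the
min-to-baseline range above the minimum), which is stable to within a
bin on simulated promoters.

## Gene activity and TSS-region similarity

A gene is **silent iff its read count is zero** - in every replicate,
when replicates are supplied, since any nonzero evidence contradicts
silence - and active otherwise. RPKM follows the standard definition
and is only recomputed here from supplied count tables; upstream
quantification is out of scope. `tss_window_correlation()` tiles
±2 kb around each TSS of a gene subset with non-overlapping 250-bp
windows in strand-oriented coordinates, normalizes per sample, and
correlates across all gene-by-window cells (Pearson by default). The
scan is non-overlapping because a stated window with no stated step is
a tiling; an overlapping scan is available through the step argument.
For multi-isoform annotations a single deterministic TSS per gene is
kept: the most upstream in gene orientation.

## Binding-site topology

`classify_topology()` operationalizes four qualitative architectures
into an explicit rule table over profile features (every threshold is a
config knob in `topology_rules()`):

| class | rule (in order) |
|---|---|
| PERIODIC_LINKER | `center_z <= -1`, >= 3 near-periodic peaks per side, repeat in [160, 220] bp |
| LINKER | `center_z <= -1`, nearest peaks both sides at 70-130 bp |
| NUCLEOSOMAL | `center_z >= +1`, offset 0 within 30 bp of the nearest peak |
| BORDER | `-1 < center_z`, twin peaks both sides at 40-90 bp |

Anything else is reported unclassifiable rather than forced into a
class. The defaults follow canonical nucleosome geometry: a 147-bp core
puts the particle borders near ±73 bp, adjacent linker nucleosomes near
±(95-100) bp, and mammalian repeat lengths fall in the 160-220 bp band.

Two numerical details matter:

* `center_z` standardizes the central smoothed occupancy against the
  800-1,000 bp flank-tail baseline, with the baseline sd **floored at
  10% of the baseline mean**. An unfloored sd converges to pure shot
  noise on any flat baseline, which makes the statistic
  depth-independently noisy (approximately unit-normal) and would
  misclassify genuinely baseline-level centers about one time in six.
  The floor turns the criterion into "at least one standardized unit,
  and at least 10%, away from baseline".
* Only *prominent* local maxima (exceeding baseline by one standardized
  unit) count as nucleosome peaks. Smoothed shot noise produces local
  maxima every 100-200 bp, which would otherwise satisfy the
  periodicity run-counting by accident. The small central bump
  tolerated in the periodic-linker class is read off the unfiltered
  maxima, since it need not clear baseline.

Peak detection requires a bin strictly greater than its two neighbors
on each side, so exact plateaus yield no peak and calls are
deterministic. Periodicity is the lag of the first non-zero-lag local
maximum of the autocorrelation of the mean-subtracted smoothed profile
(computed over the full series including lag 0, so a monotone decay
cannot fake a lag-1 peak); its strength is that autocorrelation value
clipped to [0, 1].

# The synthetic-data generator

`simulate_landscape()` builds a weighted catalogue of dyad positions;
`simulate_reads()` inverts the midpoint rule exactly (draw a dyad by
weight, jitter with `Normal(0, 20 bp)`, pick a strand fairly, place the
49-bp read so its midpoint is the jittered dyad; off-chromosome reads
are redrawn). Sampling is strand-symmetric because the library is
unstranded nucleosomal DNA. The geometries encode:

* **active promoters**: -1 dyad at TSS-180, zero dyad weight over
  [TSS-130, TSS+10] (NDR centered at TSS-60), and five phased dyads
  from TSS+100 at the 190-bp repeat;
* **silent promoters**: a single positioned dyad on the TSS;
* **binding sites**, one geometry per topology class: linker (dyads at
  ±95 bp, local background suppressed), nucleosomal (dyad on the
  center), periodic linker (four phased dyads per side plus a small
  central dyad, weight 0.01), border (one dyad at ±73 bp, fair coin
  per site);
* **background**: a uniform grid of weak dyads (weight 0.1, spacing one
  repeat length) for unpositioned nucleosomes.

On top of this, every 10-kb domain carries a lognormal weight
multiplier (sdlog 0.5). Real MNase coverage varies smoothly at domain
scale (accessibility, compaction, copy number); without this component
all windows away from genes would be statistically exchangeable and
window-rank correlations between any two samples - including perfect
replicates - would be dominated by shot noise rather than biology.
The same component gives `perturb_landscape()` its meaning: a chosen
fraction of domains receives a fresh multiplier and fresh generic
positioned dyads, so at fraction 1 the window totals are independent of
the original while at fraction 0.1 the landscape is
"related but distinct". Genes and sites whose footprint intersects a
perturbed domain are flagged, because their planted labels no longer
describe the local geometry.

`simulate_expression()` gives active genes a shared lognormal
expression level (sdlog 1.5, scaled by exonic length) and per-replicate
negative-binomial counts (dispersion 0.05 by default; 0 gives Poisson);
silent genes are zero everywhere. An active gene that samples zero in
all replicates is redrawn, so the planted activity partition is always
identifiable from the table - "active" here means *detectably*
expressed. All randomness flows from one seed through named substreams
(landscape, reads, perturb, expression), so fixtures are
bit-reproducible and regenerating one stage does not disturb another.

## What the generator does not emulate

Sequence content (and hence MNase sequence preference and GC bias),
paired-end fragments, fragment-length variation, duplicate-read
structure, mappability gaps, and copy-number variation are all absent.
Positioned nucleosomes are planted at fixed offsets with Gaussian fuzz,
so the generator cannot probe rotational (10-bp helical) positioning.
Tests passing on this generator therefore validate the *computational
contracts* - binning, normalization, correlation, classification logic
and their inverses - not robustness to the full messiness of real
libraries.

# Problem sizes and numerical choices in the test suite

The suite exercises the pipeline at desk scale, chosen so the full run
stays in the low minutes: 10-Mb two-chromosome genomes with 400 genes
and 100 sites per class at 5x10^5 reads for the genome-window
correlation checks; 13-Mb-per-chromosome genomes with 2,000 sites per
class at 10^6 reads, 50 seeds per class, for topology recovery; 10,000
genes at depth 5x10^6 for the expression twin; and brute-force oracle
comparisons at up to 300 anchors x 10^4 midpoints. Deduplication of
reads is available but off by default (the source protocol does not
state it), and no chromosome filtering is applied unless an
include-list is supplied.

# Known limitations

* The four-class topology boundary between NUCLEOSOMAL and BORDER
  (center-to-peak tolerance 30 bp; twin-peak window 40-90 bp) is an
  operational choice; profiles near the boundary deserve a sensitivity
  scan over `topology_rules()`.
* `ndr_summary()` assumes a single depleted region within ±300 bp of
  the anchor; bidirectional promoters with two NDRs report the plateau
  of the deeper one.
* The heatmap accumulates per-gene footprints with an explicit loop and
  is intended for gene panels (10^2-10^3 rows), not genome-wide runs.
* Expression replicates share one lognormal level per gene; there is no
  gene-length bias model or between-sample library-composition shift,
  so RPKM comparisons across simulated samples are optimistic relative
  to real RNA-seq.
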