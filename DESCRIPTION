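Package: nucorg
Title: Nucleosome Organization Analysis for MNase-Seq Read Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to characterize nucleosome organization from aligned
    MNase-seq reads: read-midpoint (dyad) estimation with the 73-bp offset
    rule, genome-wide fixed-window occupancy with RPKM normalization and
    between-sample Spearman/Pearson correlation, fold-change region
    detection, anchor-centered nucleosome distribution profiles around
    transcription start sites and transcription-factor binding sites,
    nucleosome-depleted-region summaries, activity-aware TSS architecture
    comparison, and a rule-based four-class topology of binding-site
    nucleosome architecture (linker, nucleosomal, periodic linker, border).
    A fully parameterized synthetic landscape and read simulator generates
    phased nucleosome arrays, promoter geometries, binding-site geometries
    and replicate expression tables, so the whole pipeline is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
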