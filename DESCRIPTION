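Package: telscope
Title: Transposable Element Landscapes and eccDNA Quantitation from Pooled
    Short-Read Sequencing
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls non-reference transposable element (TE) insertions from
    paired-end whole-genome sequencing using two-sided junction evidence
    (split reads and discordant pairs) with a minimum of four supporting
    reads, scores each insertion with a Coverage Ratio that proxies
    penetrance in pooled samples, and benchmarks false positives with
    immobile gene elements (IGEs). Provides depth-matched comparison of
    young and aged TE landscapes via seeded downsampling and bootstrap
    resampling, unique/common insertion partitioning, per-family
    composition and Wilcoxon tests with exact small-sample null
    distributions. Quantifies TE-derived extrachromosomal circular DNA
    (eccDNA) with circular-junction read detection against a doubled
    consensus index and plasmid spike-in normalization, and includes
    droplet digital PCR Poisson copy-number and qPCR delta-delta-Ct
    calculators. A seeded synthetic-data generator produces reference
    bundles, pooled haplotype samples, WGS read pairs and eccDNA-enriched
    libraries with truth tables so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    rtracklayer
Config/testthat/edition: 3
biocViews: Sequencing, Alignment, Transposon, Coverage, Software
RoxygenNote: 7.3.3
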