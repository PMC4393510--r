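Package: sweepsv
Title: Population-Scale Structural Variant Discovery from Discordant Read Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint multi-sample structural variant (SV) discovery from
    paired-end alignments. Extracts discordant read pairs from each sample,
    segregates them by chromosome pair and alignment orientation, sorts each
    partition under a fixed memory budget with spill runs and a k-way merge,
    and sweeps the sorted partitions with a greedy clustering algorithm that
    respects each library's own fragment-size tolerance (median plus a
    multiple of the median absolute deviation). Calls are reported in BEDPE
    with per-sample read-pair support, enabling cohort analytics:
    germline/private classification of breakpoints, somatic false discovery
    rate estimation from matched tumor-normal pairs, the dependence of that
    FDR on cohort size, and hierarchical clustering of samples by shared
    germline variants. A synthetic-cohort simulator with planted deletions,
    tandem duplications, inversions and translocations, plus a breakpoint
    probe-interval ROC evaluator against a truth set, make every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vegan,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
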