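Package: mcseedr
Title: Differential Methylation Analysis for Methylation-Sensitive
    Restriction Enzyme (MCSeEd) Read-Count Data
Version: 0.1.0
Authors@R:
    person("mcseedr", "maintainers", email = "mcseedr@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for reduced-representation DNA methylation
    profiling based on methylation-sensitive restriction enzymes (MCSeEd-style
    data) in the CG, CHG, CHH and 6mA contexts. Starting from per-locus,
    per-library read-count tables, the package normalizes and filters loci,
    derives per-site relative methylation levels, calls differentially
    methylated positions (DMPs) between two genotype groups with an
    overdispersion-aware binomial likelihood-ratio test, clusters directional
    DMPs into differentially methylated regions (DMRs) with window-length
    optimization, annotates DMRs against extended gene bodies (2 kb upstream,
    gene body, 2 kb downstream), computes metagene DMP profiles, builds
    shared/specific methylated gene sets across genotype comparisons, and
    intersects differentially methylated genes with a differential-expression
    table. A negative-binomial synthetic-data generator with planted DMPs and
    DMRs supports calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
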