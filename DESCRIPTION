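Package: interflow
Title: Interploidy Introgression Scans with D, f4-Ratio and fdM Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detection and characterization of interploidy introgression
    between diploid donors and an allopolyploid receptor from cohort VCFs.
    Reads per-species variant calls, applies standard site filters, maps
    the tetraploid subgenome onto the diploid coordinate frame through
    one-to-one syntenic blocks, and computes Patterson's D, the f4-ratio
    admixture proportion with block-jackknife standard errors, and
    sliding-window fd/fdM scans under the four-population topology
    ([{P1,P2},P3],O). Windowed fdM scores are converted into putative
    introgressed regions calibrated by the f4-ratio, which are contrasted
    against nucleotide diversity, Dxy, Weir-Cockerham Fst and external
    recombination or selective-sweep tracks, with Fisher-exact and
    circular-permutation overlap enrichment. A tract-based synthetic
    allopolyploid cohort generator with emitted ground truth supports
    calibration and validation of the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
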