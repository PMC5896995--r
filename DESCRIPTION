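Package: panelval
Title: Validation Analytics for Targeted Hereditary-Cancer Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-control and validation analytics for hybridization-capture
    gene panels used in germline cancer-predisposition testing. Implements
    coverage-uniformity metrics (fractions of target bases at depth thresholds,
    per-gene coverage classes, low-covered region discovery with GC content,
    off-target read fraction), a fragmentation-randomness statistic based on
    terminal nucleotide and dinucleotide composition of read ends, variant
    call-set normalization and replicate concordance analysis, base-level
    truth-set benchmarking (sensitivity, specificity, accuracy), and cohort
    read-depth copy-number scoring with log2 bin ratios, group median
    normalization, threshold calling and non-informative bin masking. A
    synthetic cohort simulator generates negative-binomial depth matrices with
    GC bias, CNV spike-ins, replicate call sets with dropout, and biased or
    uniform fragment cut sites, so every analysis is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
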