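Package: poolscreen
Title: Analysis of Pooled CRISPR Knockout Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end analysis of pooled genome-wide CRISPR/Cas9 knockout
    screens read out by sgRNA sequencing, as used to map drug-resistance
    genes in cancer cell lines and xenografts. Provides sgRNA library
    handling, spacer-based read quantification from FASTQ, median-of-ratios
    normalization, a negative-binomial Wald test for per-guide differential
    abundance, gene-level aggregation by Fisher's method with
    Benjamini-Hochberg correction, threshold/top-N hit calling with
    cross-condition intersection and trend-group detection, screen-level
    quality control, and a fully seeded screen simulator (low-MOI infection,
    serial drug selection, engraftment and metastasis bottlenecks,
    negative-binomial sequencing noise) with complete ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
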