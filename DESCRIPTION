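Package: crisprcolony
Title: Spacer Acquisition and Phage Escape Analysis for CRISPR-Immunized Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for type II CRISPR-Cas adaptation in
    structured bacterial communities. Extracts ordered spacer arrays and
    clonality barcodes from CRISPR-locus amplicon reads by fuzzy direct
    repeat detection, maps spacers to protospacers on a phage genome with
    PAM validation, computes first-to-second spacer target-distance
    histograms and the local (primed) acquisition enrichment statistic,
    classifies mono- versus multi-spacer colonies from read-class
    fractions, quantifies phage escape (titers, efficiency of plaquing,
    detection limits, escaper spike-in arithmetic, seed/PAM escape-mutation
    typing), and scores host-phage time-shift co-evolution assays. A
    synthetic-data generator produces amplicon reads, phage genomes,
    escaper populations, plaque-count tables and resistance matrices with
    known ground truth so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
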