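Package: longapa
Title: Differential Alternative Polyadenylation Analysis from Long-Read
    RNA-seq 3' Ends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls polyadenylation sites (PASs) from the 3'-terminal
    positions of long-read RNA-seq alignments, quantifies per-sample PAS
    usage (PAU), flags likely internal-priming artifacts from genomic
    A-content, and tests alternative polyadenylation between two
    conditions both per PAS (negative-binomial GLM likelihood-ratio test
    on this-site versus rest-of-gene counts) and per gene (signed
    two-sample Kolmogorov-Smirnov shift of transcription-oriented 3'-end
    distributions, positive values indicating 3'UTR lengthening).
    Includes nucleotide-composition and poly(A)-signal motif profiling
    around cleavage sites, a fully self-contained synthetic-data
    generator with known ground truth, and per-gene visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
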