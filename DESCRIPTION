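Package: termseqr
Title: Reproducible 3' RNA End Detection and Intrinsic Terminator
    Annotation from Term-seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies reproducible, stable 3' RNA ends (points of
    observed termini, POTs) in bacterial Term-seq experiments from
    strand-specific genomic coverage of read 5' ends. Candidate peaks are
    called per replicate with relaxed settings, trimmed to the most
    probable 3' end, and filtered across replicate pairs with an
    irreproducible discovery rate (IDR) copula mixture model fitted on
    peak prominences. Matched RNA-seq coverage yields a termination
    efficiency for each site. An annotation step merges POTs across
    samples, attaches gene context from GFF3/GTF and custom BED feature
    sets, and calls intrinsic (Rho-independent) terminators upstream of
    each POT via two protocols: a canonical genome-wide hairpin scan and
    a permissive local scan verified by hairpin free energy. A seeded
    synthetic-data generator plants terminators with known truth so the
    whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
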