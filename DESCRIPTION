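Package: allophase
Title: Reference-Free Subgenome Phasing and Homoeolog Expression Bias
    Analysis for Allopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phases an allopolyploid genome into two pseudo-parental
    subgenomes without progenitor references, using the GC-content ratio
    (dGC, dGC3) of homoeologous gene pairs along homoeologous chromosome
    pairs and codon-usage principal component analysis, and classifies
    homoeolog expression bias from RPKM time courses (two-fold-or-greater
    rule with silencing calls), including fractionation summaries,
    pathway enrichment, and IUPAC promoter-motif scanning.  Ships a
    synthetic allopolyploid genome and expression simulator with truth
    labels so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
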