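Package: tascan
Title: Prediction of Toxin-Antitoxin Loci and Their Mobile Genetic Element
    Associations in Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts bacterial and archaeal toxin-antitoxin (TA) loci of
    types I to VIII from annotated replicons by homology against
    experimentally validated reference toxins and antitoxins, using a
    combined identity-coverage score (H-value) filter, protein length
    filters, and type-specific strand and intergenic-distance rules.
    Computes associations between predicted TA loci and mobile genetic
    elements (prophages, genomic islands, ICEs, integrons, IS elements and
    plasmids), MinHash/Mash sequence similarity networks among those
    elements, and summary statistics of the resulting TA-MGE network.
    Includes a seeded synthetic-genome generator that plants TA loci and
    MGEs with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
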