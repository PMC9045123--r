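Package: exprdof
Title: Degree of Freedom of Genome-Wide Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the degree of freedom (DOF) of genome-wide gene
    expression -- the minimum number of state variables needed to represent
    transcriptional changes in a linear state-space model -- by gene-split
    cross-validation of the singular value decomposition with an integer
    golden-section search. Maps promoter 8-mer motifs and Gene Ontology
    terms onto the state variables by least squares, computes the Shannon
    information capacity of extreme-weight motif selections and of
    individual promoters, and builds a universal transcriptional
    coordinate system onto which any expression-change vector can be
    projected. Includes a synthetic-data generator (low-rank-plus-noise
    expression matrices, promoter sequences with planted motifs, coupled
    GO annotations) so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
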