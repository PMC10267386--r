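Package: casagm
Title: Lossless Compression of Sparse Genomic Mutation Matrices by
    Bandwidth-Reducing Reordering
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Structural lossless compression for sparse sample-by-gene
    mutation matrices (SNV counts, signed CNV calls).  Implements the
    coordinate (COO), compressed sparse column (CSC) and compressed sparse
    row (CSR) encodings together with a reordering pipeline that presorts
    non-zeros row-major, renumbers rows and columns with the reverse
    Cuthill-McKee algorithm on the matrix's bipartite graph, and stores the
    result in CSR form with the permutations needed for exact inversion.
    Ships a deterministic binary container format, a benchmarking harness
    (compression/decompression time and throughput, compressed memory,
    compression ratio, paired t-tests, tie-aware Spearman correlation) and
    seeded generators for SNV-like and CNV-like synthetic matrices.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
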