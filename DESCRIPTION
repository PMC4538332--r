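Package: tilesw
Title: Tiled Smith-Waterman Protein Database Search with Explicit Memory
    Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Smith-Waterman local alignment search of a protein database
    with affine gap penalties (Gotoh recurrences). Implements two
    score-identical engines: a naive full-matrix reference and a tiled
    engine that processes the dynamic-programming matrix in K x P tiles in
    column-major order, carrying row boundaries through a register model
    and column boundaries through an explicit shared-memory column buffer,
    the memory discipline used by GPU database-search kernels for short
    query sequences. Includes an NCBI-format substitution-matrix reader
    with bundled BLOSUM62/BLOSUM50, a packed query profile, ascending
    length sort with 32-lane interleaved database layout, a shared-memory
    budget model that dispatches queries between the tiled and reference
    paths, a warp load-balance cost simulator, a seeded synthetic protein
    corpus generator, and a command-line search tool.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
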