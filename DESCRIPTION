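Package: slimscan
Title: Short Linear Motif Discovery in Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Finds candidate short linear motifs (SLiMs/ELMs) in amino-acid
    sequences using a local copy of a curated motif-class database. Reports
    both direct regular-expression matches of every motif class against the
    query (including overlapping sites) and homology-based matches
    transferred from curated motif instances on database proteins detected
    by Smith-Waterman local alignment with affine gap penalties, with
    alignment-column projection of instance coordinates onto the query.
    Includes a synthetic database generator with implanted motif
    occurrences for fully offline testing, and a command-line interface
    with TSV/JSON output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    parallel,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
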