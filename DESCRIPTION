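Package: impliedalign
Title: Implied Alignment of Sequences on a Binary Tree
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates the multiple sequence alignment implied by a rooted
    strictly binary tree whose leaves are labeled with unaligned sequences.
    A commutative, tagged pairwise alignment operator over an extended
    alphabet decorates every node with a "preliminary context" in a
    post-order pass; a subsequent pre-order "sliding zip" pass derives
    equal-length final alignments in time linear in the alignment length per
    node, O(k*n^2) worst case and best case Omega(k*n) for n leaves and
    maximum sequence length k. Includes transition-cost-matrix input,
    IUPAC-aware FASTA and Newick handling, a pathological dataset generator
    exercising the best- and worst-case regimes, a timing harness for the
    pre-order phase, and a log2-log2 ordinary least squares model of runtime
    scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
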