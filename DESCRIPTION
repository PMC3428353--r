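Package: obpscaffold
Title: Cysteine-Scaffold Evolution of Insect Odorant-Binding Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the evolution of the six-cysteine scaffold of
    insect odorant-binding proteins (OBPs). Reads protein multiple sequence
    alignments, locates the canonical cysteine columns, builds per-sequence
    cysteine presence/absence profiles and classifies sequences into the
    classic, minus-C and plus-C subfamilies; infers a minimum set of
    cysteine-loss events on a gene tree by Dollo (or Fitch) parsimony and
    tabulates them; tests whether paired losses preferentially hit
    disulphide-bond partners with an exact binomial tail test; detects and
    delimits tandem double-domain OBP genes from self-similarity dotplots,
    splice sites and cysteine profiles; and simulates OBP families with known
    ground truth (tree, scaffold-constrained sequences, branch-placed loss
    events with partner-dependent rates, and tandem fusions) so that every
    stage of the pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
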