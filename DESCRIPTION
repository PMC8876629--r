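Package: pkscan
Title: H-Type RNA Pseudoknot Prediction by Context-Free Grammar Parsing
Version: 1.0.0
Authors@R:
    person("pkscan", "Developers", email = "pkscan@example.org",
           role = c("aut", "cre"))
Description: Detects H-type pseudoknots in RNA sequences with a syntactic
    pattern-recognition approach. Candidate core stems (two crossing
    Watson-Crick base pairs) are enumerated either by parsing all sequence
    windows with an ambiguous context-free grammar under an Earley chart
    parser, or by a direct brute-force scan; the two engines are equivalent
    by construction. Candidates are decorated with contiguous stacked base
    pairs, scored with a pseudoknot free-energy heuristic, and the optimal
    structure is selected by maximum pairing then minimum energy, emitted in
    extended dot-bracket notation. Includes an evaluation toolkit (per-base
    confusion counts, PPV/recall/F1/MCC, core-stem matching with slippage),
    FASTA and CSV input/output, a command-line interface, and a seeded
    generator of synthetic sequences with planted pseudoknots.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    optparse,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
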