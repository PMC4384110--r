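Package: foldgrammar
Title: Rule-Based Recognition of Seven-Strand Beta-Sandwich Folds from Sequence
Version: 0.1.0
Authors@R:
    person("foldgrammar", "developers", email = "foldgrammar@example.org",
           role = c("aut", "cre"))
Description: Implements a non-probabilistic sequence "grammar" for a family of
    sandwich-like beta proteins built from seven six-residue strands packed
    into two beta sheets. The grammar is a set of count-constraint rules over
    residue classes at hydrophobic-face, hydrophilic-face and whole-strand
    positions, together with loop admissibility rules. A backtracking search
    decides whether any placement of the seven strands and six loops onto a
    query sequence satisfies every rule. Also provides supersecondary-structure
    analysis (strandons, sheet arrangement constraints, the interlock
    invariant), a generator of labelled synthetic sequences, and a
    sensitivity/specificity rule-ablation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
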