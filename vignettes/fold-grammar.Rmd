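---
title: "A count-constraint grammar for seven-strand beta-sandwich folds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A count-constraint grammar for seven-strand beta-sandwich folds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldgrammar)
```

## The model

`foldgrammar` decides, from sequence alone, whether a protein can adopt a
particular sandwich-like beta fold: seven sequence-consecutive strands packed
into two beta sheets with a characteristic *interlock* arrangement of strands
2, 3, 5 and 6. The method is deliberately non-probabilistic. Instead of a
profile or an alignment, the fold is described by a *grammar*: a set of
count-constraint rules stating, for each residue class and each part of the
strand skeleton, how many residues of that class may (or must) occur there.
A query sequence is accepted if and only if **some** placement of the
skeleton onto the sequence satisfies **every** rule.

The skeleton is rigid in a few respects and flexible in others:

* seven strands, each modelled as a fixed 6-residue window;
* six connecting loops, each 3–16 residues, jointly 30–60 residues;
* optional N-/C-terminal tails, unconstrained by default.

Within a strand, side chains alternate between the sheet interior and the
solvent-exposed surface. The package follows the structure-diagram
convention that odd strand positions (1, 3, 5) face the hydrophobic core and
even positions (2, 4, 6) the surface; the accompanying prose description
inverts this parity, so the convention is configurable
(`fold_geometry(parity = "even-in")`) but a single global choice is applied
to all strands, keeping decisions deterministic.

### The rule set

The default grammar has 23 strand rules in three groups, one per row of the
published rule tables, plus the loop rules:

* **T1** (9 rules): residue content at *hydrophobic-face* positions —
  e.g. strands 2 and 3 must have all three core-facing positions
  hydrophobic; Gly is banned outright from core-facing positions; charged
  residues are banned from the core face of strands 2 and 3.
* **T2** (5 rules): residue content at *surface-face* positions — at least
  one hydrophilic residue per strand; Pro and Gly tightly capped.
* **T3** (9 rules): residue content at *any* strand position — whole-window
  caps on Ala, aromatics, charged and strand-disrupting residues.

Each rule bounds a count at up to three scopes: per strand, over the four
interlock strands (2, 3, 5, 6), over the three non-interlock strands
(1, 4, 7), and over all strands. Loops are admitted by the *loop-favorable
function*: Gly and Pro weigh 2, Asp/Asn/His/Ser/Thr weigh 1, everything else
0, and a fragment's weight sum must reach twice its length. Each loop must
also contain strongly hydrophobic residues (Trp, Ile, Phe, Leu, Val, Met) in
strict minority, and at most 12 such residues may occur across all loops.

```{r}
rs <- default_ruleset()
rs
rs$rules[["t1r1"]]$interlock   # hydrophobic-face interlock total in [9, 12]
```

### Errata decisions

The published tables and their accompanying prose disagree in a few places.
This package treats the tables as authoritative (they are internally
consistent; the prose reads as commentary) and records each decision in the
rule's provenance string:

* Cys at hydrophobic-face positions: grand total at most 2 (prose says 3);
* Gly at surface-face positions: grand total 2 — the printed grand total of
  1 is below the printed interlock subtotal of 2, which is impossible;
* the charged-residue rule's "non-interlock strands 1, 3 and 6" is read as
  strands 1, 4, 7, the defined non-interlock set;
* "no more than five of the 21 hydrophobic positions non-hydrophobic"
  implies a minimum of 16 hydrophobic residues, conflicting with the printed
  all-strands interval [13, 17]; the table wins;
* the loop prose says "all five loops"; the skeleton has six inter-strand
  loops and the 12-residue cap is applied to all six;
* single-sided table cells printed as "n≤" are read as "at most n" (the
  typographic inversion is evident from the surrounding prose).

## The search

`fold_search()` places strands left to right. Because a strand window is
fully determined the moment it is placed, *all* per-strand bounds are
checked eagerly, as are the loop rules for each completed loop; these
filters are exact and cannot change the decision. Aggregate bounds
(interlock / non-interlock / all-strands totals) are checked two ways:
running totals against maxima (exact, since counts only grow) and an
admissible feasibility bound against minima — a subtree is abandoned only
when even the maximum possible remaining contribution cannot reach the
required minimum. This pruning provably never discards a satisfying
completion; `search_params(prune = FALSE)` disables it for debugging, and
the test suite asserts decisions are identical either way.

Enumeration order is fully lexicographic (strand-1 start ascending, then
loop lengths ascending), so the reported witness is the canonically first
satisfying assignment and is reproducible across platforms. The kernel is
implemented in C++ (via Rcpp); an independent pure-R exhaustive enumerator,
`enumerate_satisfying()`, walks the same candidate space with naive
per-window recounting and confirms every leaf with the pure evaluator
`check_assignment()`. The two routes are compared on hundreds of seeded
sequences in the acceptance tests.

A consequence of taking the loop-favorability threshold literally (weight
sum at least twice the loop length, with a maximum weight of 2) is that
admissible loops must consist entirely of Gly/Pro. This looks severe, and
the threshold coefficient is configurable
(`loop_rules(favorability_coefficient = 0.5)` admits realistic loops), but
the published definition is unambiguous about the factor of two, so 2 stays
the default rather than silently substituting a guess.

## Supersecondary topology

Independently of sequence classification, `sss_topology()` describes a
protein abstractly: strands numbered in sequence order, ordered sheet
compositions, and H-bonded neighbour pairs. No coordinates are involved.

* `partition_strandons()` groups maximal runs of consecutive, pairwise
  H-bonded strands ("strandons").
* `check_arrangement()` tests two empirical constraints: consecutive but
  non-H-bonded strands may not share a sheet, and some consecutive pair
  (cyclically, so strand 7 and strand 1 count) must occupy the left edges of
  the two sheets, likewise the right edges. Real structures obey these in
  roughly nine cases out of ten, so violations are *reported*, never used to
  hard-fail classification.
* `find_interlocks()` detects the sandwich invariant: quadruples
  (i, i+1, j, j+1) with i paired to j in one sheet and i+1 to j+1 in the
  other. "Edge" and "left/right" follow the order of the sheet lists as
  given; no absolute handedness is defined.

```{r}
topo <- canonical_sandwich_topology()
partition_strandons(topo)
find_interlocks(topo)
```

## Synthetic data: what it emulates and what it does not

The evaluation experiments of the original study used a curated structure
database that cannot be bundled or downloaded here, so the package ships a
generator of labelled sequences instead.

**Positives** are built constructively. Raw rejection sampling is hopeless:
the acceptance region of the full grammar is an astronomically small
fraction of sequence space. Starting from a hand-designed 72-residue
template (`worked_positive()`), each strand residue is swapped uniformly
within its *interchange set* — residues with identical membership in every
residue class the rules consult (for strand positions: \{V, L, I, M\},
\{F, W\}, \{Q, S, T\}, \{K, R, H\}, \{D, E\}; loops draw from \{G, P\}).
Such swaps provably leave every rule count unchanged, so validity is
inherited from the template; the generator still verifies each sequence
with `check_assignment()` before release. Default loop lengths are 5
(total 30, the minimum allowed) and tails default to 0.

**Targeted negatives** defeat one rule group for *every* candidate
placement: below-minimum length (GEOMETRY), Gly at every third position
(T1: every window puts a Gly on the core face), no hydrophilic residues
anywhere (T2), charged residues at alternating positions (T3: every window
carries three charged residues, exceeding the strand-2 cap), or an alphabet
with zero loop-favorability weight (LOOPS). Rejection under the targeted
group alone is verified at generation time.

**Random background** sequences are i.i.d. draws, uniform or from a
supplied composition.

What a green test therefore establishes: the search is complete and sound
with respect to the grammar, the generator's labels are correct, and the
ablation machinery reproduces the *qualitative* structure of the published
experiment (dropping the face-specific rules floods the classifier with
false positives; relaxing the strand-2/3 hydrophobic requirement rejects
every default positive). What it does not establish: the published absolute
sensitivity (~90%) and specificity (~99%) on real proteins — synthetic
positives are far more homogeneous than the 144 real target structures, and
random strings are not real "other" proteins. Those numbers require the
external structure database and are explicitly out of scope.

## Numerical and design choices

* **Coordinates** are 0-based half-open internally; every printed report is
  1-based inclusive.
* **Bound semantics**: absent bounds are `[0, Inf]`; an exact table cell is
  `[v, v]`.
* **Non-standard letters** (X, B, Z, U, ...) belong to no residue class, so
  they can only ever hurt minimum-count rules; a warning is emitted, and
  `search_params(strict_alphabet = TRUE)` turns them into errors.
* **Ties** in `fold_explain()` (several assignments with equally few
  violated bounds) resolve to the canonically first assignment.
* **Degenerate input**: sequences shorter than the 72-residue minimum span
  are rejected without search; empty FASTA files yield an empty report with
  a warning.
* **Per-strand parity search** (letting each strand choose its own face
  parity) is mentioned as a possible extension; it is not implemented —
  only the global parity flag is — because a per-strand choice would
  multiply the search space 128-fold for a convention the source material
  applies globally.
* The total-loop-length range 30–60 is stated descriptively for real
  structures; it is enforced by default and configurable
  (`fold_geometry(enforce_loop_total = FALSE)`).
* `evaluate_classifier()` reports rates to three decimals alongside raw
  counts, and `NA` (never silent 0/0) for undefined rates.

## Known limitations

* The grammar recognizes one specific seven-strand sandwich arrangement;
  other strand counts or sheet orders need their own rule tables.
* With the literal loop threshold, real loops virtually never qualify, so
  on natural sequences the default grammar is effectively a strand-register
  filter gated by Gly/Pro-rich loops; lower the coefficient for realistic
  scans, at the cost of leaving the published definition.
* `fold_explain()` scans the whole candidate space without filters; for
  sequences much beyond ~120 residues this is noticeably slower than
  classification.
* The topology checker trusts its input description; deriving topology from
  coordinates (DSSP-style) is out of scope.
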