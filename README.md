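# foldgrammar

Rule-based recognition of seven-strand beta-sandwich folds from amino-acid
sequence.

## The problem

A large family of beta proteins folds into a *sandwich*: two packed beta
sheets built from seven sequence-consecutive strands, with strands 2, 3, 5
and 6 forming an *interlock* — the structural invariant of the fold
(strand *i* pairs with strand *j* in one sheet while *i*+1 pairs with *j*+1
in the other). Members of this family can share almost no sequence identity,
so alignment- and profile-based detection struggles. `foldgrammar`
implements an alternative: a non-probabilistic sequence **grammar**. The
fold is described by count-constraint rules over residue classes —
how many hydrophobic residues must sit at core-facing strand positions, how
many charged residues are tolerated where, which residues loops favour — and
a query sequence is accepted iff **some** placement of the
seven-strand/six-loop skeleton satisfies **every** rule:

* 7 strands × 6 positions; odd positions face the hydrophobic core, even
  positions the surface (configurable parity);
* per-loop lengths in [3, 16], total loop length in [30, 60], free tails;
* 23 strand rules (9 hydrophobic-face, 5 hydrophilic-face, 9 any-position),
  each bounding a class count per strand and over the interlock /
  non-interlock / all-strands scopes, e.g. the hydrophobic-face totals must
  lie in [9, 12] (interlock), [4, 6] (non-interlock), [13, 17] (all);
* loop admissibility via the *loop-favorable function* (Gly/Pro = 2,
  Asp/Asn/His/Ser/Thr = 1, others 0; sum ≥ 2 × loop length), a per-loop
  strong-hydrophobic minority rule and a 12-residue cap across loops.

Acceptance is decided by a canonical-order backtracking search (C++ kernel,
exact eager filters, admissible aggregate pruning), checked against an
independent exhaustive enumerator. The package also provides
supersecondary-topology analysis (strandons, sheet-arrangement constraints,
interlock detection), a generator of labelled synthetic benchmarks, and a
sensitivity/specificity rule-ablation harness.

## Worked example

```r
library(foldgrammar)

wp <- worked_positive()     # a 72-residue sequence designed to satisfy every rule
fold_search(wp$sequence)
#> fold_decision: ACCEPTED, witness strand starts (1-based) 1,12,23,34,45,56,67

fold_search(strrep("G", 80))$accepted   # poly-Gly cannot host the fold
#> [1] FALSE

# why was a mutant rejected? (Pro introduced into interlock strand 2)
mut <- paste0(substr(wp$sequence, 1, 13), "P", substr(wp$sequence, 15, 72))
fold_explain(mut)
#> fold_decision: REJECTED
#>   closest assignment misses 4 bound(s): rules t1r1, t1r7, t3r7

count_feature(wp$sequence, wp$assignment, "HYDROPHOBIC", "hydrophobic_positions")$all
#> [1] 16     # within the required [13, 17]

partition_strandons(canonical_sandwich_topology())
#> [[1]] 1 2   [[2]] 3   [[3]] 4 5   [[4]] 6 7
find_interlocks(canonical_sandwich_topology())
#>      i i1 j j1
#> [1,] 2  3 5  6
```

The witness starts `1,12,23,34,45,56,67` are the seven 6-residue strand
windows separated by five-residue loops; `t1r7`/`t3r7` are the
Pro-in-interlock-strand rules that doom the mutant's best placement.

## Command line

```sh
inst/bin/foldgrammar classify queries.fasta --format tsv
inst/bin/foldgrammar explain  queries.fasta
inst/bin/foldgrammar simulate --n-pos 10 --n-neg 2 --n-random 10 \
                     --seed 7 --out-prefix bench
inst/bin/foldgrammar evaluate bench.fasta bench_truth.tsv
inst/bin/foldgrammar ablate   bench.fasta bench_truth.tsv
inst/bin/foldgrammar topology check topo.json
inst/bin/foldgrammar dump-rules --out rules.json
```

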