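# Naive, independent oracles used to cross-check the production paths.

# per-residue scan counting: deliberately dumb double loop
oracle_count <- function(sequence, starts, members, face,
                         geometry = fold_geometry()) {
  res <- strsplit(toupper(sequence), "")[[1]]
  offsets <- switch(face,
                    hydrophobic_positions = geometry$hydrophobic_positions,
                    hydrophilic_positions = geometry$hydrophilic_positions,
                    any_position = 1:6)
  per <- integer(7)
  for (k in 1:7) {
    for (o in offsets) {
      if (res[starts[k] + o] %in% members) per[k] <- per[k] + 1L
    }
  }
  list(per_strand = per,
       interlock = sum(per[c(2, 3, 5, 6)]),
       non_interlock = sum(per[c(1, 4, 7)]),
       all = sum(per))
}

# full-enumeration decision oracle: every candidate through check_assignment
oracle_decide <- function(sequence, ruleset = default_ruleset()) {
  L <- nchar(sequence)
  cand <- enumerate_candidate_assignments(L, ruleset$geometry)
  for (i in seq_len(nrow(cand))) {
    a <- fold_assignment(cand[i, ], L, ruleset$geometry)
    if (check_assignment(sequence, a, ruleset)$satisfied) {
      return(list(accepted = TRUE, witness = a))
    }
  }
  list(accepted = FALSE, witness = NULL)
}

# random valid two-sheet topology over n strands (for property tests)
random_topology <- function(n, seed) {
  set.seed(seed)
  repeat {
    perm <- sample(n)
    cut <- sample(seq_len(n - 1L), 1L)
    sheets <- list(perm[1:cut], perm[(cut + 1L):n])
    # H-bond every sheet-adjacent pair with probability 0.8
    hb <- list()
    for (sh in sheets) {
      if (length(sh) > 1L) {
        for (i in seq_len(length(sh) - 1L)) {
          if (runif(1) < 0.8) hb[[length(hb) + 1L]] <- c(sh[i], sh[i + 1L])
        }
      }
    }
    topo <- try(sss_topology(n, sheets, hb), silent = TRUE)
    if (!inherits(topo, "try-error")) return(topo)
  }
}

# a random geometrically valid assignment on a random sequence
random_case <- function(seed, len = NULL) {
  set.seed(seed)
  loops <- sample(3:9, 6, replace = TRUE)
  while (sum(loops) < 30 || sum(loops) > 60) loops <- sample(3:9, 6, TRUE)
  ntail <- sample(0:4, 1)
  ctail <- sample(0:4, 1)
  L <- ntail + 42L + sum(loops) + ctail
  seqc <- paste(sample(amino_acids(), L, replace = TRUE), collapse = "")
  starts <- ntail + cumsum(c(0L, 6L + loops))[1:7]
  list(sequence = seqc, assignment = fold_assignment(starts, L),
       loops = loops)
}
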