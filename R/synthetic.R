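# run expr with a private, restorable RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

new_annotated <- function(id, sequence, label, true_assignment = NULL,
                          violated_group = NULL, seed = NA_integer_) {
  structure(list(id = id, sequence = sequence, label = label,
                 true_assignment = true_assignment,
                 violated_group = violated_group, seed = seed),
            class = "annotated_sequence")
}

#' @export
print.annotated_sequence <- function(x, ...) {
  cat(sprintf("annotated_sequence %s [%s%s], %d aa\n", x$id, x$label,
              if (!is.null(x$violated_group)) paste0("/", x$violated_group)
              else "", nchar(x$sequence)))
  invisible(x)
}

#' The fixed worked positive fixture
#'
#' A 72-residue sequence built from seven hand-designed strand windows joined
#' by all-Gly loops of length 5. It satisfies every default rule with strands
#' at 1-based starts 1, 12, 23, 34, 45, 56, 67 and anchors several unit and
#' acceptance tests.
#'
#' @return List with `sequence`, `strands` (the seven 6-mers), `assignment`
#'   (a [fold_assignment()]).
#' @export
#'
#' @examples
#' worked_positive()$sequence
worked_positive <- function() {
  strands <- c("VQVASQ", "FQVAVQ", "VQVAVQ", "VQSQNQ", "VQAQVK", "VQCQVY",
               "VQSQTE")
  seqc <- paste(strands, collapse = "GGGGG")
  list(sequence = seqc, strands = strands,
       assignment = fold_assignment(seq(0L, 66L, by = 11L), 72L))
}

# residues interchangeable without changing any strand-rule count: identical
# membership across every residue class the strand rules use
strand_interchange_sets <- function() {
  list(c("V", "L", "I", "M"), c("F", "W"), c("Q", "S", "T"),
       c("K", "R", "H"), c("D", "E"))
}

# swap each template residue for a random member of its interchange set
randomize_strand <- function(template) {
  sets <- strand_interchange_sets()
  vapply(template, function(ch) {
    for (s in sets) {
      if (ch %in% s) return(sample(s, 1L))
    }
    ch
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a rule-satisfying sequence with known strand coordinates
#'
#' Positives are built constructively: the seven strand windows of the worked
#' template are randomized within residue interchange sets that provably
#' leave every rule count unchanged, loops are drawn from \{Gly, Pro\} (the
#' only residues meeting the literal loop-favorability threshold), and the
#' result is verified with [check_assignment()] before being returned.
#' Rejection sampling of raw random strings is hopeless here - the
#' acceptance region is astronomically small.
#'
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param loop_lengths Six loop lengths (default all 5); each must lie in the
#'   geometry's per-loop range and their total in the total range.
#' @param n_tail,c_tail Tail lengths (default 0); tail residues are drawn
#'   uniformly from the standard alphabet.
#' @param ruleset Rule set used for generation-time verification.
#' @param max_tries Bounded retries before erroring (the constructive scheme
#'   should succeed on the first try; retries guard user-modified rule sets).
#' @param id Record id.
#' @return An `annotated_sequence` with `label = "positive"` and the true
#'   assignment.
#' @export
generate_positive <- function(seed, loop_lengths = rep(5L, 6L),
                              n_tail = 0L, c_tail = 0L,
                              ruleset = default_ruleset(),
                              max_tries = 50L, id = sprintf("pos_%d", seed)) {
  g <- ruleset$geometry
  loop_lengths <- as.integer(loop_lengths)
  lr <- g$loop_len_range
  if (length(loop_lengths) != 6L || any(loop_lengths < lr[1L]) ||
      any(loop_lengths > lr[2L])) {
    stop("loop_lengths must be six values within the per-loop range",
         call. = FALSE)
  }
  if (g$enforce_loop_total) {
    tr <- g$loop_total_range
    if (sum(loop_lengths) < tr[1L] || sum(loop_lengths) > tr[2L]) {
      stop("total of loop_lengths outside the allowed range", call. = FALSE)
    }
  }
  template <- lapply(worked_positive()$strands,
                     function(s) strsplit(s, "")[[1]])
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      strands <- lapply(template, randomize_strand)
      loops <- lapply(loop_lengths, function(l) {
        sample(c("G", "P"), l, replace = TRUE)
      })
      nt <- if (n_tail > 0L) sample(amino_acids(), n_tail, replace = TRUE)
        else character(0)
      ct <- if (c_tail > 0L) sample(amino_acids(), c_tail, replace = TRUE)
        else character(0)
      parts <- character(0)
      starts <- integer(7)
      pos <- n_tail
      for (k in 1:7) {
        starts[k] <- pos
        parts <- c(parts, strands[[k]])
        pos <- pos + 6L
        if (k < 7L) {
          parts <- c(parts, loops[[k]])
          pos <- pos + loop_lengths[k]
        }
      }
      res <- c(nt, parts, ct)
      a <- fold_assignment(starts, length(res), g)
      if (check_assignment(res, a, ruleset)$satisfied) {
        return(new_annotated(id, paste(res, collapse = ""), "positive",
                             true_assignment = a, seed = seed))
      }
    }
  })
  stop(sprintf(
    "could not generate a satisfying positive in %d tries (rule set too strict?)",
    max_tries), call. = FALSE)
}

negative_groups <- function() c("GEOMETRY", "T1", "T2", "T3", "LOOPS")

#' Generate a sequence that no assignment can satisfy for a chosen rule group
#'
#' Each construction defeats its target group for *every* candidate
#' assignment:
#' \describe{
#'   \item{GEOMETRY}{a 60-mer, below the 72-residue minimum span.}
#'   \item{T1}{Gly at every third position: any 6-residue window holds two
#'     Gly, one of which falls on a hydrophobic-face position (whatever the
#'     parity), violating the no-Gly-at-hydrophobic-positions rule.}
#'   \item{T2}{no hydrophilic residue anywhere, so no window can meet the
#'     one-hydrophilic-per-strand minimum at hydrophilic positions.}
#'   \item{T3}{charged residues at alternating positions: every window holds
#'     three charged residues, violating the interlock-strand-2 cap of two
#'     at any position.}
#'   \item{LOOPS}{alphabet \{V, Q, E, K\} only: every candidate loop has
#'     loop-favorable value 0.}
#' }
#' Generation verifies (via [fold_search()]) that the sequence is rejected
#' both under the target group alone and under the full rule set; for
#' sequences within the oracle guard, `verify = "oracle"` uses
#' [enumerate_satisfying()] instead.
#'
#' @param violated_group One of `GEOMETRY`, `T1`, `T2`, `T3`, `LOOPS`.
#' @param seed Integer seed.
#' @param length Sequence length (default 60 for GEOMETRY, 90 otherwise).
#' @param ruleset Rule set for verification.
#' @param verify `"search"` (default) or `"oracle"`.
#' @param id Record id.
#' @return An `annotated_sequence` with `label = "negative"`.
#' @export
generate_negative <- function(violated_group, seed, length = NULL,
                              ruleset = default_ruleset(),
                              verify = c("search", "oracle"),
                              id = sprintf("neg_%s_%d", violated_group, seed)) {
  verify <- match.arg(verify)
  if (!violated_group %in% negative_groups()) {
    stop(sprintf("unknown rule group '%s'", violated_group), call. = FALSE)
  }
  L <- as.integer(length %||% if (violated_group == "GEOMETRY") 60L else 90L)
  if (violated_group == "GEOMETRY" && L >= min_span(ruleset$geometry)) {
    stop("GEOMETRY negatives must be shorter than the minimum span",
         call. = FALSE)
  }
  res <- with_seed(seed, {
    switch(violated_group,
      GEOMETRY = sample(c("V", "Q", "A", "S", "T", "L", "K", "E"), L,
                        replace = TRUE),
      T1 = {
        x <- sample(c("V", "L", "I", "M", "Q", "S", "T"), L, replace = TRUE)
        x[seq(1L, L, by = 3L)] <- "G"
        x
      },
      T2 = sample(c("V", "L", "I", "M", "A", "F", "W", "C"), L,
                  replace = TRUE),
      T3 = {
        x <- character(L)
        x[seq(1L, L, by = 2L)] <- sample(c("V", "L", "I", "M"),
                                         ceiling(L / 2), replace = TRUE)
        x[seq(2L, L, by = 2L)] <- sample(c("K", "R", "H"), floor(L / 2),
                                         replace = TRUE)
        x
      },
      LOOPS = sample(c("V", "Q", "E", "K"), L, replace = TRUE)
    )
  })
  seqc <- paste(res, collapse = "")
  group_rs <- if (violated_group == "GEOMETRY") ruleset else
    subset_ruleset(ruleset, violated_group)
  rejected_group <- if (verify == "oracle") {
    length(enumerate_satisfying(seqc, group_rs)) == 0L
  } else {
    !fold_search(seqc, group_rs)$accepted
  }
  if (!rejected_group) {
    stop(sprintf("negative construction failed to defeat group %s",
                 violated_group), call. = FALSE)
  }
  new_annotated(id, seqc, "negative", violated_group = violated_group,
                seed = seed)
}

#' Generate a random background sequence
#'
#' @param seed Integer seed.
#' @param length_range `c(min, max)` sequence length (drawn uniformly), or a
#'   single length.
#' @param composition `"uniform"` or a named residue frequency vector;
#'   frequencies not summing to 1 are renormalized with a warning.
#' @param id Record id.
#' @return An `annotated_sequence` with `label = "random"` (truth unknown).
#' @export
generate_random <- function(seed, length_range = c(72L, 120L),
                            composition = "uniform",
                            id = sprintf("rnd_%d", seed)) {
  if (identical(composition, "uniform")) {
    p <- rep(1 / 20, 20)
    names(p) <- amino_acids()
  } else {
    p <- composition
    bad <- setdiff(names(p), amino_acids())
    if (is.null(names(p)) || length(bad)) {
      stop("composition must be a named frequency vector over amino acids",
           call. = FALSE)
    }
    if (any(p < 0) || sum(p) <= 0) stop("invalid frequencies", call. = FALSE)
    if (abs(sum(p) - 1) > 1e-9) {
      warning("frequencies do not sum to 1; renormalizing", call. = FALSE)
    }
    p <- p / sum(p)
  }
  with_seed(seed, {
    L <- if (length(length_range) == 1L) as.integer(length_range) else
      sample(length_range[1L]:length_range[2L], 1L)
    res <- sample(names(p), L, replace = TRUE, prob = p)
    new_annotated(id, paste(res, collapse = ""), "random", seed = seed)
  })
}

#' Build a labelled synthetic benchmark
#'
#' Positives, targeted negatives (across all five groups) and random
#' background sequences, shuffled deterministically by the seed.
#'
#' @param n_pos Number of positives.
#' @param n_neg_per_group Number of targeted negatives per group (5 groups).
#' @param n_random Number of random background sequences.
#' @param seed Integer seed.
#' @param random_length_range Length range for the random records.
#' @param ruleset Rule set used by the generators.
#' @return Object of class `fold_benchmark`: list with `records` (list of
#'   `annotated_sequence`) and `truth` (data frame `id`, `label`, `group`).
#' @export
make_benchmark <- function(n_pos, n_neg_per_group, n_random, seed = 1L,
                           random_length_range = c(72L, 120L),
                           ruleset = default_ruleset()) {
  stopifnot(n_pos >= 0L, n_neg_per_group >= 0L, n_random >= 0L)
  records <- list()
  sub <- function(i, tag) as.integer(seed * 100000L + i)
  i <- 0L
  for (j in seq_len(n_pos)) {
    i <- i + 1L
    records[[length(records) + 1L]] <-
      generate_positive(sub(i), ruleset = ruleset,
                        id = sprintf("pos_%03d", j))
  }
  for (grp in negative_groups()) {
    for (j in seq_len(n_neg_per_group)) {
      i <- i + 1L
      records[[length(records) + 1L]] <-
        generate_negative(grp, sub(i), ruleset = ruleset,
                          id = sprintf("neg_%s_%03d", grp, j))
    }
  }
  for (j in seq_len(n_random)) {
    i <- i + 1L
    records[[length(records) + 1L]] <-
      generate_random(sub(i), random_length_range,
                      id = sprintf("rnd_%03d", j))
  }
  ord <- with_seed(seed, sample(seq_along(records)))
  records <- records[ord]
  truth <- data.frame(
    id = vapply(records, `[[`, character(1), "id"),
    label = vapply(records, `[[`, character(1), "label"),
    group = vapply(records, function(r) r$violated_group %||% NA_character_,
                   character(1)),
    stringsAsFactors = FALSE)
  structure(list(records = records, truth = truth, seed = seed),
            class = "fold_benchmark")
}

#' Write a benchmark as FASTA plus a truth table
#'
#' @param benchmark A `fold_benchmark`.
#' @param prefix Output path prefix; writes `<prefix>.fasta` and
#'   `<prefix>_truth.tsv`.
#' @return Invisibly, the two file paths.
#' @export
write_benchmark <- function(benchmark, prefix) {
  stopifnot(inherits(benchmark, "fold_benchmark"))
  fa <- paste0(prefix, ".fasta")
  tsv <- paste0(prefix, "_truth.tsv")
  recs <- data.frame(
    id = vapply(benchmark$records, `[[`, character(1), "id"),
    desc = "",
    seq = vapply(benchmark$records, `[[`, character(1), "sequence"),
    stringsAsFactors = FALSE)
  write_fasta(recs, fa)
  write.table(benchmark$truth, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fa, tsv))
}
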