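#' Strand assignment onto a sequence
#'
#' A placement of the seven 6-residue strand windows on a sequence. Strand
#' starts are stored 0-based (internal convention; all printed reports are
#' 1-based inclusive). Loop lengths, N-tail and C-tail are implied.
#'
#' @param strand_starts Integer vector of 7 strand start offsets (0-based,
#'   strictly ascending, windows non-overlapping).
#' @param seq_length Length of the target sequence.
#' @param geometry A [fold_geometry()] used for basic validation.
#' @param check_loops Validate loop lengths against the geometry ranges
#'   (default `FALSE`: out-of-range loops are reported as rule violations by
#'   [check_assignment()], not construction errors).
#' @return Object of class `fold_assignment` with fields `strand_starts`,
#'   `loop_lengths`, `n_tail`, `c_tail`, `seq_length`.
#' @export
#'
#' @examples
#' a <- fold_assignment(seq(0, 66, by = 11), 72)
#' a$loop_lengths  # six loops of 5
fold_assignment <- function(strand_starts, seq_length,
                            geometry = fold_geometry(), check_loops = FALSE) {
  s <- as.integer(strand_starts)
  L <- as.integer(seq_length)
  sl <- geometry$strand_length
  if (length(s) != geometry$n_strands) {
    stop(sprintf("expected %d strand starts", geometry$n_strands), call. = FALSE)
  }
  if (any(is.na(s)) || s[1L] < 0L || s[length(s)] + sl > L) {
    stop("strand windows must fit within the sequence", call. = FALSE)
  }
  loops <- diff(s) - sl
  if (any(loops < 0L)) stop("strand windows overlap", call. = FALSE)
  if (check_loops) {
    lr <- geometry$loop_len_range
    if (any(loops < lr[1L] | loops > lr[2L])) {
      stop("loop length outside allowed range", call. = FALSE)
    }
    if (geometry$enforce_loop_total) {
      tr <- geometry$loop_total_range
      if (sum(loops) < tr[1L] || sum(loops) > tr[2L]) {
        stop("total loop length outside allowed range", call. = FALSE)
      }
    }
  }
  structure(list(strand_starts = s, loop_lengths = loops, n_tail = s[1L],
                 c_tail = L - (s[length(s)] + sl), seq_length = L),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("fold_assignment: strand starts (1-based) %s; loops %s; tails %d/%d\n",
              paste(x$strand_starts + 1L, collapse = ","),
              paste(x$loop_lengths, collapse = ","), x$n_tail, x$c_tail))
  invisible(x)
}

#' Extract a strand window
#'
#' @param residues Character vector of residues (see [split_residues()]).
#' @param assignment A `fold_assignment`.
#' @param k Strand index 1..7.
#' @param geometry A [fold_geometry()].
#' @return Character vector of 6 residues.
#' @keywords internal
strand_window <- function(residues, assignment, k, geometry = fold_geometry()) {
  s <- assignment$strand_starts[k]
  residues[(s + 1L):(s + geometry$strand_length)]
}

loop_fragment <- function(residues, assignment, j, geometry = fold_geometry()) {
  a <- assignment$strand_starts[j] + geometry$strand_length
  b <- assignment$strand_starts[j + 1L]
  if (b <= a) return(character(0))
  residues[(a + 1L):b]
}

resolve_members <- function(class) {
  if (length(class) == 1L && class %in% names(residue_classes())) {
    residue_classes()[[class]]
  } else {
    toupper(class)
  }
}

#' Count residues of a class at a strand face or in loops
#'
#' The measurement primitive of the grammar: counts residues belonging to a
#' residue class at the designated face positions of each strand window, and
#' aggregates over the interlock strands (2, 3, 5, 6), the non-interlock
#' strands (1, 4, 7) and all strands. With `face = "loops"` the per-loop
#' counts (over all loop positions) are returned instead.
#'
#' @param sequence Sequence string or residue character vector.
#' @param assignment A [fold_assignment()].
#' @param class Residue-class name or character vector of one-letter codes.
#' @param face One of `"hydrophobic_positions"`, `"hydrophilic_positions"`,
#'   `"any_position"`, `"loops"`.
#' @param geometry A [fold_geometry()].
#' @return For strand faces, a list with `per_strand` (length 7), `interlock`,
#'   `non_interlock`, `all`; for loops, a list with `per_loop` (length 6) and
#'   `total`.
#' @export
#'
#' @examples
#' seq72 <- worked_positive()$sequence
#' a <- fold_assignment(seq(0, 66, by = 11), 72)
#' count_feature(seq72, a, "HYDROPHOBIC", "hydrophobic_positions")$all  # 16
count_feature <- function(sequence, assignment, class,
                          face = c("hydrophobic_positions",
                                   "hydrophilic_positions", "any_position",
                                   "loops"),
                          geometry = fold_geometry()) {
  face <- match.arg(face)
  res <- if (is.character(sequence) && length(sequence) == 1L) {
    split_residues(sequence, warn = FALSE)
  } else sequence
  members <- resolve_members(class)
  if (face == "loops") {
    per_loop <- vapply(seq_len(geometry$n_strands - 1L), function(j) {
      sum(loop_fragment(res, assignment, j, geometry) %in% members)
    }, integer(1))
    return(list(per_loop = per_loop, total = sum(per_loop)))
  }
  offsets <- switch(face,
                    hydrophobic_positions = geometry$hydrophobic_positions,
                    hydrophilic_positions = geometry$hydrophilic_positions,
                    any_position = seq_len(geometry$strand_length))
  per_strand <- vapply(seq_len(geometry$n_strands), function(k) {
    w <- strand_window(res, assignment, k, geometry)
    sum(w[offsets] %in% members)
  }, integer(1))
  list(per_strand = per_strand,
       interlock = sum(per_strand[geometry$interlock_strands]),
       non_interlock = sum(per_strand[geometry$non_interlock_strands]),
       all = sum(per_strand))
}

# violation accumulator: plain parallel vectors, one data.frame at the end
viol_new <- function() {
  acc <- new.env(parent = emptyenv())
  acc$rule_id <- character(0)
  acc$scope <- character(0)
  acc$observed <- numeric(0)
  acc$lower <- numeric(0)
  acc$upper <- numeric(0)
  acc
}

viol_add <- function(acc, rule_id, scope, observed, lower, upper) {
  n <- length(acc$rule_id) + 1L
  acc$rule_id[n] <- rule_id
  acc$scope[n] <- scope
  acc$observed[n] <- observed
  acc$lower[n] <- lower
  acc$upper[n] <- upper
}

viol_df <- function(acc) {
  data.frame(rule_id = acc$rule_id, scope = acc$scope,
             observed = acc$observed, lower = acc$lower, upper = acc$upper,
             stringsAsFactors = FALSE)
}

empty_violations <- function() viol_df(viol_new())

viol_rule <- function(acc, counts, rule) {
  ps <- rule$per_strand
  for (k in 1:7) {
    obs <- counts$per_strand[k]
    if (obs < ps[k, 1L] || obs > ps[k, 2L]) {
      viol_add(acc, rule$id, paste0("strand_", k), obs, ps[k, 1L], ps[k, 2L])
    }
  }
  if (counts$interlock < rule$interlock[1L] ||
      counts$interlock > rule$interlock[2L]) {
    viol_add(acc, rule$id, "interlock", counts$interlock,
             rule$interlock[1L], rule$interlock[2L])
  }
  if (counts$non_interlock < rule$non_interlock[1L] ||
      counts$non_interlock > rule$non_interlock[2L]) {
    viol_add(acc, rule$id, "non_interlock", counts$non_interlock,
             rule$non_interlock[1L], rule$non_interlock[2L])
  }
  if (counts$all < rule$all[1L] || counts$all > rule$all[2L]) {
    viol_add(acc, rule$id, "all", counts$all, rule$all[1L], rule$all[2L])
  }
}

#' Evaluate one rule against precomputed counts
#'
#' @param counts Output of [count_feature()] for the rule's class and face.
#' @param rule A [fold_rule()].
#' @return Data frame of violation entries (zero rows iff all bounds met).
#' @export
evaluate_rule <- function(counts, rule) {
  acc <- viol_new()
  viol_rule(acc, counts, rule)
  viol_df(acc)
}

#' Loop-favorable function
#'
#' Integer score of a candidate loop fragment: the sum of per-residue
#' weights (by default Gly/Pro 2; Asp/Asn/His/Ser/Thr 1; others 0).
#'
#' @param fragment Residue string or character vector.
#' @param weights Named weight vector (default [default_loop_weights()]).
#' @return Numeric scalar.
#' @export
#'
#' @examples
#' loop_favorable_value("GPGPG")  # 10
loop_favorable_value <- function(fragment, weights = default_loop_weights()) {
  res <- if (is.character(fragment) && length(fragment) == 1L) {
    split_residues(fragment, warn = FALSE)
  } else fragment
  w <- numeric(20); names(w) <- amino_acids()
  w[names(weights)] <- weights
  sum(w[res[res %in% names(w)]])
}

#' Check the loop rules of an assignment
#'
#' For each of the six loops: the loop-favorable value must reach
#' `coefficient * loop length`; strongly hydrophobic residues must be in the
#' strict minority; loop lengths must lie in the per-loop range and their
#' total in the total range. The strongly hydrophobic count summed over all
#' loops is capped (default 12).
#'
#' @param sequence Sequence string or residue vector.
#' @param assignment A [fold_assignment()].
#' @param rules A [loop_rules()] object.
#' @param geometry A [fold_geometry()].
#' @return Data frame of violation entries.
#' @export
check_loops <- function(sequence, assignment, rules = loop_rules(),
                        geometry = fold_geometry()) {
  res <- if (is.character(sequence) && length(sequence) == 1L) {
    split_residues(sequence, warn = FALSE)
  } else sequence
  acc <- viol_new()
  viol_loops(acc, res, assignment, rules, geometry)
  viol_df(acc)
}

viol_loops <- function(acc, res, assignment, rules, geometry) {
  strong <- residue_classes()$STRONG_HYDROPHOBIC
  w <- rules$favorability_weights
  tot_strong <- 0L
  tot_len <- 0L
  for (j in seq_len(geometry$n_strands - 1L)) {
    frag <- loop_fragment(res, assignment, j, geometry)
    l <- length(frag)
    tot_len <- tot_len + l
    scope <- paste0("loop_", j)
    fav <- sum(w[match(frag, names(w))], na.rm = TRUE)
    need <- rules$favorability_coefficient * l
    if (fav < need) {
      viol_add(acc, "loop_favorability", scope, fav, need, Inf)
    }
    ns <- sum(frag %in% strong)
    tot_strong <- tot_strong + ns
    if (rules$per_loop_hydrophobic_lt_hydrophilic && ns >= l - ns) {
      viol_add(acc, "loop_hydrophobic_majority", scope, ns, 0,
               max(0, ceiling(l / 2) - 1L))
    }
    lr <- geometry$loop_len_range
    if (l < lr[1L] || l > lr[2L]) {
      viol_add(acc, "loop_length", scope, l, lr[1L], lr[2L])
    }
  }
  if (tot_strong > rules$total_loop_hydrophobic_max) {
    viol_add(acc, "loop_hydrophobic_total", "loops", tot_strong, 0,
             rules$total_loop_hydrophobic_max)
  }
  if (geometry$enforce_loop_total) {
    tr <- geometry$loop_total_range
    if (tot_len < tr[1L] || tot_len > tr[2L]) {
      viol_add(acc, "loop_total_length", "loops", tot_len, tr[1L], tr[2L])
    }
  }
}

#' Check a fixed assignment against a full rule set
#'
#' Pure and deterministic: evaluates every strand rule of the rule set via
#' [count_feature()] / [evaluate_rule()] and appends the loop-rule check.
#'
#' @param sequence Sequence string or residue vector.
#' @param assignment A [fold_assignment()] (or a vector of 7 0-based strand
#'   starts).
#' @param ruleset A `fold_ruleset` (default [default_ruleset()]).
#' @return Object of class `violation_report`: list with `violations` (data
#'   frame) and `satisfied` (logical).
#' @export
#'
#' @examples
#' pos <- worked_positive()
#' rep <- check_assignment(pos$sequence, pos$assignment)
#' rep$satisfied  # TRUE
check_assignment <- function(sequence, assignment,
                             ruleset = default_ruleset()) {
  geometry <- ruleset$geometry
  res <- if (is.character(sequence) && length(sequence) == 1L) {
    split_residues(sequence, warn = FALSE)
  } else sequence
  if (!inherits(assignment, "fold_assignment")) {
    assignment <- fold_assignment(assignment, length(res), geometry)
  }
  if (assignment$seq_length != length(res)) {
    stop("assignment was built for a different sequence length", call. = FALSE)
  }
  acc <- viol_new()
  cache <- new.env(parent = emptyenv())
  for (r in ruleset$rules) {
    key <- paste(r$class, r$face, sep = "|")
    cnt <- cache[[key]]
    if (is.null(cnt)) {
      cnt <- count_feature(res, assignment, r$members, r$face, geometry)
      cache[[key]] <- cnt
    }
    viol_rule(acc, cnt, r)
  }
  if (ruleset$loop_rules_enabled) {
    viol_loops(acc, res, assignment, ruleset$loop_rules, geometry)
  }
  viol <- viol_df(acc)
  structure(list(violations = viol, satisfied = nrow(viol) == 0L,
                 assignment = assignment),
            class = "violation_report")
}

#' @export
print.violation_report <- function(x, ...) {
  if (x$satisfied) {
    cat("violation_report: satisfied (no violations)\n")
  } else {
    cat(sprintf("violation_report: %d violation(s)\n", nrow(x$violations)))
    print(x$violations)
  }
  invisible(x)
}
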