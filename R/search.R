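#' Search parameters
#'
#' @param enumerate_all Count all satisfying assignments (and collect up to
#'   `max_witnesses` of them) instead of stopping at the first.
#' @param max_witnesses Maximum number of witnesses to collect.
#' @param prune Enable admissible feasibility pruning on aggregate minimum
#'   bounds (debug switch; the decision is identical with pruning on or off).
#' @param strict_alphabet Error (rather than warn) on non-standard residue
#'   letters.
#' @return Object of class `fold_search_params`.
#' @export
search_params <- function(enumerate_all = FALSE, max_witnesses = 1L,
                          prune = TRUE, strict_alphabet = FALSE) {
  stopifnot(max_witnesses >= 1L)
  structure(list(enumerate_all = isTRUE(enumerate_all),
                 max_witnesses = as.integer(max_witnesses),
                 prune = isTRUE(prune),
                 strict_alphabet = isTRUE(strict_alphabet)),
            class = "fold_search_params")
}

# ---- shared precomputation -------------------------------------------------

face_offsets <- function(face, geometry) {
  switch(face,
         hydrophobic_positions = geometry$hydrophobic_positions,
         hydrophilic_positions = geometry$hydrophilic_positions,
         any_position = seq_len(geometry$strand_length))
}

# descriptor table: unique (class, face) pairs among the strand rules
descriptor_table <- function(ruleset) {
  keys <- vapply(ruleset$rules, function(r) paste(r$class, r$face, sep = "|"),
                 character(1))
  uk <- unique(keys)
  desc <- lapply(uk, function(k) {
    r <- ruleset$rules[[match(k, keys)]]
    list(members = r$members, face = r$face)
  })
  list(descriptors = desc, rule_desc = match(keys, uk))
}

# W x D matrix of per-window class counts (production counting path)
window_count_matrix <- function(res, desc, geometry) {
  L <- length(res)
  W <- L - geometry$strand_length + 1L
  D <- length(desc)
  wc <- matrix(0L, nrow = max(W, 0L), ncol = max(D, 1L))
  if (W < 1L) return(wc)
  idx <- seq_len(W)
  for (d in seq_len(D)) {
    ind <- as.integer(res %in% desc[[d]]$members)
    acc <- integer(W)
    for (o in face_offsets(desc[[d]]$face, geometry)) {
      acc <- acc + ind[idx + o - 1L]
    }
    wc[, d] <- acc
  }
  wc
}

cap_int <- function(x) {
  x <- as.numeric(x)
  x[!is.finite(x) | x > .Machine$integer.max] <- .Machine$integer.max
  as.integer(x)
}

# everything the C++ kernel needs, derived once per (sequence, ruleset)
search_precompute <- function(res, ruleset, explain = FALSE) {
  g <- ruleset$geometry
  dt <- descriptor_table(ruleset)
  D <- length(dt$descriptors)
  R <- length(ruleset$rules)
  L <- length(res)
  W <- L - g$strand_length + 1L
  wc <- window_count_matrix(res, dt$descriptors, g)
  valid <- matrix(1L, nrow = max(W, 0L), ncol = 7L)
  svio <- matrix(0L, nrow = if (explain) max(W, 0L) else 0L,
                 ncol = if (explain) 7L else 0L)
  agg_lo <- matrix(0L, nrow = max(R, 1L), ncol = 3L)
  agg_hi <- matrix(.Machine$integer.max, nrow = max(R, 1L), ncol = 3L)
  if (W >= 1L && R > 0L) {
    for (i in seq_len(R)) {
      r <- ruleset$rules[[i]]
      v <- wc[, dt$rule_desc[i]]
      for (k in 1:7) {
        lo <- r$per_strand[k, 1L]; hi <- r$per_strand[k, 2L]
        if (lo > 0 || is.finite(hi)) {
          ok <- v >= lo & v <= hi
          valid[, k] <- valid[, k] & ok
          if (explain) svio[, k] <- svio[, k] + as.integer(!ok)
        }
      }
      agg_lo[i, ] <- cap_int(c(r$interlock[1L], r$non_interlock[1L], r$all[1L]))
      agg_hi[i, ] <- cap_int(c(r$interlock[2L], r$non_interlock[2L], r$all[2L]))
    }
  }
  lw <- if (ruleset$loop_rules_enabled) {
    ruleset$loop_rules$favorability_weights
  } else {
    numeric(20)
  }
  names(lw) <- amino_acids()
  wvec <- unname(lw[match(res, names(lw))])
  wvec[is.na(wvec)] <- 0
  strong <- residue_classes()$STRONG_HYDROPHOBIC
  tot <- if (g$enforce_loop_total) g$loop_total_range else
    c(6L * g$loop_len_range[1L], 6L * g$loop_len_range[2L])
  list(
    wc = wc, valid = valid, svio = svio,
    rule_desc = if (R > 0L) as.integer(dt$rule_desc - 1L) else integer(0),
    agg_lo = agg_lo, agg_hi = agg_hi,
    face_size = vapply(dt$descriptors, function(d) {
      length(face_offsets(d$face, ruleset$geometry))
    }, integer(1)),
    cumw = cumsum(c(0, wvec)),
    cumstrong = as.integer(cumsum(c(0L, as.integer(res %in% strong)))),
    check_fav = ruleset$loop_rules_enabled,
    check_major = ruleset$loop_rules_enabled &&
      ruleset$loop_rules$per_loop_hydrophobic_lt_hydrophilic,
    strong_cap = if (ruleset$loop_rules_enabled &&
                     is.finite(ruleset$loop_rules$total_loop_hydrophobic_max)) {
      as.integer(ruleset$loop_rules$total_loop_hydrophobic_max)
    } else -1L,
    coeff = if (ruleset$loop_rules_enabled) {
      ruleset$loop_rules$favorability_coefficient
    } else 0,
    loop_min = g$loop_len_range[1L], loop_max = g$loop_len_range[2L],
    tot_min = tot[1L], tot_max = tot[2L],
    max_n_tail = cap_int(g$max_n_tail), max_c_tail = cap_int(g$max_c_tail),
    L = L, W = W
  )
}

call_kernel <- function(pc, mode, max_wit, prune) {
  cpp_search(pc$wc, pc$valid, pc$svio, pc$rule_desc, pc$agg_lo, pc$agg_hi,
             as.integer(pc$face_size), pc$cumw, pc$cumstrong, pc$coeff,
             pc$check_fav, pc$check_major, pc$strong_cap,
             pc$loop_min, pc$loop_max, pc$tot_min, pc$tot_max,
             pc$max_n_tail, pc$max_c_tail, pc$L, as.integer(mode),
             as.integer(max_wit), prune)
}

new_decision <- function(accepted, witness = NULL, n_satisfying = NULL,
                         best_failing = NULL) {
  structure(list(accepted = accepted, witness = witness,
                 n_satisfying = n_satisfying, best_failing = best_failing),
            class = "fold_decision")
}

#' @export
print.fold_decision <- function(x, ...) {
  if (isTRUE(x$accepted)) {
    cat(sprintf("fold_decision: ACCEPTED, witness strand starts (1-based) %s\n",
                paste(x$witness$strand_starts + 1L, collapse = ",")))
  } else {
    cat("fold_decision: REJECTED\n")
  }
  if (!is.null(x$n_satisfying)) {
    cat(sprintf("  satisfying assignments: %s\n",
                format(x$n_satisfying, big.mark = ",")))
  }
  if (!is.null(x$best_failing)) {
    cat(sprintf("  closest assignment misses %d bound(s): rules %s\n",
                nrow(x$best_failing$violations),
                paste(unique(x$best_failing$violations$rule_id),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Decide whether a sequence admits a rule-satisfying strand assignment
#'
#' The classifier core: a backtracking search over all placements of the
#' seven 6-residue strands and six loops onto the sequence, accepting iff
#' some placement satisfies every rule of the rule set. Strands are placed
#' left to right in canonical order (strand-1 start ascending, then loop
#' lengths ascending), so the witness is the canonically first satisfying
#' assignment and is reproducible across platforms.
#'
#' @param sequence Sequence string or residue character vector.
#' @param ruleset A `fold_ruleset` (default [default_ruleset()]).
#' @param params A [search_params()].
#' @return A `fold_decision` with fields `accepted`, `witness` (a
#'   [fold_assignment()] or `NULL`) and, when `enumerate_all`,
#'   `n_satisfying`.
#' @export
#'
#' @examples
#' fold_search(worked_positive()$sequence)           # accepted
#' fold_search(strrep("G", 80))$accepted             # FALSE
fold_search <- function(sequence, ruleset = default_ruleset(),
                        params = search_params()) {
  validate_ruleset(ruleset)
  res <- if (is.character(sequence) && length(sequence) == 1L) {
    split_residues(sequence, strict = params$strict_alphabet)
  } else sequence
  if (length(res) < min_span(ruleset$geometry)) {
    return(new_decision(FALSE,
                        n_satisfying = if (params$enumerate_all) 0 else NULL))
  }
  pc <- search_precompute(res, ruleset)
  mode <- if (params$enumerate_all) 1L else 0L
  k <- call_kernel(pc, mode, params$max_witnesses, params$prune)
  wit <- k$witnesses
  if (nrow(wit) == 0L) {
    return(new_decision(FALSE,
                        n_satisfying = if (params$enumerate_all) 0 else NULL))
  }
  new_decision(TRUE,
               witness = fold_assignment(wit[1L, ], length(res),
                                         ruleset$geometry),
               n_satisfying = if (params$enumerate_all) k$n_satisfying else NULL)
}

#' Enumerate every candidate assignment of the skeleton
#'
#' All placements with 6-residue strands, per-loop lengths within the
#' geometry's per-loop range, total loop length within the total range (when
#' enforced) and tails within caps, in canonical order. Purely geometric: no
#' rules are consulted.
#'
#' @param sequence_length Integer.
#' @param geometry A [fold_geometry()].
#' @return Integer matrix, one row per assignment, columns = 0-based strand
#'   starts. Zero rows if the sequence is too short.
#' @export
#'
#' @examples
#' nrow(enumerate_candidate_assignments(72))  # 6188
enumerate_candidate_assignments <- function(sequence_length,
                                            geometry = fold_geometry()) {
  L <- as.integer(sequence_length)
  g <- geometry
  sl <- g$strand_length
  lmin <- g$loop_len_range[1L]; lmax <- g$loop_len_range[2L]
  tot <- if (g$enforce_loop_total) g$loop_total_range else
    c(6L * lmin, 6L * lmax)
  acc <- new.env(parent = emptyenv())
  acc$rows <- vector("list", 256L)
  acc$n <- 0L
  push <- function(starts) {
    acc$n <- acc$n + 1L
    if (acc$n > length(acc$rows)) {
      acc$rows <- c(acc$rows, vector("list", length(acc$rows)))
    }
    acc$rows[[acc$n]] <- starts
  }
  rec <- function(starts, tl) {
    k <- length(starts)
    if (k == 7L) {
      ct <- L - (starts[7L] + sl)
      if (tl >= tot[1L] && tl <= tot[2L] && ct >= 0L && ct <= g$max_c_tail) {
        push(starts)
      }
      return(invisible())
    }
    a <- starts[k] + sl
    for (l in lmin:lmax) {
      s_next <- a + l
      # minimal room for the remaining strands and loops
      if (s_next + sl + (6L - k) * (sl + lmin) > L) break
      rec(c(starts, s_next), tl + l)
    }
  }
  s0_hi <- min(L - 7L * sl - tot[1L], cap_int(g$max_n_tail))
  if (s0_hi >= 0L) {
    for (s0 in 0:s0_hi) rec(s0, 0L)
  }
  if (acc$n == 0L) {
    return(matrix(integer(0), ncol = 7L))
  }
  do.call(rbind, acc$rows[seq_len(acc$n)])
}

#' Exhaustively enumerate satisfying assignments (oracle mode)
#'
#' An implementation independent of the backtracking kernel, intended as a
#' testing oracle: strand-window admissibility is recounted naively per
#' window, the candidate tree is walked exhaustively in canonical order, and
#' every surviving leaf is confirmed with the pure [check_assignment()]
#' evaluator. Guarded against long sequences because the candidate space
#' grows combinatorially.
#'
#' @param sequence Sequence string or residue vector.
#' @param ruleset A `fold_ruleset`.
#' @param guard Maximum sequence length accepted (default 500); longer input
#'   is an error suggesting [fold_search()].
#' @return List of satisfying [fold_assignment()]s in canonical order.
#' @export
enumerate_satisfying <- function(sequence, ruleset = default_ruleset(),
                                 guard = 500L) {
  validate_ruleset(ruleset)
  res <- if (is.character(sequence) && length(sequence) == 1L) {
    split_residues(sequence, warn = FALSE)
  } else sequence
  if (length(res) > guard) {
    stop(sprintf(
      "sequence of length %d exceeds the oracle guard (%d); use fold_search()",
      length(res), guard), call. = FALSE)
  }
  g <- ruleset$geometry
  sl <- g$strand_length
  L <- length(res)
  if (L < min_span(g)) return(list())
  W <- L - sl + 1L
  # naive per-window recount of every rule's per-strand bounds
  valid <- matrix(TRUE, nrow = W, ncol = 7L)
  for (r in ruleset$rules) {
    off <- face_offsets(r$face, g)
    cnt <- vapply(seq_len(W), function(s) {
      sum(res[s + off - 1L] %in% r$members)
    }, integer(1))
    for (k in 1:7) {
      valid[, k] <- valid[, k] & cnt >= r$per_strand[k, 1L] &
        cnt <= r$per_strand[k, 2L]
    }
  }
  lr <- ruleset$loop_rules
  strong <- residue_classes()$STRONG_HYDROPHOBIC
  loop_ok <- function(a, l) {  # 0-based fragment start
    if (!ruleset$loop_rules_enabled) return(TRUE)
    frag <- res[(a + 1L):(a + l)]
    fav <- loop_favorable_value(frag, lr$favorability_weights)
    if (fav < lr$favorability_coefficient * l) return(FALSE)
    if (lr$per_loop_hydrophobic_lt_hydrophilic) {
      ns <- sum(frag %in% strong)
      if (ns >= l - ns) return(FALSE)
    }
    TRUE
  }
  lmin <- g$loop_len_range[1L]; lmax <- g$loop_len_range[2L]
  tot <- if (g$enforce_loop_total) g$loop_total_range else
    c(6L * lmin, 6L * lmax)
  out <- list()
  rec <- function(starts, tl) {
    k <- length(starts)
    if (k == 7L) {
      ct <- L - (starts[7L] + sl)
      if (tl < tot[1L] || tl > tot[2L] || ct < 0L || ct > g$max_c_tail) {
        return(invisible())
      }
      a <- fold_assignment(starts, L, g)
      if (check_assignment(res, a, ruleset)$satisfied) {
        out[[length(out) + 1L]] <<- a
      }
      return(invisible())
    }
    a0 <- starts[k] + sl
    for (l in lmin:lmax) {
      s_next <- a0 + l
      if (s_next + sl + (6L - k) * (sl + lmin) > L) break
      if (!valid[s_next + 1L, k + 1L]) next
      if (!loop_ok(a0, l)) next
      rec(c(starts, s_next), tl + l)
    }
  }
  s0_hi <- min(L - 7L * sl - tot[1L], cap_int(g$max_n_tail))
  if (s0_hi >= 0L) {
    for (s0 in 0:s0_hi) {
      if (valid[s0 + 1L, 1L]) rec(s0, 0L)
    }
  }
  out
}

#' Explain a classification decision
#'
#' For accepted sequences this is identical to [fold_search()]. For rejected
#' sequences, every candidate assignment is scanned and the one with the
#' fewest violated bounds (canonically first on ties) is reported together
#' with its full violation report.
#'
#' @inheritParams fold_search
#' @return A `fold_decision`; for rejects, `best_failing` is a
#'   `violation_report` carrying the closest assignment.
#' @export
fold_explain <- function(sequence, ruleset = default_ruleset(),
                         params = search_params()) {
  validate_ruleset(ruleset)
  res <- if (is.character(sequence) && length(sequence) == 1L) {
    split_residues(sequence, strict = params$strict_alphabet)
  } else sequence
  dec <- fold_search(res, ruleset, params)
  if (dec$accepted) return(dec)
  if (length(res) < min_span(ruleset$geometry)) {
    return(dec)  # no candidate assignments at all: nothing to explain
  }
  pc <- search_precompute(res, ruleset, explain = TRUE)
  k <- call_kernel(pc, 2L, 1L, FALSE)
  if (length(k$best_starts) == 0L) return(dec)
  best <- fold_assignment(k$best_starts, length(res), ruleset$geometry)
  dec$best_failing <- check_assignment(res, best, ruleset)
  dec
}

#' Classify a batch of sequence records
#'
#' @param records Data frame with columns `id` and `seq` (e.g. from
#'   [read_fasta()]).
#' @param ruleset A `fold_ruleset`.
#' @param params A [search_params()].
#' @param explain Attach `best_failing` to rejected records.
#' @return Named list of `fold_decision` objects, order preserving; a
#'   per-record error is captured as a decision with `accepted = NA` and an
#'   `error` field, and the batch continues.
#' @export
classify_batch <- function(records, ruleset = default_ruleset(),
                           params = search_params(), explain = FALSE) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  if (anyDuplicated(records$id)) {
    warning("duplicate record ids in batch", call. = FALSE)
  }
  out <- vector("list", nrow(records))
  names(out) <- records$id
  for (i in seq_len(nrow(records))) {
    out[[i]] <- tryCatch({
      if (explain) fold_explain(records$seq[i], ruleset, params)
      else fold_search(records$seq[i], ruleset, params)
    }, error = function(e) {
      d <- new_decision(NA)
      d$error <- conditionMessage(e)
      d
    })
  }
  out
}
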