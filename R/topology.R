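#' Abstract supersecondary-structure topology
#'
#' A description of a beta protein at supersecondary-structure level: the
#' number of sequence-ordered strands, the ordered composition of each beta
#' sheet, and which strand pairs share hydrogen bonds. No 3D coordinates are
#' involved; H-bonded pairs must be spatial neighbours within one sheet.
#'
#' @param n_strands Integer, number of strands (numbered `1..n_strands`).
#' @param sheets List of integer vectors, one per sheet; the order of each
#'   vector is the spatial order of strands within that sheet. Every strand
#'   must appear in exactly one sheet.
#' @param hbond_pairs Two-column integer matrix (or list of length-2 vectors)
#'   of unordered H-bonded strand pairs; each pair must be adjacent in the
#'   sheet that contains it.
#' @return An object of class `sss_topology`.
#' @export
#'
#' @examples
#' # the canonical seven-strand sandwich arrangement
#' topo <- sss_topology(7, list(c(1, 2, 5, 4), c(7, 6, 3)),
#'                      rbind(c(1, 2), c(2, 5), c(5, 4), c(7, 6), c(6, 3)))
#' partition_strandons(topo)
sss_topology <- function(n_strands, sheets, hbond_pairs = NULL) {
  n_strands <- as.integer(n_strands)
  sheets <- lapply(sheets, as.integer)
  if (is.null(hbond_pairs) || (is.matrix(hbond_pairs) && nrow(hbond_pairs) == 0L) ||
      (is.list(hbond_pairs) && length(hbond_pairs) == 0L)) {
    hb <- matrix(integer(0), ncol = 2L)
  } else if (is.list(hbond_pairs)) {
    hb <- do.call(rbind, lapply(hbond_pairs, as.integer))
  } else {
    hb <- matrix(as.integer(hbond_pairs), ncol = 2L)
  }
  obj <- structure(list(n_strands = n_strands, sheets = sheets,
                        hbond_pairs = hb),
                   class = "sss_topology")
  validate_topology(obj)
  obj
}

validate_topology <- function(x) {
  if (!inherits(x, "sss_topology")) stop("not an sss_topology", call. = FALSE)
  n <- x$n_strands
  if (is.na(n) || n < 1L) stop("n_strands must be a positive integer", call. = FALSE)
  members <- unlist(x$sheets)
  if (any(lengths(x$sheets) == 0L)) stop("sheets must be non-empty", call. = FALSE)
  if (length(members) != n || !setequal(members, seq_len(n)) ||
      anyDuplicated(members)) {
    stop("every strand 1..n must appear in exactly one sheet", call. = FALSE)
  }
  hb <- x$hbond_pairs
  if (nrow(hb)) {
    if (any(is.na(hb)) || any(hb < 1L) || any(hb > n)) {
      stop("hbond_pairs reference unknown strands", call. = FALSE)
    }
    for (i in seq_len(nrow(hb))) {
      if (!pair_sheet_adjacent(x, hb[i, 1L], hb[i, 2L])) {
        stop(sprintf("hbond pair (%d,%d) is not adjacent within one sheet",
                     hb[i, 1L], hb[i, 2L]), call. = FALSE)
      }
    }
    key <- paste(pmin(hb[, 1L], hb[, 2L]), pmax(hb[, 1L], hb[, 2L]))
    if (anyDuplicated(key)) stop("duplicate hbond pairs", call. = FALSE)
  }
  invisible(x)
}

# TRUE iff strands a, b are neighbours in the order of some sheet
pair_sheet_adjacent <- function(topology, a, b) {
  for (sh in topology$sheets) {
    ia <- match(a, sh); ib <- match(b, sh)
    if (!is.na(ia) && !is.na(ib) && abs(ia - ib) == 1L) return(TRUE)
  }
  FALSE
}

hbonded <- function(topology, a, b) {
  hb <- topology$hbond_pairs
  if (!nrow(hb)) return(FALSE)
  any((hb[, 1L] == a & hb[, 2L] == b) | (hb[, 1L] == b & hb[, 2L] == a))
}

sheet_of <- function(topology, strand) {
  for (i in seq_along(topology$sheets)) {
    if (strand %in% topology$sheets[[i]]) return(i)
  }
  NA_integer_
}

#' @export
print.sss_topology <- function(x, ...) {
  cat(sprintf("sss_topology: %d strands, %d sheets, %d H-bond pairs\n",
              x$n_strands, length(x$sheets), nrow(x$hbond_pairs)))
  for (i in seq_along(x$sheets)) {
    cat(sprintf("  sheet %d: %s\n", i, paste(x$sheets[[i]], collapse = "-")))
  }
  invisible(x)
}

#' Read a topology description from JSON
#'
#' Expects keys `n_strands`, `sheets` (list of lists) and `hbond_pairs`
#' (list of 2-element lists).
#'
#' @param path Path to a JSON file.
#' @return An `sss_topology`.
#' @export
read_topology <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (k in c("n_strands", "sheets")) {
    if (is.null(doc[[k]])) stop(sprintf("topology JSON lacks key '%s'", k),
                                call. = FALSE)
  }
  sss_topology(doc$n_strands,
               lapply(doc$sheets, function(s) unlist(s)),
               lapply(doc$hbond_pairs, function(p) unlist(p)))
}

#' Write a topology description to JSON
#'
#' @param topology An `sss_topology`.
#' @param path Output file path.
#' @export
write_topology <- function(topology, path) {
  validate_topology(topology)
  doc <- list(n_strands = topology$n_strands,
              sheets = topology$sheets,
              hbond_pairs = apply(topology$hbond_pairs, 1L, identity,
                                  simplify = FALSE))
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  invisible(path)
}

#' Partition strands into strandons
#'
#' A strandon is a maximal run of sequence-consecutive strands in which each
#' adjacent pair is H-bonded (hence spatial neighbours in one sheet). The
#' strandons partition the strand set.
#'
#' @param topology An `sss_topology`.
#' @return List of integer vectors, ordered by first member.
#' @export
#'
#' @examples
#' topo <- sss_topology(7, list(c(1, 2, 5, 4), c(7, 6, 3)),
#'                      rbind(c(1, 2), c(2, 5), c(5, 4), c(7, 6), c(6, 3)))
#' partition_strandons(topo)  # {1,2} {3} {4,5} {6,7}
partition_strandons <- function(topology) {
  validate_topology(topology)
  n <- topology$n_strands
  out <- list()
  cur <- 1L
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      if (!hbonded(topology, i, i + 1L)) {
        out[[length(out) + 1L]] <- cur:i
        cur <- i + 1L
      }
    }
  }
  out[[length(out) + 1L]] <- cur:n
  out
}

#' Check sheet-arrangement constraints
#'
#' Two empirical constraints on how consecutive strands may be arranged in
#' the two sheets of a sandwich:
#' * Constraint 1: two sequence-consecutive strands that are *not* H-bonded
#'   may not lie in the same sheet (their connecting loop would have to cross
#'   the sheet).
#' * Constraint 2: some pair of (cyclically) consecutive strands must sit at
#'   the left edges of the two sheets, and some pair at the right edges.
#'
#' These constraints hold for the large majority of real sandwich structures
#' but not all of them, so violations are reported rather than raised.
#'
#' @param topology An `sss_topology`.
#' @return Data frame with columns `constraint`, `strands`, `message`;
#'   zero rows iff both constraints hold. Fewer than two sheets yields a
#'   `constraint = "C2-not-applicable"` entry.
#' @export
check_arrangement <- function(topology) {
  validate_topology(topology)
  n <- topology$n_strands
  viol <- list()
  add <- function(constraint, strands, message) {
    viol[[length(viol) + 1L]] <<- data.frame(
      constraint = constraint,
      strands = paste(strands, collapse = ","),
      message = message, stringsAsFactors = FALSE)
  }
  # Constraint 1
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      if (!hbonded(topology, i, i + 1L) &&
          sheet_of(topology, i) == sheet_of(topology, i + 1L)) {
        add("C1", c(i, i + 1L),
            sprintf("consecutive strands %d and %d share a sheet without H-bonds",
                    i, i + 1L))
      }
    }
  }
  # Constraint 2
  if (length(topology$sheets) != 2L) {
    add("C2-not-applicable", integer(0),
        sprintf("constraint 2 requires exactly two sheets (found %d)",
                length(topology$sheets)))
  } else {
    cyc_consecutive <- function(a, b) {
      d <- abs(a - b)
      d == 1L || d == n - 1L  # (n,1) counts as consecutive
    }
    lefts <- vapply(topology$sheets, function(s) s[1L], integer(1))
    rights <- vapply(topology$sheets, function(s) s[length(s)], integer(1))
    if (!cyc_consecutive(lefts[1L], lefts[2L])) {
      add("C2", lefts, "left-edge strands of the two sheets are not consecutive")
    }
    if (!cyc_consecutive(rights[1L], rights[2L])) {
      add("C2", rights, "right-edge strands of the two sheets are not consecutive")
    }
  }
  if (length(viol)) do.call(rbind, viol) else
    data.frame(constraint = character(0), strands = character(0),
               message = character(0), stringsAsFactors = FALSE)
}

#' Find interlocks
#'
#' An interlock is a quadruple of strands `(i, i+1, j, j+1)` with `i+1 < j`
#' such that `i` and `j` are sheet-adjacent in one sheet while `i+1` and
#' `j+1` are sheet-adjacent in the other. It is the structural invariant of
#' two-sheet sandwich folds.
#'
#' @param topology An `sss_topology` with exactly two sheets.
#' @return Integer matrix with columns `i`, `i1`, `j`, `j1`, rows in
#'   ascending `(i, j)` order; zero rows if no interlock exists.
#' @export
find_interlocks <- function(topology) {
  validate_topology(topology)
  if (length(topology$sheets) != 2L) {
    stop("interlocks are defined for two-sheet sandwich topologies",
         call. = FALSE)
  }
  n <- topology$n_strands
  rows <- list()
  if (n >= 4L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq_len(n - 1L)) {
        if (i + 1L >= j) next
        si <- sheet_of(topology, i); sj <- sheet_of(topology, j)
        si1 <- sheet_of(topology, i + 1L); sj1 <- sheet_of(topology, j + 1L)
        if (si == sj && si1 == sj1 && si != si1 &&
            pair_sheet_adjacent(topology, i, j) &&
            pair_sheet_adjacent(topology, i + 1L, j + 1L)) {
          rows[[length(rows) + 1L]] <- c(i = i, i1 = i + 1L, j = j, j1 = j + 1L)
        }
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    matrix(integer(0), ncol = 4L, dimnames = list(NULL, c("i", "i1", "j", "j1")))
}

#' Sandwich structural invariant
#'
#' `TRUE` iff the topology contains at least one interlock.
#'
#' @param topology An `sss_topology` with exactly two sheets.
#' @return Logical scalar.
#' @export
is_sandwich_invariant <- function(topology) {
  nrow(find_interlocks(topology)) > 0L
}

#' The canonical seven-strand sandwich topology
#'
#' Sheets ordered `1-2-5-4` and `7-6-3`, H-bonds along each sheet; its
#' strandons are `{1,2} {3} {4,5} {6,7}` and its single interlock is
#' `(2,3,5,6)`.
#'
#' @return An `sss_topology`.
#' @export
canonical_sandwich_topology <- function() {
  sss_topology(7L, list(c(1L, 2L, 5L, 4L), c(7L, 6L, 3L)),
               rbind(c(1L, 2L), c(2L, 5L), c(5L, 4L), c(7L, 6L), c(6L, 3L)))
}
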