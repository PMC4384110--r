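#' Strand/loop geometry of the seven-strand sandwich model
#'
#' The skeleton onto which a query sequence is mapped: seven strands of six
#' residues each, six connecting loops, optional N-/C-terminal tails.
#' Within a strand, side chains alternate between the sheet interior and the
#' surface; by default the odd positions (1, 3, 5) face the hydrophobic core
#' and the even positions (2, 4, 6) the surface. `parity = "even-in"` flips
#' this convention globally.
#'
#' @param loop_len_range Allowed length of each individual loop (default 3..16).
#' @param loop_total_range Allowed total length of the six loops (default
#'   30..60); set `enforce_loop_total = FALSE` to drop the total constraint.
#' @param parity `"odd-in"` (positions 1,3,5 hydrophobic, the default) or
#'   `"even-in"`.
#' @param max_n_tail,max_c_tail Maximum residues allowed before strand 1 /
#'   after strand 7 (default unbounded).
#' @param enforce_loop_total Logical.
#' @return An object of class `fold_geometry`.
#' @export
fold_geometry <- function(loop_len_range = c(3L, 16L),
                          loop_total_range = c(30L, 60L),
                          parity = c("odd-in", "even-in"),
                          max_n_tail = Inf, max_c_tail = Inf,
                          enforce_loop_total = TRUE) {
  parity <- match.arg(parity)
  odd <- c(1L, 3L, 5L); even <- c(2L, 4L, 6L)
  g <- structure(list(
    n_strands = 7L,
    strand_length = 6L,
    interlock_strands = c(2L, 3L, 5L, 6L),
    non_interlock_strands = c(1L, 4L, 7L),
    hydrophobic_positions = if (parity == "odd-in") odd else even,
    hydrophilic_positions = if (parity == "odd-in") even else odd,
    parity = parity,
    loop_len_range = as.integer(loop_len_range),
    loop_total_range = as.integer(loop_total_range),
    enforce_loop_total = isTRUE(enforce_loop_total),
    max_n_tail = max_n_tail,
    max_c_tail = max_c_tail
  ), class = "fold_geometry")
  validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  stopifnot(inherits(g, "fold_geometry"))
  if (length(g$loop_len_range) != 2L || g$loop_len_range[1L] > g$loop_len_range[2L] ||
      g$loop_len_range[1L] < 0L) {
    stop("loop_len_range must be a valid [min,max]", call. = FALSE)
  }
  if (length(g$loop_total_range) != 2L ||
      g$loop_total_range[1L] > g$loop_total_range[2L]) {
    stop("loop_total_range must be a valid [min,max]", call. = FALSE)
  }
  if (!setequal(c(g$hydrophobic_positions, g$hydrophilic_positions), 1:6) ||
      length(intersect(g$hydrophobic_positions, g$hydrophilic_positions))) {
    stop("hydrophobic/hydrophilic positions must partition 1..6", call. = FALSE)
  }
  if (g$max_n_tail < 0 || g$max_c_tail < 0) stop("tail caps must be >= 0",
                                                 call. = FALSE)
  invisible(g)
}

# minimal sequence length an assignment can span (strands + minimal loops)
min_span <- function(geometry) {
  tot_min <- max(6L * geometry$loop_len_range[1L],
                 if (geometry$enforce_loop_total) geometry$loop_total_range[1L] else 0L)
  7L * geometry$strand_length + tot_min
}

#' Construct a count-constraint rule
#'
#' A rule counts residues of one class at one face of the strand windows and
#' bounds the counts per strand, over the four interlock strands (2,3,5,6),
#' over the three non-interlock strands (1,4,7), and over all strands.
#' Omitted bounds are unconstrained.
#'
#' @param id Unique rule identifier.
#' @param group Rule group: `"T1"` (hydrophobic-face rules), `"T2"`
#'   (hydrophilic-face rules) or `"T3"` (any-position rules).
#' @param class Residue-class name (see [residue_classes()]) or a character
#'   vector of one-letter codes.
#' @param face `"hydrophobic_positions"`, `"hydrophilic_positions"` or
#'   `"any_position"`.
#' @param per_strand Named list `strand index -> c(min, max)`; missing strands
#'   are unconstrained.
#' @param interlock,non_interlock,all `c(min, max)` bounds for the scope
#'   totals (`NULL` = unconstrained; `Inf` upper bounds allowed).
#' @param provenance Free-text note on where the rule comes from.
#' @return An object of class `fold_rule`.
#' @export
fold_rule <- function(id, group, class, face,
                      per_strand = list(), interlock = NULL,
                      non_interlock = NULL, all = NULL, provenance = "user") {
  face <- match.arg(face, c("hydrophobic_positions", "hydrophilic_positions",
                            "any_position"))
  if (is.character(class) && length(class) == 1L &&
      class %in% names(residue_classes())) {
    members <- residue_classes()[[class]]
    class_name <- class
  } else {
    members <- toupper(as.character(class))
    if (length(members) == 1L && nchar(members) > 1L) {
      members <- strsplit(members, "")[[1]]  # "PG" -> c("P","G")
    }
    class_name <- paste(members, collapse = "")
  }
  bad <- setdiff(members, amino_acids())
  if (length(bad)) stop(sprintf("rule '%s': unknown residue letter(s) %s",
                                id, paste(bad, collapse = ",")), call. = FALSE)
  norm_bound <- function(b, what) {
    if (is.null(b)) return(c(0, Inf))
    b <- as.numeric(b)
    if (length(b) == 1L) b <- c(b, b)
    if (length(b) != 2L || is.na(b[1L]) || b[1L] > b[2L] || b[1L] < 0) {
      stop(sprintf("rule '%s': invalid bound for %s", id, what), call. = FALSE)
    }
    b
  }
  ps <- matrix(rep(c(0, Inf), each = 7L), nrow = 7L,
               dimnames = list(1:7, c("min", "max")))
  for (k in names(per_strand)) {
    ki <- suppressWarnings(as.integer(k))
    if (is.na(ki) || ki < 1L || ki > 7L) {
      stop(sprintf("rule '%s': unknown strand index '%s'", id, k), call. = FALSE)
    }
    ps[ki, ] <- norm_bound(per_strand[[k]], paste0("strand ", k))
  }
  structure(list(id = id, group = match.arg(group, c("T1", "T2", "T3")),
                 class = class_name, members = members, face = face,
                 per_strand = ps,
                 interlock = norm_bound(interlock, "interlock total"),
                 non_interlock = norm_bound(non_interlock, "non-interlock total"),
                 all = norm_bound(all, "all-strands total"),
                 provenance = provenance),
            class = "fold_rule")
}

#' Loop admissibility rules
#'
#' Loops are admitted by a "loop-favorable function": each residue carries an
#' integer weight (Gly and Pro 2; Asp, Asn, His, Ser, Thr 1; all others 0)
#' and the weight sum of a candidate loop fragment must reach
#' `favorability_coefficient` times the fragment length. Additionally each
#' loop must contain fewer strongly hydrophobic residues (Trp, Ile, Phe, Leu,
#' Val, Met) than other residues, and the strongly hydrophobic total over all
#' six loops is capped.
#'
#' @param favorability_weights Named integer vector residue -> weight.
#' @param favorability_coefficient Required weight per residue (default 2,
#'   which with 0/1/2 weights forces loops to be entirely Gly/Pro).
#' @param per_loop_hydrophobic_lt_hydrophilic Enforce the per-loop
#'   strong-hydrophobic minority rule.
#' @param total_loop_hydrophobic_max Cap on strongly hydrophobic residues
#'   summed over all loops (default 12).
#' @return Object of class `fold_loop_rules`.
#' @export
loop_rules <- function(favorability_weights = default_loop_weights(),
                       favorability_coefficient = 2,
                       per_loop_hydrophobic_lt_hydrophilic = TRUE,
                       total_loop_hydrophobic_max = 12) {
  w <- numeric(20); names(w) <- amino_acids()
  bad <- setdiff(names(favorability_weights), amino_acids())
  if (length(bad)) stop(sprintf("unknown residue letter(s) in weights: %s",
                                paste(bad, collapse = ",")), call. = FALSE)
  if (any(favorability_weights < 0)) stop("weights must be non-negative",
                                          call. = FALSE)
  w[names(favorability_weights)] <- favorability_weights
  if (favorability_coefficient <= 0) stop("favorability_coefficient must be > 0",
                                          call. = FALSE)
  structure(list(favorability_weights = w,
                 favorability_coefficient = favorability_coefficient,
                 per_loop_hydrophobic_lt_hydrophilic =
                   isTRUE(per_loop_hydrophobic_lt_hydrophilic),
                 total_loop_hydrophobic_max = total_loop_hydrophobic_max),
            class = "fold_loop_rules")
}

#' @rdname loop_rules
#' @export
default_loop_weights <- function() {
  c(G = 2, P = 2, D = 1, N = 1, H = 1, S = 1, T = 1)
}

#' The default rule set of the sandwich grammar
#'
#' Encodes the 9 hydrophobic-face rules (group T1), the 5 hydrophilic-face
#' rules (group T2) and the 9 any-position rules (group T3), one per table
#' row, plus the loop rules. Bound semantics: an exact cell value means
#' `[v, v]`; a single-sided cell becomes `[v, Inf]` or `[0, v]`. Three
#' documented errata are applied where the prose and the tables disagree
#' (the tables win): the Cys grand total at hydrophobic positions is 2, the
#' Gly grand total at hydrophilic positions is 2 (a subtotal cannot exceed
#' the grand total), and the non-interlock scope of the charged-residue rule
#' is strands 1, 4, 7.
#'
#' @param geometry A [fold_geometry()].
#' @return Object of class `fold_ruleset`.
#' @export
#'
#' @examples
#' rs <- default_ruleset()
#' length(rs$rules)          # 23 strand rules
#' rs$rules[[1]]$interlock   # hydrophobic-face interlock total in [9, 12]
default_ruleset <- function(geometry = fold_geometry()) {
  r <- fold_rule
  rules <- list(
    ## -- group T1: residue content at hydrophobic positions ----------------
    r("t1r1", "T1", "HYDROPHOBIC", "hydrophobic_positions",
      per_strand = list(`2` = 3, `3` = 3, `5` = c(1, 6), `6` = c(1, 6),
                        `1` = c(1, 6), `4` = c(1, 6), `7` = c(1, 6)),
      interlock = c(9, 12), non_interlock = c(4, 6), all = c(13, 17),
      provenance = "hydrophobic-face rules, row 1"),
    r("t1r2", "T1", "STRONG_HYDROPHOBIC", "hydrophobic_positions",
      per_strand = list(`2` = c(1, 6), `3` = c(1, 6), `5` = c(1, 6),
                        `6` = c(1, 6)),
      interlock = c(6, 10), non_interlock = c(2, 5), all = c(8, 15),
      provenance = "hydrophobic-face rules, row 2"),
    r("t1r3", "T1", "ALA", "hydrophobic_positions",
      per_strand = setNames(rep(list(c(0, 1)), 7), 1:7),
      interlock = c(0, 2), non_interlock = c(0, 2), all = c(0, 2),
      provenance = "hydrophobic-face rules, row 3"),
    r("t1r4", "T1", "CYS", "hydrophobic_positions",
      per_strand = setNames(rep(list(c(0, 1)), 7), 1:7),
      interlock = c(0, 2), non_interlock = c(0, 2), all = c(0, 2),
      provenance = "hydrophobic-face rules, row 4; erratum: table max 2 over prose max 3"),
    r("t1r5", "T1", "TYR", "hydrophobic_positions",
      per_strand = setNames(rep(list(c(0, 1)), 7), 1:7),
      interlock = c(0, 1), non_interlock = c(0, 1), all = c(0, 2),
      provenance = "hydrophobic-face rules, row 5"),
    r("t1r6", "T1", "AROMATIC", "hydrophobic_positions",
      per_strand = list(`2` = c(0, 2), `3` = c(0, 2), `5` = c(0, 2),
                        `6` = c(0, 2), `1` = c(0, 1), `4` = c(0, 1),
                        `7` = c(0, 1)),
      interlock = c(0, 3), non_interlock = c(0, 1), all = c(0, 3),
      provenance = "hydrophobic-face rules, row 6"),
    r("t1r7", "T1", "PRO", "hydrophobic_positions",
      per_strand = list(`2` = 0, `3` = 0, `5` = 0, `6` = 0,
                        `1` = c(0, 1), `4` = c(0, 1), `7` = c(0, 1)),
      interlock = c(0, 0), non_interlock = c(0, 1), all = c(0, 1),
      provenance = "hydrophobic-face rules, row 7"),
    r("t1r8", "T1", "GLY", "hydrophobic_positions",
      per_strand = setNames(rep(list(0), 7), 1:7),
      interlock = c(0, 0), non_interlock = c(0, 0), all = c(0, 0),
      provenance = "hydrophobic-face rules, row 8; no Gly at any hydrophobic position"),
    r("t1r9", "T1", "CHARGED", "hydrophobic_positions",
      per_strand = list(`2` = 0, `3` = 0, `5` = c(0, 2), `6` = c(0, 2),
                        `1` = c(0, 2), `4` = c(0, 2), `7` = c(0, 2)),
      interlock = c(0, 2), non_interlock = c(0, 3), all = c(0, 4),
      provenance = "hydrophobic-face rules, row 9; erratum: non-interlock scope is strands 1,4,7"),
    ## -- group T2: residue content at hydrophilic positions ----------------
    r("t2r1", "T2", "HYDROPHILIC", "hydrophilic_positions",
      per_strand = setNames(rep(list(c(1, 6)), 7), 1:7),
      interlock = c(7, 10), non_interlock = c(5, 8), all = c(13, 18),
      provenance = "hydrophilic-face rules, row 1"),
    r("t2r2", "T2", "CHARGED", "hydrophilic_positions",
      interlock = c(0, 5), non_interlock = c(0, 6), all = c(1, 9),
      provenance = "hydrophilic-face rules, row 2"),
    r("t2r3", "T2", "PRO", "hydrophilic_positions",
      per_strand = list(`2` = 0, `3` = 0, `5` = c(0, 1), `6` = 0,
                        `1` = c(0, 1), `4` = c(0, 1), `7` = c(0, 1)),
      interlock = c(0, 1), non_interlock = c(0, 2), all = c(0, 2),
      provenance = "hydrophilic-face rules, row 3"),
    r("t2r4", "T2", "GLY", "hydrophilic_positions",
      per_strand = setNames(rep(list(c(0, 1)), 7), 1:7),
      interlock = c(0, 2), non_interlock = c(0, 1), all = c(0, 2),
      provenance = "hydrophilic-face rules, row 4; erratum: grand total 2 (printed 1 is below the interlock subtotal)"),
    r("t2r5", "T2", "PRO_GLY", "hydrophilic_positions",
      per_strand = setNames(rep(list(c(0, 1)), 7), 1:7),
      interlock = c(0, 3), non_interlock = c(0, 2), all = c(0, 3),
      provenance = "hydrophilic-face rules, row 5"),
    ## -- group T3: residue content at any strand position ------------------
    r("t3r1", "T3", "HYDROPHOBIC", "any_position",
      per_strand = list(`2` = c(3, 6), `3` = c(3, 6), `5` = c(1, 6),
                        `6` = c(2, 6), `1` = c(1, 4), `4` = c(1, 4),
                        `7` = c(1, 4)),
      interlock = c(10, 18), non_interlock = c(5, 9), all = c(17, 26),
      provenance = "any-position rules, row 1"),
    r("t3r2", "T3", "ALA", "any_position",
      per_strand = list(`2` = c(0, 1), `3` = c(0, 1), `5` = c(0, 2),
                        `6` = c(0, 1), `1` = c(0, 2), `4` = c(0, 2),
                        `7` = c(0, 2)),
      interlock = c(0, 3), non_interlock = c(0, 3), all = c(0, 4),
      provenance = "any-position rules, row 2"),
    r("t3r3", "T3", "AROMATIC", "any_position",
      per_strand = list(`2` = c(0, 2), `3` = c(0, 3), `5` = c(0, 2),
                        `6` = c(0, 2), `1` = c(0, 2), `4` = c(0, 1),
                        `7` = c(0, 2)),
      interlock = c(0, 6), non_interlock = c(0, 3), all = c(2, 8),
      provenance = "any-position rules, row 3"),
    r("t3r4", "T3", "HYDROPHILIC", "any_position",
      per_strand = list(`2` = c(1, 6), `3` = c(1, 6), `5` = c(1, 6),
                        `6` = c(1, 6), `1` = c(2, 5), `4` = c(2, 5),
                        `7` = c(2, 5)),
      interlock = c(8, 15), non_interlock = c(9, 13), all = c(18, 27),
      provenance = "any-position rules, row 4"),
    r("t3r5", "T3", "CHARGED", "any_position",
      per_strand = list(`2` = c(0, 2), `3` = c(0, 3), `5` = c(0, 2),
                        `6` = c(0, 2), `1` = c(0, 3), `4` = c(0, 4),
                        `7` = c(0, 4)),
      interlock = c(1, 7), non_interlock = c(1, 7), all = c(1, 12),
      provenance = "any-position rules, row 5"),
    r("t3r6", "T3", "DISRUPTOR5", "any_position",
      per_strand = list(`2` = c(0, 1), `3` = c(0, 3), `5` = c(0, 2),
                        `6` = c(0, 2), `1` = c(0, 2), `4` = c(0, 4),
                        `7` = c(0, 4)),
      interlock = c(0, 5), non_interlock = c(2, 6), all = c(2, 10),
      provenance = "any-position rules, row 6"),
    r("t3r7", "T3", "PRO", "any_position",
      per_strand = list(`2` = 0, `3` = 0, `5` = c(0, 1), `6` = 0,
                        `1` = c(0, 2), `4` = c(0, 2), `7` = c(0, 1)),
      interlock = c(0, 1), non_interlock = c(0, 3), all = c(0, 3),
      provenance = "any-position rules, row 7"),
    r("t3r8", "T3", "GLY", "any_position",
      per_strand = setNames(rep(list(c(0, 1)), 7), 1:7),
      interlock = c(0, 2), non_interlock = c(0, 1), all = c(0, 2),
      provenance = "any-position rules, row 8"),
    r("t3r9", "T3", "PRO_GLY_ALA", "any_position",
      per_strand = list(`2` = c(0, 2), `3` = c(0, 1), `5` = c(0, 2),
                        `6` = c(0, 1), `1` = c(0, 3), `4` = c(0, 2),
                        `7` = c(0, 2)),
      interlock = c(0, 4), non_interlock = c(1, 5), all = c(0, 6),
      provenance = "any-position rules, row 9")
  )
  new_ruleset(geometry, rules, loop_rules(), loop_rules_enabled = TRUE,
              provenance = "default")
}

new_ruleset <- function(geometry, rules, loop_rules, loop_rules_enabled = TRUE,
                        provenance = "default") {
  names(rules) <- vapply(rules, `[[`, character(1), "id")
  rs <- structure(list(geometry = geometry, rules = rules,
                       loop_rules = loop_rules,
                       loop_rules_enabled = isTRUE(loop_rules_enabled),
                       provenance = provenance),
                  class = "fold_ruleset")
  validate_ruleset(rs)
  rs
}

validate_ruleset <- function(rs) {
  stopifnot(inherits(rs, "fold_ruleset"))
  validate_geometry(rs$geometry)
  ids <- vapply(rs$rules, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate rule ids", call. = FALSE)
  for (r in rs$rules) {
    if (!inherits(r, "fold_rule")) stop("rules must be fold_rule objects",
                                        call. = FALSE)
  }
  if (!inherits(rs$loop_rules, "fold_loop_rules")) {
    stop("loop_rules must be a fold_loop_rules object", call. = FALSE)
  }
  invisible(rs)
}

#' @export
print.fold_ruleset <- function(x, ...) {
  grp <- table(vapply(x$rules, `[[`, character(1), "group"))
  cat(sprintf("fold_ruleset (%s): %d strand rules (%s)%s\n",
              x$provenance, length(x$rules),
              paste(sprintf("%s: %d", names(grp), grp), collapse = ", "),
              if (x$loop_rules_enabled) " + loop rules" else ", loop rules off"))
  invisible(x)
}

#' Rule groups of a rule set
#'
#' @param ruleset A `fold_ruleset`.
#' @return Named list mapping group name (`T1`, `T2`, `T3`, `LOOPS`) to rule ids.
#' @export
rule_groups <- function(ruleset) {
  grp <- split(names(ruleset$rules),
               vapply(ruleset$rules, `[[`, character(1), "group"))
  if (ruleset$loop_rules_enabled) grp$LOOPS <- "loop_rules"
  grp
}

#' Restrict a rule set to chosen rule groups
#'
#' @param ruleset A `fold_ruleset`.
#' @param groups Character vector drawn from `T1`, `T2`, `T3`, `LOOPS`.
#' @return A `fold_ruleset` containing only the requested groups (geometry
#'   unchanged).
#' @export
subset_ruleset <- function(ruleset, groups) {
  validate_ruleset(ruleset)
  bad <- setdiff(groups, c("T1", "T2", "T3", "LOOPS"))
  if (length(bad)) stop(sprintf("unknown rule group(s): %s",
                                paste(bad, collapse = ",")), call. = FALSE)
  keep <- vapply(ruleset$rules, function(r) r$group %in% groups, logical(1))
  new_ruleset(ruleset$geometry, ruleset$rules[keep], ruleset$loop_rules,
              loop_rules_enabled = ruleset$loop_rules_enabled &&
                "LOOPS" %in% groups,
              provenance = sprintf("%s[%s]", ruleset$provenance,
                                   paste(groups, collapse = "+")))
}

#' Load a rule-set override document
#'
#' Reads a JSON document (file path or pre-parsed list) that overrides parts
#' of the default rule set. Recognised top-level keys:
#' \describe{
#'   \item{geometry}{any arguments of [fold_geometry()]}
#'   \item{loop_rules}{any arguments of [loop_rules()]}
#'   \item{rules}{list of entries with an `id`; an existing id patches that
#'     rule's `per_strand` / `interlock` / `non_interlock` / `all` bounds, a
#'     new id adds a rule (requires `group`, `class`, `face`)}
#'   \item{drop_rules}{character vector of rule ids to remove}
#'   \item{groups}{restrict to these rule groups}
#' }
#' An empty document yields [default_ruleset()]. Bounds are `[min, max]`
#' pairs with `min <= max`.
#'
#' @param doc File path or list.
#' @return A validated `fold_ruleset` with provenance `"user"`.
#' @export
load_ruleset <- function(doc = list()) {
  if (is.character(doc) && length(doc) == 1L) {
    doc <- jsonlite::fromJSON(doc, simplifyVector = FALSE)
  }
  stopifnot(is.list(doc))
  geo_args <- doc$geometry %||% list()
  for (k in c("loop_len_range", "loop_total_range")) {
    if (!is.null(geo_args[[k]])) geo_args[[k]] <- unlist(geo_args[[k]])
  }
  geometry <- do.call(fold_geometry, geo_args)
  rs <- default_ruleset(geometry)
  if (!is.null(doc$loop_rules)) {
    lr_args <- doc$loop_rules
    if (!is.null(lr_args$favorability_weights)) {
      lr_args$favorability_weights <- unlist(lr_args$favorability_weights)
    }
    cur <- rs$loop_rules
    defaults <- list(favorability_weights = cur$favorability_weights,
                     favorability_coefficient = cur$favorability_coefficient,
                     per_loop_hydrophobic_lt_hydrophilic =
                       cur$per_loop_hydrophobic_lt_hydrophilic,
                     total_loop_hydrophobic_max = cur$total_loop_hydrophobic_max)
    bad <- setdiff(names(lr_args), names(defaults))
    if (length(bad)) stop(sprintf("unknown loop_rules field(s): %s",
                                  paste(bad, collapse = ",")), call. = FALSE)
    defaults[names(lr_args)] <- lr_args
    rs$loop_rules <- do.call(loop_rules, defaults)
  }
  rules <- rs$rules
  for (entry in doc$rules %||% list()) {
    if (is.null(entry$id)) stop("rule override without an 'id'", call. = FALSE)
    tidy <- function(x) if (is.null(x)) NULL else unlist(x)
    if (entry$id %in% names(rules)) {
      old <- rules[[entry$id]]
      ps_old <- apply(old$per_strand, 1L, function(b) c(b[1L], b[2L]),
                      simplify = FALSE)
      names(ps_old) <- 1:7
      ps_new <- lapply(entry$per_strand %||% list(), tidy)
      ps_old[names(ps_new)] <- ps_new
      rules[[entry$id]] <- fold_rule(
        old$id, old$group, old$members, old$face, per_strand = ps_old,
        interlock = tidy(entry$interlock) %||% old$interlock,
        non_interlock = tidy(entry$non_interlock) %||% old$non_interlock,
        all = tidy(entry$all) %||% old$all,
        provenance = paste0(old$provenance, "; user override"))
    } else {
      for (k in c("group", "class", "face")) {
        if (is.null(entry[[k]])) {
          stop(sprintf("new rule '%s' lacks field '%s'", entry$id, k),
               call. = FALSE)
        }
      }
      rules[[entry$id]] <- fold_rule(
        entry$id, entry$group, unlist(entry$class), entry$face,
        per_strand = lapply(entry$per_strand %||% list(), tidy),
        interlock = tidy(entry$interlock),
        non_interlock = tidy(entry$non_interlock), all = tidy(entry$all),
        provenance = "user")
    }
  }
  if (!is.null(doc$drop_rules)) {
    drop <- unlist(doc$drop_rules)
    miss <- setdiff(drop, names(rules))
    if (length(miss)) stop(sprintf("drop_rules: unknown id(s) %s",
                                   paste(miss, collapse = ",")), call. = FALSE)
    rules <- rules[setdiff(names(rules), drop)]
  }
  rs <- new_ruleset(geometry, rules, rs$loop_rules,
                    loop_rules_enabled = rs$loop_rules_enabled,
                    provenance = if (length(doc)) "user" else "default")
  if (!is.null(doc$groups)) rs <- subset_ruleset(rs, unlist(doc$groups))
  rs
}

#' Serialize a rule set (with provenance notes) to JSON
#'
#' @param ruleset A `fold_ruleset`.
#' @param path Output path, or `NULL` to return the JSON string.
#' @export
dump_ruleset <- function(ruleset, path = NULL) {
  validate_ruleset(ruleset)
  enc_bound <- function(b) if (is.infinite(b[2L])) list(b[1L], "Inf") else
    list(b[1L], b[2L])
  rules <- lapply(unname(ruleset$rules), function(r) {
    ps <- apply(r$per_strand, 1L, enc_bound, simplify = FALSE)
    names(ps) <- 1:7
    list(id = r$id, group = r$group, class = r$class,
         members = paste(r$members, collapse = ""), face = r$face,
         per_strand = ps, interlock = enc_bound(r$interlock),
         non_interlock = enc_bound(r$non_interlock), all = enc_bound(r$all),
         provenance = r$provenance)
  })
  g <- ruleset$geometry
  doc <- list(
    provenance = ruleset$provenance,
    geometry = list(loop_len_range = g$loop_len_range,
                    loop_total_range = g$loop_total_range,
                    parity = g$parity,
                    enforce_loop_total = g$enforce_loop_total),
    rules = rules,
    loop_rules = list(
      favorability_weights = as.list(
        ruleset$loop_rules$favorability_weights[
          ruleset$loop_rules$favorability_weights > 0]),
      favorability_coefficient = ruleset$loop_rules$favorability_coefficient,
      per_loop_hydrophobic_lt_hydrophilic =
        ruleset$loop_rules$per_loop_hydrophobic_lt_hydrophilic,
      total_loop_hydrophobic_max = ruleset$loop_rules$total_loop_hydrophobic_max),
    loop_rules_enabled = ruleset$loop_rules_enabled)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' Provenance hash of a rule set
#'
#' A short deterministic fingerprint of the serialized rule set, logged by
#' the command-line tools so that reports record which rules produced them.
#'
#' @param ruleset A `fold_ruleset`.
#' @return Character scalar.
#' @export
ruleset_hash <- function(ruleset) {
  txt <- as.character(dump_ruleset(ruleset))
  bytes <- utf8ToInt(txt)
  h <- 0
  for (chunk in split(bytes, ceiling(seq_along(bytes) / 1024L))) {
    h <- (h * 31 + sum(chunk * seq_along(chunk))) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
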