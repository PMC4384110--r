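#' Sensitivity/specificity of a rule set on a labelled sequence set
#'
#' Classifies every record with [fold_search()] and summarizes the confusion
#' counts. `label = "random"` records are treated as negatives when
#' `random_as = "negative"` (the default), mirroring the use of background
#' sets as presumed non-members.
#'
#' @param records Data frame with columns `id`, `seq`, or a `fold_benchmark`.
#' @param labels Character vector of labels (`positive` / `negative` /
#'   `random`) aligned with `records`; ignored when `records` is a benchmark.
#' @param ruleset A `fold_ruleset`.
#' @param params A [search_params()].
#' @param random_as How to treat `random` labels: `"negative"` or `"error"`.
#' @return Object of class `confusion_summary`: counts `tp`, `fn`, `fp`,
#'   `tn`, rates `sensitivity`, `specificity` (`NA` when undefined), the
#'   accepted record ids, and a per-group breakdown when group annotations
#'   are present.
#' @export
evaluate_classifier <- function(records, labels = NULL,
                                ruleset = default_ruleset(),
                                params = search_params(),
                                random_as = c("negative", "error")) {
  random_as <- match.arg(random_as)
  groups <- NULL
  if (inherits(records, "fold_benchmark")) {
    labels <- records$truth$label
    groups <- records$truth$group
    records <- data.frame(
      id = vapply(records$records, `[[`, character(1), "id"),
      seq = vapply(records$records, `[[`, character(1), "sequence"),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(records), nrow(records) == length(labels))
  if (any(is.na(labels) | !labels %in% c("positive", "negative", "random"))) {
    stop("every record needs a label in {positive, negative, random}",
         call. = FALSE)
  }
  if (any(labels == "random")) {
    if (random_as == "error") stop("unlabelled (random) records present",
                                   call. = FALSE)
    labels[labels == "random"] <- "negative"
  }
  decisions <- classify_batch(records, ruleset, params)
  acc <- vapply(decisions, function(d) isTRUE(d$accepted), logical(1))
  pos <- labels == "positive"
  tp <- sum(acc & pos); fn <- sum(!acc & pos)
  fp <- sum(acc & !pos); tn <- sum(!acc & !pos)
  sens <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  by_group <- NULL
  if (!is.null(groups) && any(!is.na(groups))) {
    by_group <- do.call(rbind, lapply(split(seq_along(groups),
                                            groups), function(ix) {
      data.frame(n = length(ix), rejected = sum(!acc[ix]),
                 stringsAsFactors = FALSE)
    }))
    by_group$group <- rownames(by_group)
    rownames(by_group) <- NULL
  }
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn,
                 sensitivity = sens, specificity = spec,
                 accepted_ids = records$id[acc], by_group = by_group,
                 n = nrow(records)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf(
    "confusion_summary: n=%d TP=%d FN=%d FP=%d TN=%d sens=%s spec=%s\n",
    x$n, x$tp, x$fn, x$fp, x$tn,
    ifelse(is.na(x$sensitivity), "n/a", sprintf("%.3f", x$sensitivity)),
    ifelse(is.na(x$specificity), "n/a", sprintf("%.3f", x$specificity))))
  invisible(x)
}

#' The six rule-ablation presets
#'
#' Mirrors the published sensitivity/specificity experiment: (1) the full
#' rule set; (2) the any-position rules alone; (3) hydrophilic-face +
#' any-position; (4) hydrophobic-face + any-position; (5) hydrophobic-face
#' alone; (6) the full set with the strand-2/3 hydrophobic-face requirement
#' relaxed from exactly 3 to at most 2 while keeping the interlock total at
#' no less than 9.
#'
#' @param ruleset Base rule set (default [default_ruleset()]).
#' @return Named list of `fold_ruleset` objects with attribute
#'   `"description"` on each element.
#' @export
ablation_presets <- function(ruleset = default_ruleset()) {
  relaxed <- ruleset
  r <- relaxed$rules[["t1r1"]]
  stopifnot(!is.null(r))
  ps <- apply(r$per_strand, 1L, function(b) c(b[1L], b[2L]), simplify = FALSE)
  names(ps) <- 1:7
  ps[["2"]] <- c(0, 2)
  ps[["3"]] <- c(0, 2)
  relaxed$rules[["t1r1"]] <- fold_rule(
    r$id, r$group, r$members, r$face, per_strand = ps,
    interlock = r$interlock, non_interlock = r$non_interlock, all = r$all,
    provenance = paste0(r$provenance,
                        "; ablation: strands 2,3 relaxed to <=2, interlock total kept >=9"))
  relaxed$provenance <- paste0(ruleset$provenance, "[relaxed23]")
  presets <- list(
    all      = ruleset,
    T3_only  = subset_ruleset(ruleset, "T3"),
    T2_T3    = subset_ruleset(ruleset, c("T2", "T3")),
    T1_T3    = subset_ruleset(ruleset, c("T1", "T3")),
    T1_only  = subset_ruleset(ruleset, "T1"),
    relaxed23 = relaxed
  )
  descr <- c(
    all = "all rule groups (T1 + T2 + T3 + loop rules)",
    T3_only = "any-position rules only",
    T2_T3 = "hydrophilic-face + any-position rules",
    T1_T3 = "hydrophobic-face + any-position rules",
    T1_only = "hydrophobic-face rules only",
    relaxed23 = "all groups; strands 2,3 hydrophobic-face bound relaxed to [0,2]")
  for (nm in names(presets)) attr(presets[[nm]], "description") <- descr[[nm]]
  presets
}

#' Run the rule-ablation experiment
#'
#' Evaluates every preset on the same labelled set and tabulates the
#' confusion counts, keeping the accepted-id sets so that nestedness between
#' presets can be checked.
#'
#' @param records Data frame (`id`, `seq`) or `fold_benchmark`.
#' @param labels Labels aligned with `records` (unless a benchmark is given).
#' @param presets Named list of rule sets (default [ablation_presets()]).
#' @param params A [search_params()].
#' @return Object of class `ablation_result`: `table` (one row per preset)
#'   and `accepted` (named list of accepted id vectors).
#' @export
run_ablation <- function(records, labels = NULL, presets = ablation_presets(),
                         params = search_params()) {
  rows <- list()
  accepted <- list()
  for (nm in names(presets)) {
    cs <- evaluate_classifier(records, labels, presets[[nm]], params)
    rows[[nm]] <- data.frame(
      preset = nm, n = cs$n, accepted = length(cs$accepted_ids),
      tp = cs$tp, fn = cs$fn, fp = cs$fp, tn = cs$tn,
      sensitivity = round(cs$sensitivity, 3),
      specificity = round(cs$specificity, 3),
      stringsAsFactors = FALSE)
    accepted[[nm]] <- cs$accepted_ids
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 accepted = accepted),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' Fit empirical count bounds from annotated positives
#'
#' The bound-recovery primitive of the iterative rule-fitting procedure:
#' given sequences with known (true) strand assignments, record the observed
#' minimum and maximum count for every descriptor and scope, and assemble a
#' candidate rule set from those bounds. On positives generated from a rule
#' set, every fitted interval is contained in the generating rule's interval.
#'
#' @param annotated List of `annotated_sequence` records, each carrying a
#'   `true_assignment`.
#' @param ruleset Rule set whose descriptors (and ids/groups) the candidate
#'   rules inherit (default [default_ruleset()]).
#' @return Object of class `fitted_bounds`: `bounds` (data frame with one
#'   row per rule and scope: observed `min`, `max`) and `ruleset` (candidate
#'   `fold_ruleset` built from the fitted bounds).
#' @export
fit_bounds <- function(annotated, ruleset = default_ruleset()) {
  if (length(annotated) == 0L) stop("need at least one annotated record",
                                    call. = FALSE)
  for (r in annotated) {
    if (is.null(r$true_assignment)) {
      stop(sprintf("record '%s' lacks a true assignment", r$id), call. = FALSE)
    }
  }
  g <- ruleset$geometry
  # counts[[record]][[class|face]] = count_feature output
  rows <- list()
  fitted_rules <- list()
  counts_all <- lapply(annotated, function(rec) {
    res <- split_residues(rec$sequence, warn = FALSE)
    cache <- list()
    for (r in ruleset$rules) {
      key <- paste(r$class, r$face, sep = "|")
      if (is.null(cache[[key]])) {
        cache[[key]] <- count_feature(res, rec$true_assignment, r$members,
                                      r$face, g)
      }
    }
    cache
  })
  for (r in ruleset$rules) {
    key <- paste(r$class, r$face, sep = "|")
    per <- sapply(counts_all, function(c) c[[key]]$per_strand)  # 7 x n
    ti <- vapply(counts_all, function(c) c[[key]]$interlock, numeric(1))
    tn <- vapply(counts_all, function(c) c[[key]]$non_interlock, numeric(1))
    ta <- vapply(counts_all, function(c) c[[key]]$all, numeric(1))
    ps <- lapply(1:7, function(k) c(min(per[k, ]), max(per[k, ])))
    names(ps) <- 1:7
    fitted_rules[[r$id]] <- fold_rule(
      r$id, r$group, r$members, r$face, per_strand = ps,
      interlock = c(min(ti), max(ti)), non_interlock = c(min(tn), max(tn)),
      all = c(min(ta), max(ta)),
      provenance = sprintf("fitted from %d annotated positives",
                           length(annotated)))
    for (k in 1:7) {
      rows[[length(rows) + 1L]] <- data.frame(
        rule_id = r$id, class = r$class, face = r$face,
        scope = paste0("strand_", k), min = min(per[k, ]), max = max(per[k, ]),
        stringsAsFactors = FALSE)
    }
    for (sc in c("interlock", "non_interlock", "all")) {
      v <- switch(sc, interlock = ti, non_interlock = tn, all = ta)
      rows[[length(rows) + 1L]] <- data.frame(
        rule_id = r$id, class = r$class, face = r$face, scope = sc,
        min = min(v), max = max(v), stringsAsFactors = FALSE)
    }
  }
  structure(list(
    bounds = do.call(rbind, c(rows, make.row.names = FALSE)),
    ruleset = new_ruleset(g, fitted_rules, ruleset$loop_rules,
                          loop_rules_enabled = ruleset$loop_rules_enabled,
                          provenance = "fitted")),
    class = "fitted_bounds")
}
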