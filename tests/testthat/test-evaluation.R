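test_that("evaluate_classifier summarizes confusion counts correctly", {
  pos <- lapply(1:5, function(i) generate_positive(i + 40))
  neg <- lapply(1:5, function(i) {
    generate_negative(c("GEOMETRY", "T1", "T2", "T3", "LOOPS")[i], i + 40)
  })
  records <- data.frame(
    id = c(sprintf("p%d", 1:5), sprintf("n%d", 1:5)),
    seq = c(vapply(pos, `[[`, character(1), "sequence"),
            vapply(neg, `[[`, character(1), "sequence")),
    stringsAsFactors = FALSE)
  labels <- rep(c("positive", "negative"), each = 5)
  cs <- evaluate_classifier(records, labels)
  expect_equal(cs$tp, 5)
  expect_equal(cs$tn, 5)
  expect_equal(cs$sensitivity, 1)
  expect_equal(cs$specificity, 1)

  # record order invariance
  ord <- c(7, 2, 9, 1, 4, 10, 3, 6, 5, 8)
  cs2 <- evaluate_classifier(records[ord, ], labels[ord])
  expect_equal(cs2$tp, cs$tp)
  expect_equal(cs2$specificity, cs$specificity)
  expect_setequal(cs2$accepted_ids, cs$accepted_ids)

  # empty set: counts 0, rates not applicable
  cs0 <- evaluate_classifier(records[0, ], character(0))
  expect_equal(cs0$tp + cs0$fn + cs0$fp + cs0$tn, 0)
  expect_true(is.na(cs0$sensitivity))
  expect_true(is.na(cs0$specificity))

  # an impossible added rule drives sensitivity to zero
  rs <- default_ruleset()
  rs$rules[["impossible"]] <- fold_rule("impossible", "T1", "TYR",
                                        "hydrophobic_positions",
                                        per_strand = list(`1` = c(3, 3)))
  cs3 <- evaluate_classifier(records, labels, rs)
  expect_equal(cs3$sensitivity, 0)

  expect_error(evaluate_classifier(records, rep("weird", 10)), "label")
})

test_that("ablation presets mirror the published experiment design", {
  pres <- ablation_presets()
  expect_named(pres, c("all", "T3_only", "T2_T3", "T1_T3", "T1_only",
                       "relaxed23"))
  expect_identical(dump_ruleset(pres$all), dump_ruleset(default_ruleset()))

  grp <- function(rs) unique(vapply(rs$rules, `[[`, character(1), "group"))
  expect_identical(grp(pres$T3_only), "T3")
  expect_false(pres$T3_only$loop_rules_enabled)
  expect_setequal(grp(pres$T2_T3), c("T2", "T3"))
  expect_setequal(grp(pres$T1_T3), c("T1", "T3"))
  expect_identical(grp(pres$T1_only), "T1")

  # preset 6 differs from the full set only in the strand-2/3 bounds
  r6 <- pres$relaxed23$rules[["t1r1"]]
  expect_equal(unname(r6$per_strand["2", ]), c(0, 2))
  expect_equal(unname(r6$per_strand["3", ]), c(0, 2))
  expect_equal(r6$interlock, c(9, 12))  # interlock total kept >= 9
  others <- setdiff(names(pres$relaxed23$rules), "t1r1")
  for (id in others) {
    expect_identical(pres$relaxed23$rules[[id]], default_ruleset()$rules[[id]])
  }
})

test_that("run_ablation reproduces nestedness and the strand-2/3 effect", {
  pos <- lapply(1:6, function(i) generate_positive(i + 900))
  rnd <- lapply(1:12, function(i) generate_random(i + 900, 100))
  records <- data.frame(
    id = c(sprintf("p%d", 1:6), sprintf("r%d", 1:12)),
    seq = c(vapply(pos, `[[`, character(1), "sequence"),
            vapply(rnd, `[[`, character(1), "sequence")),
    stringsAsFactors = FALSE)
  labels <- c(rep("positive", 6), rep("random", 12))
  res <- run_ablation(records, labels)
  expect_identical(res$table$preset,
                   c("all", "T3_only", "T2_T3", "T1_T3", "T1_only",
                     "relaxed23"))
  # subset-ordered rule sets give superset-ordered accepted sets
  expect_true(all(res$accepted$all %in% res$accepted$T2_T3))
  expect_true(all(res$accepted$T2_T3 %in% res$accepted$T3_only))
  expect_true(all(res$accepted$T1_T3 %in% res$accepted$T3_only))
  expect_true(all(res$accepted$T1_T3 %in% res$accepted$T1_only))
  # positives built with exactly 3 hydrophobic in strands 2,3 all fail preset 6
  expect_equal(res$table$sensitivity[res$table$preset == "relaxed23"], 0)
  expect_equal(res$table$sensitivity[res$table$preset == "all"], 1)
})

test_that("fit_bounds recovers intervals nested in the generating bounds", {
  pos <- lapply(1:25, function(i) generate_positive(i + 2000))
  fb <- fit_bounds(pos)
  rs <- default_ruleset()
  for (r in rs$rules) {
    f <- fb$ruleset$rules[[r$id]]
    expect_true(all(f$per_strand[, 1] >= r$per_strand[, 1]))
    expect_true(all(f$per_strand[, 2] <= r$per_strand[, 2]))
    expect_gte(f$interlock[1], r$interlock[1])
    expect_lte(f$interlock[2], r$interlock[2])
    expect_gte(f$all[1], r$all[1])
    expect_lte(f$all[2], r$all[2])
  }
  # the generator never places Gly inside strands
  gly <- fb$bounds[fb$bounds$rule_id == "t3r8" & fb$bounds$scope == "all", ]
  expect_equal(c(gly$min, gly$max), c(0, 0))

  # single record: min = max = observed
  fb1 <- fit_bounds(pos[1])
  expect_true(all(fb1$bounds$min == fb1$bounds$max))

  expect_error(fit_bounds(list()), "at least one")
  expect_error(fit_bounds(list(generate_random(1, 100))), "true assignment")
})
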