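test_that("default rule set encodes one rule per table row with the errata", {
  rs <- default_ruleset()
  grp <- vapply(rs$rules, `[[`, character(1), "group")
  expect_equal(sum(grp == "T1"), 9)
  expect_equal(sum(grp == "T2"), 5)
  expect_equal(sum(grp == "T3"), 9)
  expect_length(rs$rules, 23)
  expect_false(anyDuplicated(names(rs$rules)) > 0)
  # every rule carries a provenance anchor
  expect_true(all(nzchar(vapply(rs$rules, `[[`, character(1), "provenance"))))

  r1 <- rs$rules[["t1r1"]]
  expect_equal(unname(r1$per_strand["2", ]), c(3, 3))
  expect_equal(unname(r1$per_strand["3", ]), c(3, 3))
  expect_equal(unname(r1$per_strand["5", ]), c(1, 6))
  expect_equal(r1$interlock, c(9, 12))
  expect_equal(r1$non_interlock, c(4, 6))
  expect_equal(r1$all, c(13, 17))

  # no Gly at any hydrophobic position
  g <- rs$rules[["t1r8"]]
  expect_equal(g$all, c(0, 0))
  expect_equal(unname(g$per_strand[, 2]), rep(0, 7))

  # aromatic any-position grand total in [2, 8]
  expect_equal(rs$rules[["t3r3"]]$all, c(2, 8))

  # errata: Cys grand total 2 (table over prose)
  expect_equal(rs$rules[["t1r4"]]$all, c(0, 2))
  # errata: Gly hydrophilic-face grand total 2 (>= interlock subtotal)
  expect_equal(rs$rules[["t2r4"]]$all, c(0, 2))
  expect_equal(rs$rules[["t2r4"]]$interlock, c(0, 2))
  # errata: charged-residue non-interlock scope is strands 1,4,7
  ch <- rs$rules[["t1r9"]]
  expect_equal(unname(ch$per_strand["2", ]), c(0, 0))
  expect_equal(unname(ch$per_strand["3", ]), c(0, 0))
  expect_equal(unname(ch$per_strand["1", 2]), 2)
  expect_equal(unname(ch$per_strand["4", 2]), 2)
  expect_equal(unname(ch$per_strand["7", 2]), 2)
  expect_equal(ch$non_interlock, c(0, 3))

  # loop rules: weights and thresholds
  lr <- rs$loop_rules
  expect_equal(unname(lr$favorability_weights[c("G", "P")]), c(2, 2))
  expect_equal(unname(lr$favorability_weights[c("D", "N", "H", "S", "T")]),
               rep(1, 5))
  expect_equal(sum(lr$favorability_weights), 9)
  expect_equal(lr$favorability_coefficient, 2)
  expect_equal(lr$total_loop_hydrophobic_max, 12)
})

test_that("built-in residue classes are exactly as defined", {
  rc <- residue_classes()
  expect_setequal(rc$HYDROPHOBIC, strsplit("WIFLCVMAY", "")[[1]])
  expect_setequal(rc$STRONG_HYDROPHOBIC, strsplit("WIFLVM", "")[[1]])
  expect_setequal(rc$HYDROPHILIC, strsplit("QERTSYDHKN", "")[[1]])
  expect_setequal(rc$CHARGED, strsplit("DERKH", "")[[1]])
  expect_setequal(rc$DISRUPTOR5, strsplit("PGNDE", "")[[1]])
})

test_that("count_feature counts memberships at the right face", {
  a <- fold_assignment(seq(0, 66, by = 11), 72)
  wp <- worked_positive()

  # single-window checks on a synthetic strand
  one <- fold_assignment(c(0, 9, 18, 27, 36, 45, 54), 60,
                         fold_geometry(enforce_loop_total = FALSE))
  seq1 <- paste(rep("VQVQVQ", 7), collapse = "QQQ")
  cnt <- count_feature(seq1, one, "HYDROPHOBIC", "hydrophobic_positions",
                       fold_geometry(enforce_loop_total = FALSE))
  expect_equal(cnt$per_strand, rep(3L, 7))

  cnt2 <- count_feature(paste0("VQVASQ", strrep("Q", 66)),
                        fold_assignment(c(0, 9, 18, 27, 36, 45, 54), 72),
                        "HYDROPHILIC", "hydrophilic_positions")
  expect_equal(cnt2$per_strand[1], 2L)  # Q,Q count; A does not

  # frozen worked-example counts (verified by an independent recount)
  cw <- count_feature(wp$sequence, a, "HYDROPHOBIC", "hydrophobic_positions")
  expect_equal(cw$per_strand, c(2L, 3L, 3L, 1L, 3L, 3L, 1L))
  expect_equal(cw$interlock, 12L)
  expect_equal(cw$non_interlock, 4L)
  expect_equal(cw$all, 16L)
})

test_that("count_feature agrees with a naive per-residue scan", {
  rc <- residue_classes()
  for (seed in 1:12) {
    case <- random_case(seed)
    for (cls in c("HYDROPHOBIC", "CHARGED", "GLY", "PRO_GLY_ALA")) {
      for (face in c("hydrophobic_positions", "hydrophilic_positions",
                     "any_position")) {
        got <- count_feature(case$sequence, case$assignment, cls, face)
        want <- oracle_count(case$sequence, case$assignment$strand_starts,
                             rc[[cls]], face)
        expect_equal(got$per_strand, want$per_strand)
        expect_equal(got$all, want$all)
        # conservation: interlock + non-interlock = all
        expect_equal(got$interlock + got$non_interlock, got$all)
      }
    }
  }
})

test_that("evaluate_rule reports violated bounds per scope", {
  rs <- default_ruleset()
  zero <- list(per_strand = rep(0L, 7), interlock = 0L, non_interlock = 0L,
               all = 0L)
  expect_identical(nrow(evaluate_rule(zero, rs$rules[["t1r8"]])), 0L)

  low <- list(per_strand = c(0L, 2L, 3L, 1L, 3L, 3L, 1L), interlock = 11L,
              non_interlock = 4L, all = 15L)
  v <- evaluate_rule(low, rs$rules[["t1r1"]])
  expect_true(any(v$scope == "strand_2" & v$observed == 2))
  expect_true(any(v$scope == "strand_1"))

  high <- list(per_strand = c(1L, 1L, 1L, 0L, 1L, 1L, 0L), interlock = 4L,
               non_interlock = 1L, all = 5L)
  v2 <- evaluate_rule(high, rs$rules[["t3r2"]])
  expect_true(any(v2$scope == "all" & v2$observed == 5))
})

test_that("loop favorability and loop checks follow the definitions", {
  expect_equal(loop_favorable_value("GPGPG"), 10)
  expect_equal(loop_favorable_value("DNST"), 4)
  expect_equal(loop_favorable_value("AAAA"), 0)

  wp <- worked_positive()
  expect_identical(nrow(check_loops(wp$sequence, wp$assignment)), 0L)

  # a strongly hydrophobic loop: favorability + majority violations
  bad <- paste0(substr(wp$sequence, 1, 6), "LVLVL",
                substr(wp$sequence, 12, 72))
  v <- check_loops(bad, wp$assignment)
  expect_true(any(v$rule_id == "loop_favorability" & v$scope == "loop_1"))
  expect_true(any(v$rule_id == "loop_hydrophobic_majority" &
                    v$scope == "loop_1"))

  # total loop length 29 < 30
  short <- fold_assignment(c(0, 11, 22, 33, 44, 55, 65), 71)
  sseq <- paste0(substr(wp$sequence, 1, 60), substr(wp$sequence, 62, 72))
  v2 <- check_loops(sseq, short)
  expect_true(any(v2$rule_id == "loop_total_length" & v2$observed == 29))
})

test_that("check_assignment accepts the worked fixture and flags mutations", {
  wp <- worked_positive()
  expect_true(check_assignment(wp$sequence, wp$assignment)$satisfied)

  shifted <- fold_assignment(c(0, 12, 22, 33, 44, 55, 66), 72)
  rep_s <- check_assignment(wp$sequence, shifted)
  expect_false(rep_s$satisfied)
  expect_true(any(rep_s$violations$rule_id %in% c("t1r1", "t1r2")))

  polyg <- strrep("G", 72)
  rep_g <- check_assignment(polyg, wp$assignment)
  expect_false(rep_g$satisfied)
  expect_true(any(rep_g$violations$rule_id == "t1r8"))
  expect_true(any(rep_g$violations$rule_id == "t3r8"))
})

test_that("adding rules never removes violations", {
  extra <- fold_rule("impossible", "T3", "TYR", "any_position",
                     all = c(7, 7))
  rs <- default_ruleset()
  rs_plus <- rs
  rs_plus$rules <- c(rs$rules, list(impossible = extra))
  for (seed in 1:8) {
    case <- random_case(seed + 50)
    v0 <- check_assignment(case$sequence, case$assignment, rs)$violations
    v1 <- check_assignment(case$sequence, case$assignment, rs_plus)$violations
    key <- function(v) paste(v$rule_id, v$scope)
    expect_true(all(key(v0) %in% key(v1)))
    expect_gte(nrow(v1), nrow(v0))
  }
})

test_that("load_ruleset validates and inherits defaults", {
  expect_identical(dump_ruleset(load_ruleset(list())),
                   dump_ruleset(default_ruleset()))

  over <- load_ruleset(list(loop_rules = list(favorability_coefficient = 0.5)))
  expect_equal(over$loop_rules$favorability_coefficient, 0.5)
  expect_identical(length(over$rules), 23L)

  expect_error(load_ruleset(list(rules = list(list(id = "t1r1",
                                                   all = c(5, 2))))),
               "invalid bound")
  expect_error(load_ruleset(list(rules = list(list(
    id = "new", group = "T3", class = "ZZ", face = "any_position")))),
    "unknown residue")
  expect_error(load_ruleset(list(rules = list(list(
    id = "t1r1", per_strand = list(`9` = c(0, 1)))))), "unknown strand")
  expect_error(load_ruleset(list(drop_rules = "nope")), "unknown id")

  # file round trip
  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(list(loop_rules = list(favorability_coefficient = 1)),
                       tf, auto_unbox = TRUE)
  expect_equal(load_ruleset(tf)$loop_rules$favorability_coefficient, 1)
})

test_that("parity flip moves the hydrophobic face to even positions", {
  g <- fold_geometry(parity = "even-in")
  expect_equal(g$hydrophobic_positions, c(2L, 4L, 6L))
  a <- fold_assignment(seq(0, 66, by = 11), 72)
  wp <- worked_positive()
  cnt <- count_feature(wp$sequence, a, "HYDROPHOBIC",
                       "hydrophobic_positions", g)
  # under flipped parity the worked strands place Q on the "hydrophobic" face
  expect_lt(cnt$all, 16L)
})
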