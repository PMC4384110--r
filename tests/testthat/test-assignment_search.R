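test_that("candidate enumeration covers exactly the geometric space", {
  expect_identical(nrow(enumerate_candidate_assignments(71)), 0L)

  cand <- enumerate_candidate_assignments(72)
  expect_identical(nrow(cand), 6188L)  # compositions of 30 into 6 parts [3,16]
  loops <- t(apply(cand, 1, function(s) diff(s) - 6L))
  expect_true(all(loops >= 3 & loops <= 16))
  expect_true(all(rowSums(loops) == 30))
  expect_true(all(cand[, 1] == 0))
  # canonical order: strand-1 start, then loop lengths, ascending
  expect_true(all(diff(cand[, 2]) >= 0 | diff(cand[, 1]) > 0))

  # with the total-range disabled but no tails, length 72 still forces
  # total 30 (with free tails, smaller totals fit with tail slack)
  g_free <- fold_geometry(enforce_loop_total = FALSE,
                          max_n_tail = 0, max_c_tail = 0)
  expect_identical(nrow(enumerate_candidate_assignments(72, g_free)), 6188L)

  # brute-force count cross-check with a narrowed per-loop range
  g_small <- fold_geometry(loop_len_range = c(3L, 8L))
  L <- 75L
  grid <- as.matrix(expand.grid(rep(list(3:8), 6)))
  tot <- rowSums(grid)
  brute <- 0L
  for (nt in 0:(L - 72L)) {
    brute <- brute + sum(tot >= 30 & tot <= 60 & (nt + 42L + tot) <= L)
  }
  expect_identical(nrow(enumerate_candidate_assignments(L, g_small)), brute)
})

test_that("search accepts the worked fixture with the canonical witness", {
  wp <- worked_positive()
  d <- fold_search(wp$sequence)
  expect_true(d$accepted)
  expect_equal(d$witness$strand_starts + 1L, c(1L, 12L, 23L, 34L, 45L, 56L, 67L))

  # N-tail absorbed
  d2 <- fold_search(paste0("MST", wp$sequence))
  expect_true(d2$accepted)
  expect_equal(d2$witness$strand_starts[1] + 1L, 4L)

  # poly-G rejected at several lengths
  for (L in c(72, 85, 100)) {
    expect_false(fold_search(strrep("G", L))$accepted)
  }
})

test_that("enumerate_satisfying agrees with search and with brute force", {
  wp <- worked_positive()
  sat <- enumerate_satisfying(wp$sequence)
  expect_length(sat, 1L)
  expect_equal(sat[[1]]$strand_starts, wp$assignment$strand_starts)

  expect_identical(enumerate_satisfying(strrep("A", 71)), list())
  expect_error(enumerate_satisfying(strrep("A", 600)), "guard")

  # dual-route + brute-force equivalence on random sequences
  biased <- c(V = .2, Q = .2, G = .15, L = .05, S = .1, T = .1, A = .05,
              K = .05, E = .05, N = .05)
  for (seed in 1:10) {
    comp <- if (seed %% 2) "uniform" else biased
    r <- suppressWarnings(generate_random(seed + 300, c(72, 90), comp))
    d <- fold_search(r$sequence)
    sat <- enumerate_satisfying(r$sequence)
    expect_identical(d$accepted, length(sat) > 0)
    if (d$accepted) {
      expect_equal(d$witness$strand_starts, sat[[1]]$strand_starts)
    }
  }

  # fully naive oracle (every candidate through check_assignment) on a
  # narrowed geometry, where the candidate space is small enough to scan
  rs_small <- default_ruleset(fold_geometry(loop_len_range = c(4L, 6L),
                                            loop_total_range = c(30L, 32L)))
  wp <- worked_positive()
  for (s in c(wp$sequence,
              generate_random(555, 73)$sequence,
              generate_negative("LOOPS", 9, length = 74)$sequence)) {
    d <- fold_search(s, rs_small)
    o <- oracle_decide(s, rs_small)
    expect_identical(d$accepted, o$accepted)
    if (d$accepted) {
      expect_equal(d$witness$strand_starts, o$witness$strand_starts)
    }
  }
})

test_that("decision is identical with pruning on or off", {
  wp <- worked_positive()
  seqs <- c(wp$sequence, paste0("MST", wp$sequence), strrep("G", 80),
            generate_negative("LOOPS", 5)$sequence)
  for (s in seqs) {
    on <- fold_search(s, params = search_params(prune = TRUE))
    off <- fold_search(s, params = search_params(prune = FALSE))
    expect_identical(on$accepted, off$accepted)
    if (on$accepted) {
      expect_equal(on$witness$strand_starts, off$witness$strand_starts)
    }
  }
})

test_that("enumerate_all counts all satisfying assignments consistently", {
  wp <- worked_positive()
  d <- fold_search(wp$sequence, params = search_params(enumerate_all = TRUE,
                                                       max_witnesses = 10))
  expect_equal(d$n_satisfying, length(enumerate_satisfying(wp$sequence)))

  p <- generate_positive(11, c_tail = 3L)
  d2 <- fold_search(p$sequence, params = search_params(enumerate_all = TRUE))
  expect_equal(d2$n_satisfying, length(enumerate_satisfying(p$sequence)))
})

test_that("appending tail residues never revokes acceptance", {
  p <- generate_positive(21)
  expect_true(fold_search(p$sequence)$accepted)
  expect_true(fold_search(paste0("MKT", p$sequence))$accepted)
  expect_true(fold_search(paste0(p$sequence, "HHHHHH"))$accepted)
  expect_true(fold_search(paste0("M", p$sequence, "LEHHHH"))$accepted)
})

test_that("rule-subset monotonicity holds on mixed sequences", {
  rs <- default_ruleset()
  rs_t3 <- subset_ruleset(rs, "T3")
  rs_t23 <- subset_ruleset(rs, c("T2", "T3"))
  set.seed(4)
  seqs <- c(vapply(1:10, function(i) generate_random(i + 700, 100)$sequence,
                   character(1)),
            worked_positive()$sequence)
  for (s in seqs) {
    acc_full <- fold_search(s, rs)$accepted
    acc_t23 <- fold_search(s, rs_t23)$accepted
    acc_t3 <- fold_search(s, rs_t3)$accepted
    if (acc_full) expect_true(acc_t23)
    if (acc_t23) expect_true(acc_t3)
  }
})

test_that("explain reports the closest failing assignment", {
  wp <- worked_positive()
  # mutate the third residue of strand 2 (V -> P): Pro enters an interlock strand
  m <- paste0(substr(wp$sequence, 1, 13), "P", substr(wp$sequence, 15, 72))
  e <- fold_explain(m)
  expect_false(e$accepted)
  expect_s3_class(e$best_failing, "violation_report")
  expect_true(any(grepl("^t[13]r7$", e$best_failing$violations$rule_id)))

  # minimality: no candidate in a deterministic subsample beats the report
  cand <- enumerate_candidate_assignments(nchar(m))
  rs <- default_ruleset()
  mres <- split_residues(m, warn = FALSE)
  sub <- seq(1L, nrow(cand), by = 23L)
  nv <- vapply(sub, function(i) {
    nrow(check_assignment(mres, fold_assignment(cand[i, ], nchar(m)),
                          rs)$violations)
  }, integer(1))
  expect_lte(nrow(e$best_failing$violations), min(nv))
  # the canonical placement itself cannot beat the reported one
  canonical <- check_assignment(mres, worked_positive()$assignment, rs)
  expect_lte(nrow(e$best_failing$violations), nrow(canonical$violations))

  # accepted input: no best_failing
  ok <- fold_explain(wp$sequence)
  expect_true(ok$accepted)
  expect_null(ok$best_failing)

  # poly-G: violations cite Gly rules
  pg <- fold_explain(strrep("G", 72))
  expect_true(any(grepl("t1r8|t3r8", pg$best_failing$violations$rule_id)))
})

test_that("classify_batch preserves order and survives per-record errors", {
  wp <- worked_positive()
  records <- data.frame(id = c("a", "b"),
                        seq = c(wp$sequence, strrep("G", 80)),
                        stringsAsFactors = FALSE)
  out <- classify_batch(records)
  expect_named(out, c("a", "b"))
  expect_true(out$a$accepted)
  expect_false(out$b$accepted)

  expect_identical(classify_batch(records[0, , drop = FALSE]),
                   setNames(list(), character(0)))

  dup <- records
  dup$id <- c("x", "x")
  expect_warning(classify_batch(dup), "duplicate")

  bad <- data.frame(id = "z", seq = "VXQ*!!", stringsAsFactors = FALSE)
  out2 <- classify_batch(bad, params = search_params(strict_alphabet = TRUE))
  expect_true(is.na(out2$z$accepted))
  expect_match(out2$z$error, "non-standard")
})

test_that("strict alphabet errors while default warns", {
  s <- paste0(substr(worked_positive()$sequence, 1, 71), "X")
  expect_warning(fold_search(s), "non-standard")
  expect_error(fold_search(s, params = search_params(strict_alphabet = TRUE)),
               "non-standard")
})
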