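cat3 <- task_catalog(c(1, 1, 2), rep("reading_video", 3))
abc_cohort <- cohort(cat3, list(learner_record("A", c(1, 2, 3), 80),
                                learner_record("B", c(2, 1, 3), 50),
                                learner_record("C", c(1, 3), 65)))

nominal_cohort <- function(N, T, S = 2) {
  cat <- task_catalog(sort(rep_len(1:S, T)), rep("quiz", T))
  cohort(cat, lapply(seq_len(N), function(i)
    learner_record(sprintf("n%02d", i), 1:T, grade = 50 + i)))
}

test_that("position matrix counts and normalises correctly", {
  pm <- position_probability_matrix(abc_cohort)
  expect_equal(unname(pm$P[1, ]), c(2 / 3, 1 / 3, 0))
  expect_equal(unname(pm$P[3, ]), c(0, 1 / 3, 2 / 3))
  expect_equal(unname(rowSums(pm$P)), rep(1, 3))
})

test_that("an all-nominal cohort yields the identity position matrix and superdiagonal transitions", {
  co <- nominal_cohort(4, 5)
  pm <- position_probability_matrix(co)
  expect_equal(unname(pm$P), diag(5))
  ts <- transition_summary(co, "task", include_start = FALSE)
  expected <- matrix(0, 5, 5)
  expected[cbind(1:4, 2:5)] <- 1
  expect_equal(unname(ts$conditional[1:4, ]), expected[1:4, ])
  expect_identical(ts$undefined_rows, 5L) # last task has no successor
  # session-level conditional concentrates on diagonal + superdiagonal
  ss <- transition_summary(co, "session", include_start = FALSE)
  k <- nrow(ss$conditional)
  ondiag <- sum(diag(ss$conditional), na.rm = TRUE) +
    sum(ss$conditional[cbind(1:(k - 1), 2:k)], na.rm = TRUE)
  expect_equal(ondiag, sum(ss$conditional, na.rm = TRUE))
})

test_that("never-completed tasks give flagged all-zero position rows", {
  co <- cohort(cat3, list(learner_record("A", c(1, 3))))
  pm <- position_probability_matrix(co)
  expect_identical(unname(pm$never_completed), 2L)
  expect_equal(unname(pm$P[2, ]), rep(0, 3))
})

test_that("transition counting matches the worked three-learner example", {
  ts <- transition_summary(abc_cohort, "task", include_start = FALSE)
  expect_equal(ts$counts["1", "2"], 1L)
  expect_equal(ts$counts["2", "3"], 1L)
  expect_equal(ts$counts["2", "1"], 1L)
  expect_equal(ts$counts["1", "3"], 2L)
  expect_equal(sum(ts$counts), 5L)
  expect_equal(ts$joint["1", "3"], 0.4)
  expect_equal(unname(ts$conditional["1", ]), c(0, 1 / 3, 2 / 3))
  expect_true(all(diag(ts$counts) == 0L)) # a task cannot precede itself
})

test_that("session coarse-graining substitutes session IDs before counting", {
  cat22 <- task_catalog(c(1, 1, 2, 2), rep("quiz", 4))
  co <- cohort(cat22, list(learner_record("A", 1:4)))
  ss <- transition_summary(co, "session", include_start = FALSE)
  # session sequence (1,1,2,2): transitions 1->1, 1->2, 2->2
  expect_equal(unname(ss$conditional["1", ]), c(1 / 2, 1 / 2))
  expect_equal(unname(ss$conditional["2", ]), c(0, 1))
  # with the virtual start state the first completion is itself a transition
  ss0 <- transition_summary(co, "session", include_start = TRUE)
  expect_equal(ss0$counts["0", "1"], 1L)
  expect_equal(sum(ss0$counts), 4L)
})

test_that("degenerate cohorts give all-zero transition matrices without error", {
  co <- cohort(cat3, list(learner_record("A", 2)))
  ts <- transition_summary(co, "task", include_start = FALSE)
  expect_equal(sum(ts$counts), 0L)
  expect_true(all(is.na(ts$conditional)))
  expect_setequal(ts$undefined_rows, 1:3)
})

test_that("matrices equal independent brute-force recounts on random cohorts", {
  for (seed in 1:6) {
    N <- sample(1:5, 1)
    T <- sample(2:6, 1)
    co <- rand_cohort(N, T, seed = seed * 100)
    seqs <- sequences(co)

    pm <- position_probability_matrix(co)
    expect_equal(unname(pm$counts), unname(oracle_position_counts(seqs, T)))

    ts <- transition_summary(co, "task", include_start = FALSE)
    m <- oracle_transition_counts(seqs, 1:T)
    expect_equal(unname(ts$counts), unname(m))
    if (sum(m) > 0) {
      expect_equal(unname(ts$joint), unname(m / sum(m)))
      for (i in 1:T) {
        if (sum(m[i, ]) > 0)
          expect_equal(unname(ts$conditional[i, ]), m[i, ] / sum(m[i, ]))
        else expect_true(all(is.na(ts$conditional[i, ])))
      }
    }

    sess_seqs <- lapply(seqs, function(s) co$catalog$session[s])
    ss <- transition_summary(co, "session", include_start = FALSE)
    expect_equal(unname(ss$counts),
                 unname(oracle_transition_counts(sess_seqs, 1:co$catalog$S)))

    dm <- deviation_matrix(co, order_by = "id")
    for (id in rownames(dm$D)) {
      row <- oracle_deviation_row(co$learners[[id]]$sequence, T)
      got <- dm$D[id, ]
      expect_equal(unname(got[seq_along(row)]), row)
      if (length(row) < length(got))
        expect_true(all(is.na(got[(length(row) + 1):length(got)])))
    }
  }
})

test_that("probability mass is conserved and learner order is irrelevant", {
  co <- rand_cohort(5, 6, seed = 7)
  ts <- transition_summary(co, "task", include_start = FALSE)
  expect_equal(sum(ts$joint), 1, tolerance = 1e-12)
  defined <- rowSums(ts$joint) > 0
  expect_equal(unname(rowSums(ts$conditional[defined, , drop = FALSE])),
               rep(1, sum(defined)), tolerance = 1e-12)
  pm <- position_probability_matrix(co)
  done <- rowSums(pm$counts) > 0
  expect_equal(unname(rowSums(pm$P[done, , drop = FALSE])),
               rep(1, sum(done)), tolerance = 1e-12)

  co_perm <- cohort(co$catalog, rev(co$learners))
  expect_equal(position_probability_matrix(co_perm)$P, pm$P)
  expect_equal(transition_summary(co_perm, "task", include_start = FALSE)$counts,
               ts$counts)
})

test_that("delta transition splits signed differences and tracks missing rows", {
  g1 <- cohort(cat3, list(learner_record("A", c(1, 2, 3))))
  g2 <- cohort(cat3, list(learner_record("B", c(1, 3, 2))))
  ta <- transition_summary(g1, "task", include_start = FALSE)
  tb <- transition_summary(g2, "task", include_start = FALSE)
  d <- delta_transition(ta, tb)
  expect_equal(d$positive["1", "2"], 1)
  expect_equal(d$negative["1", "3"], 1)
  expect_true(all(d$positive >= 0, na.rm = TRUE))
  expect_true(all(d$negative >= 0, na.rm = TRUE))
  # identical inputs: both parts vanish
  dz <- delta_transition(ta, ta)
  expect_true(all(dz$positive == 0, na.rm = TRUE))
  expect_true(all(dz$negative == 0, na.rm = TRUE))
  # rows undefined in one matrix are flagged and NA in the parts
  expect_true(3 %in% d$missing_rows)
  expect_true(all(is.na(d$delta["3", ])))
  # mismatched state sets refuse
  sb <- transition_summary(g2, "session")
  expect_error(delta_transition(ta, sb), "mismatch")
})

test_that("J-S distance honours its bounds, symmetry and closed-form values", {
  expect_equal(js_distance(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(js_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(js_distance(c(1, 0, 0), c(0, 0.5, 0.5)), 1)
  # closed form: JSD((1,0),(1/2,1/2)) = H(3/4,1/4) - 1/2 bits
  h <- -(0.75 * log2(0.75) + 0.25 * log2(0.25))
  expect_equal(js_divergence(c(1, 0), c(0.5, 0.5)), h - 0.5, tolerance = 1e-12)
  expect_equal(js_distance(c(1, 0), c(0.5, 0.5)), sqrt(h - 0.5),
               tolerance = 1e-12)
  # independent oracle, symmetry, bounds and the triangle inequality
  set.seed(11)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    p <- runif(k); q <- runif(k); r <- runif(k)
    expect_equal(js_divergence(p, q), oracle_jsd(p, q), tolerance = 1e-9)
    expect_equal(js_distance(p, q), js_distance(q, p))
    expect_gte(js_distance(p, q), 0)
    expect_lte(js_distance(p, q), 1)
    expect_lte(js_distance(p, q),
               js_distance(p, r) + js_distance(r, q) + 1e-12)
  }
})

test_that("J-S profiles compare rows and renormalised columns, skipping undefined rows", {
  g1 <- cohort(cat3, list(learner_record("A", c(1, 2, 3))))
  ta <- transition_summary(g1, "task", include_start = FALSE)
  pr <- js_profile(ta, ta)
  expect_equal(unname(pr$rows[c("1", "2")]), c(0, 0))
  expect_true(is.na(pr$rows["3"]))  # no outgoing transitions from task 3
  expect_equal(pr$mean_outgoing, 0)
  expect_equal(pr$mean_incoming, 0)
  expect_true(3 %in% pr$skipped_rows)

  g2 <- cohort(cat3, list(learner_record("B", c(1, 3, 2))))
  tb <- transition_summary(g2, "task", include_start = FALSE)
  pr2 <- js_profile(ta, tb)
  expect_equal(unname(pr2$rows["1"]), 1) # disjoint successors of task 1
  expect_true(all(pr2$rows >= 0 & pr2$rows <= 1, na.rm = TRUE))
  expect_equal(js_profile(tb, ta)$mean_outgoing, pr2$mean_outgoing)
  # joint-column mode also runs and stays in bounds
  pr3 <- js_profile(ta, tb, incoming = "joint")
  expect_true(all(pr3$cols >= 0 & pr3$cols <= 1, na.rm = TRUE))
})

test_that("deviation entries follow the fractional-position normalisation", {
  co <- cohort(cat3, list(learner_record("A", c(1, 3), 60),
                          learner_record("B", integer(0), 90)))
  dm <- deviation_matrix(co, order_by = "grade")
  expect_identical(dm$order, c("B", "A")) # grade descending
  expect_equal(dm$D["A", 1], 1 / 2 - 1 / 3)
  expect_equal(dm$D["A", 2], 0)
  expect_true(all(is.na(dm$D["B", ])))
  expect_true(all(abs(dm$D) <= 1, na.rm = TRUE))
  # full nominal completion gives an all-zero (white) row
  full <- cohort(cat3, list(learner_record("A", 1:3)))
  expect_equal(unname(deviation_matrix(full, "id")$D["A", ]), rep(0, 3))
})
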