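test_that("synthetic catalogs partition tasks into contiguous sessions with the stated mix", {
  cat <- make_catalog(123, 10, seed = 1)
  expect_equal(cat$T, 123L)
  expect_equal(cat$S, 10L)
  expect_identical(cat$task_ids, 1:123)
  expect_true(all(diff(cat$session) %in% 0:1))
  # coursework closes the scaled default sessions (3, 4 and 9 of 10)
  cw <- which(cat$type == "coursework")
  expect_setequal(cat$session[cw], c(3, 4, 9))
  for (t in cw) expect_equal(t, max(which(cat$session == cat$session[t])))
  # uniform single-type catalogs and determinism
  cat6 <- make_catalog(6, 2, type_mix = c(reading_video = 1),
                       coursework_sessions = integer(0), seed = 2)
  expect_identical(cat6$session, rep(1:2, each = 3L))
  expect_true(all(cat6$type == "reading_video"))
  expect_identical(make_catalog(40, 4, seed = 7), make_catalog(40, 4, seed = 7))
  expect_error(make_catalog(3, 5), "T >= S")
})

test_that("behavioural theta interpolates between uniform and pinned nominal order", {
  mkgr <- function(aw, ab) data.frame(
    label = "g", size = 4, grade_mean = 70, grade_sd = 5,
    adherence_within = aw, adherence_between = ab, coursework_boost = 0,
    coursework_pull = 0, skip_multiplier = 1, completion_mean = 1,
    completion_sd = 0, p_confident = 0.7)
  cat <- make_catalog(6, 2, type_mix = c(reading_video = 1),
                      coursework_sessions = integer(0), seed = 3)
  sc0 <- scenario_config(T = 6, S = 2, N = 4, groups = mkgr(0, 0), seed = 4)
  expect_equal(behavioural_theta(sc0, "g", cat), matrix(0, 6, 6))
  # saturating adherence reproduces the nominal order
  sc_inf <- scenario_config(T = 6, S = 2, N = 4, groups = mkgr(60, 60), seed = 4)
  th_inf <- behavioural_theta(sc_inf, "g", cat)
  s <- simulate_sequence(th_inf, 6, seed = 8)
  expect_identical(s$sequence, 1:6)
  # distinct adherence separates groups in likelihood
  gr2 <- rbind(mkgr(1, 4), mkgr(4, 1))
  gr2$label <- c("hi", "lo"); gr2$size <- c(2, 2)
  sc2 <- scenario_config(T = 6, S = 2, N = 4, groups = gr2, seed = 4)
  th_hi <- behavioural_theta(sc2, "hi", cat)
  th_lo <- behavioural_theta(sc2, "lo", cat)
  hi <- model_only_cohort(th_hi, 60, lengths = 6, seed = 21, catalog = cat)
  lo <- model_only_cohort(th_lo, 60, lengths = 6, seed = 22, catalog = cat)
  expect_gt(cohort_loglik(th_hi, hi$cohort), cohort_loglik(th_lo, hi$cohort))
  expect_gt(cohort_loglik(th_lo, lo$cohort), cohort_loglik(th_hi, lo$cohort))
})

test_that("generated cohorts are deterministic under the scenario seed and pass validation", {
  sc <- scenario_config(T = 30, S = 3, N = 12, seed = 77,
                        groups = data.frame(
                          label = c("g1", "g2"), size = c(6, 6),
                          grade_mean = c(80, 55), grade_sd = c(3, 5),
                          adherence_within = c(2.5, 3.5),
                          adherence_between = c(3.5, 1.5),
                          coursework_boost = c(0, 1), coursework_pull = c(0, 3),
                          skip_multiplier = c(0.6, 1.4),
                          completion_mean = c(0.95, 0.7),
                          completion_sd = c(0.04, 0.1),
                          p_confident = c(0.76, 0.65)))
  a <- simulate_cohort(sc)
  b <- simulate_cohort(sc)
  expect_identical(sequences(a$cohort), sequences(b$cohort))
  expect_identical(vapply(a$cohort$learners, function(l) l$grade, 1),
                   vapply(b$cohort$learners, function(l) l$grade, 1))
  # byte-identical canonical CSV output
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort_csv(a$cohort, d1); write_cohort_csv(b$cohort, d2)
  expect_identical(readLines(file.path(d1, "events.csv")),
                   readLines(file.path(d2, "events.csv")))
  # every generated record already satisfies the cohort invariants
  expect_s3_class(cohort(a$cohort$catalog, a$cohort$learners), "cohort")
  expect_identical(names(a$ground_truth$group_of), names(a$cohort$learners))
})

test_that("model-only cohorts reproduce the uniform-ordering law", {
  e <- enumerate_order_probabilities(matrix(0, 3, 3))
  mc <- model_only_cohort(matrix(0, 3, 3), 20000, seed = 5)
  obs <- table(factor(vapply(sequences(mc$cohort), paste, "", collapse = "-"),
                      levels = names(e)))
  expect_gt(stats::chisq.test(obs, p = e)$p.value, 0.01)
  expect_identical(mc$ground_truth$mode, "model")
  # length rule is honoured and seeded runs are identical
  mc2 <- model_only_cohort(matrix(0, 4, 4), 5, lengths = c(0, 1, 2, 3, 4),
                           seed = 6)
  expect_identical(lengths(sequences(mc2$cohort)), setNames(0:4, names(
    mc2$cohort$learners)))
  mc3 <- model_only_cohort(matrix(0, 4, 4), 5, lengths = c(0, 1, 2, 3, 4),
                           seed = 6)
  expect_identical(sequences(mc2$cohort), sequences(mc3$cohort))
})

test_that("branch subgroups produce bimodal downstream position histograms", {
  # isolate the branching mechanism: high adherence, no other skips
  gr <- data.frame(label = "g", size = 60, grade_mean = 70, grade_sd = 5,
                   adherence_within = 30, adherence_between = 30,
                   coursework_boost = 0, coursework_pull = 0,
                   skip_multiplier = 0, completion_mean = 1,
                   completion_sd = 0, p_confident = 0.7)
  sc <- scenario_config(T = 12, S = 2, N = 60, groups = gr, skip_min = 0,
                        skip_max = 0, branch_fraction = 0.5,
                        branch_tasks = c(5, 6), seed = 31)
  sim <- simulate_cohort(sc)
  pm <- position_probability_matrix(sim$cohort)
  # a task well downstream of the branch sits at nominal position in one
  # branch and two earlier in the other
  row <- pm$P[10, ]
  expect_gte(row[10], 0.2)
  expect_gte(row[8], 0.2)
  expect_lt(row[9], min(row[8], row[10]))
})

test_that("a rising skip curve makes completion frequency fall along the course", {
  sc <- scenario_config(seed = 2024)
  sim <- simulate_cohort(sc)
  st <- task_completion_stats(sim$cohort)
  expect_lt(stats::cor(st$task_id, st$frequency, method = "spearman"), 0)
})

test_that("the default scenario emulates the reported cohort structure", {
  sc <- scenario_config(seed = 2024)
  expect_equal(sc$T, 123L)
  expect_equal(sc$S, 10L)
  expect_equal(sc$N, 81L)
  sim <- simulate_cohort(sc)
  co <- sim$cohort
  expect_equal(co$N, 81L)

  # grades per true group recover the configured means within 3 SE
  gt <- sim$ground_truth$group_of
  gr <- vapply(co$learners, function(l) l$grade, 1)
  for (lab in c("g1", "g2")) {
    spec <- sc$groups[sc$groups$label == lab, ]
    se <- spec$grade_sd / sqrt(spec$size)
    expect_lt(abs(mean(gr[gt == lab]) - spec$grade_mean), 3 * se)
  }

  # confidence per true group recovers the configured probabilities
  cf <- confidence_scores(co)
  grp_conf <- vapply(split(cf$responses$confident,
                           gt[cf$responses$learner_id]), mean, 1)
  for (lab in c("g1", "g2")) {
    p <- sc$groups$p_confident[sc$groups$label == lab]
    n <- sum(gt[cf$responses$learner_id] == lab)
    expect_lt(abs(grp_conf[[lab]] - p), 3 * sqrt(p * (1 - p) / n))
  }
  # and the low group tests as less confident (paired over tasks)
  tt <- group_confidence_test(cf, group_labelling(gt))
  expect_lt(tt$p_value, 0.05)
  expect_gt(tt$groups$mean[1], tt$groups$mean[2])

  # position structure: deviations from nominal grow along the course
  pm <- position_probability_matrix(co)
  mean_abs_dev <- vapply(1:co$catalog$T, function(t) {
    if (sum(pm$counts[t, ]) == 0) return(NA_real_)
    sum(pm$P[t, ] * abs(seq_len(co$catalog$T) - t))
  }, 1)
  expect_gt(stats::cor(seq_along(mean_abs_dev), mean_abs_dev,
                       use = "complete.obs"), 0.3)

  # session transitions concentrate on the diagonal + superdiagonal
  ss <- transition_summary(co, "session")
  cond <- ss$conditional
  k <- nrow(cond)
  mass <- vapply(2:k, function(i)
    sum(cond[i, c(i, min(i + 1, k))], na.rm = TRUE), 1)
  expect_gt(mean(mass), 0.4) # far above the uniform baseline 2/11
})
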