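# Independent brute-force recounts used as oracles. Deliberately written as
# plain double loops, sharing no code with the package implementations.

oracle_position_counts <- function(seqs, T) {
  counts <- matrix(0L, T, T)
  for (s in seqs) {
    for (j in seq_along(s)) counts[s[j], j] <- counts[s[j], j] + 1L
  }
  counts
}

oracle_transition_counts <- function(state_seqs, states) {
  k <- length(states)
  m <- matrix(0L, k, k)
  for (s in state_seqs) {
    if (length(s) >= 2) {
      for (i in seq_len(length(s) - 1)) {
        a <- match(s[i], states)
        b <- match(s[i + 1], states)
        m[a, b] <- m[a, b] + 1L
      }
    }
  }
  m
}

oracle_task_stats <- function(seqs, T) {
  freq <- numeric(T)
  mean_rank <- rep(NA_real_, T)
  for (t in seq_len(T)) {
    ranks <- c()
    for (s in seqs) {
      pos <- which(s == t)
      if (length(pos)) ranks <- c(ranks, pos)
    }
    freq[t] <- length(ranks) / length(seqs)
    if (length(ranks)) mean_rank[t] <- mean(ranks)
  }
  list(frequency = freq, mean_rank = mean_rank)
}

oracle_deviation_row <- function(s, T) {
  n <- length(s)
  if (n == 0) return(numeric(0))
  out <- numeric(n)
  for (j in seq_len(n)) out[j] <- j / n - s[j] / T
  out
}

# J-S divergence by direct summation over the support (independent of the
# package's entropy-difference form)
oracle_jsd <- function(p, q) {
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    keep <- a > 0
    sum(a[keep] * log2(a[keep] / b[keep]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

# random small cohort: N learners over T tasks, random subset sizes and
# orders, occasionally empty sequences
rand_cohort <- function(N, T, seed, sessions = NULL) {
  set.seed(seed)
  if (is.null(sessions)) sessions <- sort(sample(1:2, T, replace = TRUE))
  sessions <- sessions - min(sessions) + 1L
  catalog <- task_catalog(sessions, sample(TASK_TYPES, T, replace = TRUE))
  recs <- lapply(seq_len(N), function(i) {
    n <- sample(0:T, 1)
    learner_record(sprintf("r%02d", i),
                   if (n > 0) sample(T, n) else integer(0),
                   grade = runif(1, 30, 95))
  })
  cohort(catalog, recs)
}

# shared fixture for the two-group classification experiments: pure-model
# cohorts drawn from group-specific behavioural matrices
two_group_model_cohort <- function(theta_g1, theta_g2, n_per, len, seed,
                                   catalog) {
  m1 <- model_only_cohort(theta_g1, n_per, lengths = len, seed = seed,
                          catalog = catalog)
  m2 <- model_only_cohort(theta_g2, n_per, lengths = len, seed = seed + 1L,
                          catalog = catalog)
  recs <- m1$cohort$learners
  for (l in m2$cohort$learners) {
    l$learner_id <- paste0("B", l$learner_id)
    recs[[l$learner_id]] <- l
  }
  co <- cohort(catalog, recs)
  labels <- setNames(rep(c("g1", "g2"), each = n_per), names(recs))
  list(cohort = co, groups = group_labelling(labels))
}

# adherence-contrast scenario used by the classification experiments:
# groups differ only in their nominal-order adherence
classifier_scenario_groups <- function(aw, ab) {
  data.frame(label = c("g1", "g2"), size = c(20, 20),
             grade_mean = c(79.3, 55.6), grade_sd = c(3.3, 4.6),
             adherence_within = aw, adherence_between = ab,
             coursework_boost = c(0, 0), coursework_pull = c(0, 0),
             skip_multiplier = c(1, 1), completion_mean = c(0.85, 0.85),
             completion_sd = c(0.05, 0.05), p_confident = c(0.76, 0.65))
}
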