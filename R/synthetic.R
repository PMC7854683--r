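# Seeded synthetic cohort generator.
#
# Real course-completion records of this kind are private LMS data, so the
# package ships a generator that emulates their reported structure: a cohort
# of learners working through sessions of ordered tasks, mostly following
# the nominal order (diagonal-dominant transition structure), with skips
# that accumulate along the course (broadening position histograms), a
# branching subgroup that skips designated tasks (bimodal histograms),
# group-dependent adherence (high performers track the session sequence,
# low performers track within-session order but jump between sessions and
# towards coursework), and group-dependent grades and confidence.

#' Build a synthetic task catalog
#'
#' Partitions `T` tasks into `S` contiguous session blocks and assigns task
#' types by a stated mix, with coursework tasks placed in designated
#' sessions (one per session, at the session end, mimicking coursework
#' deadlines).
#'
#' @param T number of tasks.
#' @param S number of sessions (`T >= S >= 1`).
#' @param type_mix named numeric vector of proportions over non-coursework
#'   entries of [TASK_TYPES]; the default mix is dominated by
#'   readings/videos with a substantial share of discussion posts, polls,
#'   G-charts and quizzes.
#' @param coursework_sessions integer vector of sessions that end with a
#'   coursework task; defaults to sessions 3, 4 and 9 scaled to `S`.
#' @param seed optional integer seed (type assignment is randomised).
#' @return A [task_catalog].
#' @export
make_catalog <- function(T, S, type_mix = NULL, coursework_sessions = NULL,
                         seed = NULL) {
  if (T < S || S < 1) stop("need T >= S >= 1")
  if (!is.null(seed)) set.seed(seed)
  # contiguous, nearly equal session blocks
  sizes <- rep(T %/% S, S)
  extra <- T %% S
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  session <- rep(seq_len(S), times = sizes)

  if (is.null(coursework_sessions)) {
    coursework_sessions <- unique(pmin(S, pmax(1L, ceiling(c(3, 4, 9) * S / 10))))
  }
  if (is.null(type_mix)) {
    type_mix <- c(reading_video = 0.46, discussion_post = 0.16,
                  multi_response_poll = 0.15, g_chart = 0.10, quiz = 0.13)
  }
  if (!all(names(type_mix) %in% setdiff(TASK_TYPES, "coursework")))
    stop("type_mix names must be non-coursework task types")
  if (any(type_mix < 0) || sum(type_mix) <= 0) stop("impossible type mix")

  type <- rep(NA_character_, T)
  cw <- integer(0)
  for (s in coursework_sessions) {
    cand <- max(which(session == s)) # last task of the session
    cw <- c(cw, cand)
  }
  cw <- unique(cw)
  if (length(cw) >= T) stop("impossible mix: coursework would fill the course")
  type[cw] <- "coursework"
  rest <- which(is.na(type))
  probs <- type_mix / sum(type_mix)
  counts <- floor(probs * length(rest))
  # largest-remainder top-up
  rem <- probs * length(rest) - counts
  short <- length(rest) - sum(counts)
  if (short > 0) {
    top <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[top] <- counts[top] + 1L
  }
  pool <- rep(names(type_mix), times = counts)
  type[rest] <- sample(pool)
  task_catalog(session, type)
}

#' Scenario configuration for the synthetic generator
#'
#' All parameters of [simulate_cohort()] in one validated object. The
#' defaults emulate the reference study conditions: 81 learners, 123 tasks
#' in 10 sessions with coursework closing sessions 3, 4 and 9; top and
#' bottom performance groups of 20 with grade means 79.3 (sd 3.3) and 55.6
#' (sd 4.6) around a middle group; a skip rate rising along the course; a
#' branching subgroup of 40% skipping two tasks about two-thirds through;
#' coursework pulled early in the low group's sequences; and per-group
#' confident-response probabilities 0.76 / 0.65.
#'
#' @param T,S,N task, session and learner counts.
#' @param groups data.frame with one row per group: `label`, `size`,
#'   `grade_mean`, `grade_sd`, `adherence_within`, `adherence_between`
#'   (log-scale nominal-successor propensities inside and across session
#'   boundaries), `coursework_boost` (extra basal log-propensity of
#'   coursework tasks), `coursework_pull` (positions coursework tasks are
#'   moved forward after simulation), `skip_multiplier`, `completion_mean`,
#'   `completion_sd` (fraction of the simulated sequence retained),
#'   `p_confident`.
#' @param skip_min,skip_max per-task skip probability at the start and end of
#'   the course (linear, non-decreasing in task index).
#' @param branch_fraction fraction of learners who skip `branch_tasks`.
#' @param branch_tasks task IDs skipped by the branching subgroup; `NULL`
#'   picks two adjacent tasks about two-thirds through the course.
#' @param seed mandatory integer seed.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(T = 123, S = 10, N = 81, groups = NULL,
                            skip_min = 0.02, skip_max = 0.25,
                            branch_fraction = 0.4, branch_tasks = NULL,
                            seed) {
  if (missing(seed)) stop("a seed is mandatory in scenario_config()")
  if (is.null(groups)) {
    n_tail <- floor(N * 0.25)
    groups <- data.frame(
      label = c("g1", "mid", "g2"),
      size = c(n_tail, N - 2 * n_tail, n_tail),
      grade_mean = c(79.3, 68.4, 55.6),
      grade_sd = c(3.3, 6.0, 4.6),
      adherence_within = c(2.5, 3.0, 3.5),
      adherence_between = c(3.5, 2.5, 1.5),
      coursework_boost = c(0, 0.5, 1.5),
      coursework_pull = c(0, 2, 6),
      skip_multiplier = c(0.6, 1.0, 1.4),
      completion_mean = c(0.95, 0.85, 0.70),
      completion_sd = c(0.04, 0.08, 0.12),
      p_confident = c(0.76, 0.70, 0.65))
  }
  need <- c("label", "size", "grade_mean", "grade_sd", "adherence_within",
            "adherence_between", "coursework_boost", "coursework_pull",
            "skip_multiplier", "completion_mean", "completion_sd",
            "p_confident")
  if (!all(need %in% names(groups)))
    stop("groups must have columns: ", paste(need, collapse = ", "))
  if (sum(groups$size) != N) stop("group sizes must sum to N")
  if (any(groups$size < 1)) stop("group sizes must be positive")
  probs <- c(skip_min, skip_max, branch_fraction, groups$p_confident,
             groups$completion_mean)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (skip_max < skip_min) stop("skip rate must be non-decreasing")
  if (is.null(branch_tasks)) {
    b <- max(2L, round(2 * T / 3))
    branch_tasks <- c(b - 1L, b)
  }
  structure(list(T = as.integer(T), S = as.integer(S), N = as.integer(N),
                 groups = groups, skip_min = skip_min, skip_max = skip_max,
                 branch_fraction = branch_fraction,
                 branch_tasks = as.integer(branch_tasks),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Group-specific behavioural parameter matrix
#'
#' Encodes the generator's behavioural assumptions as a hypercubic-model
#' parameter matrix: basal log-propensities decay with nominal rank (earlier
#' tasks are tried first), each acquired task boosts its nominal successor
#' (`adherence_within` inside a session, `adherence_between` across a
#' session boundary), and coursework tasks get an extra basal boost
#' (`coursework_boost`). All terms scale with the adherence parameters, so
#' adherence 0 gives the uniform model and large adherence pins the nominal
#' order.
#'
#' @param scenario a [scenario_config].
#' @param label group label (row of `scenario$groups`).
#' @param catalog the [task_catalog] the cohort uses (session membership and
#'   coursework placement matter); defaults to `make_catalog(T, S)` with the
#'   scenario seed.
#' @return A `T x T` parameter matrix.
#' @export
behavioural_theta <- function(scenario, label, catalog = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  g <- scenario$groups[scenario$groups$label == label, ]
  if (nrow(g) != 1) stop("unknown group label: ", label)
  if (is.null(catalog))
    catalog <- make_catalog(scenario$T, scenario$S, seed = scenario$seed)
  T <- catalog$T
  a_w <- g$adherence_within
  a_b <- g$adherence_between
  a_mean <- (a_w + a_b) / 2
  theta <- matrix(0, T, T)
  if (T > 1)
    diag(theta) <- -2 * a_mean * (seq_len(T) - 1) / (T - 1)
  for (i in seq_len(T - 1)) {
    same <- catalog$session[i + 1] == catalog$session[i]
    theta[i, i + 1] <- theta[i, i + 1] + if (same) a_w else a_b
  }
  cw <- which(catalog$type == "coursework")
  if (length(cw))
    diag(theta)[cw] <- diag(theta)[cw] + g$coursework_boost
  theta
}

# move listed tasks earlier in a sequence by `pull` positions
pull_forward <- function(s, tasks, pull) {
  if (pull <= 0) return(s)
  for (t in intersect(tasks, s)) {
    pos <- match(t, s)
    new_pos <- max(1L, pos - as.integer(pull))
    if (new_pos < pos) s <- append(s[-pos], t, after = new_pos - 1L)
  }
  s
}

#' Simulate a behavioural synthetic cohort
#'
#' Draws each learner's full-course sequence from their group's
#' [behavioural_theta()] via the model simulator, then applies the
#' behavioural post-processing that real data exhibit but the model does not
#' describe: the rising skip-rate curve (tasks dropped, order preserved, so
#' downstream positions shift — the broadening effect), the branching
#' subgroup that skips designated tasks (bimodality), the coursework
#' pull-forward for low-adherence groups, and truncation to a group-specific
#' completed fraction (censoring). Grades and per-task confidence responses
#' are drawn per group. Fully reproducible under the scenario seed.
#'
#' @param scenario a [scenario_config].
#' @return A list with `cohort` (a [cohort]), `ground_truth` (list:
#'   `theta` per group, `group_of` named labels, `mode = "behavioural"`,
#'   `scenario`) — the true group assignment used for generation.
#' @export
simulate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  set.seed(scenario$seed)
  catalog <- make_catalog(scenario$T, scenario$S, seed = scenario$seed)
  T <- catalog$T
  skip_base <- scenario$skip_min +
    (scenario$skip_max - scenario$skip_min) *
      (seq_len(T) - 1) / max(T - 1, 1)
  cw_tasks <- which(catalog$type == "coursework")

  thetas <- lapply(scenario$groups$label, function(lab)
    behavioural_theta(scenario, lab, catalog))
  names(thetas) <- scenario$groups$label

  recs <- list()
  group_of <- character(0)
  idx <- 0L
  for (gi in seq_len(nrow(scenario$groups))) {
    g <- scenario$groups[gi, ]
    theta <- thetas[[g$label]]
    for (k in seq_len(g$size)) {
      idx <- idx + 1L
      id <- sprintf("L%03d", idx)
      s <- cpp_simulate_sequence(theta, T) + 1L
      # truncation: group-specific completed fraction of the course
      frac <- min(max(rnorm(1, g$completion_mean, g$completion_sd), 0.05), 1)
      s <- head(s, max(1L, round(frac * T)))
      # rising skip-rate curve, order preserved
      keep <- runif(length(s)) >= pmin(skip_base[s] * g$skip_multiplier, 0.9)
      s <- s[keep]
      # branching subgroup skips the designated tasks
      if (runif(1) < scenario$branch_fraction)
        s <- setdiff(s, scenario$branch_tasks)
      # low-adherence groups reach coursework early
      s <- pull_forward(s, cw_tasks, g$coursework_pull)
      if (!length(s)) s <- 1L
      grade <- min(max(rnorm(1, g$grade_mean, g$grade_sd), 0), 100)
      resp <- ifelse(runif(length(s)) < g$p_confident, "confident",
                     ifelse(runif(length(s)) < 0.5, "revisit", "support"))
      recs[[id]] <- learner_record(id, s, grade = grade,
                                   confidence = setNames(resp, s))
      group_of[id] <- g$label
    }
  }
  list(cohort = cohort(catalog, recs),
       ground_truth = list(theta = thetas, group_of = group_of,
                           mode = "behavioural", scenario = scenario))
}

#' Simulate a model-only cohort (no behavioural post-processing)
#'
#' Clean sequences drawn directly from one parameter matrix, for
#' parameter-recovery and oracle tests where the data must match the model
#' assumptions exactly.
#'
#' @param theta parameter matrix.
#' @param N number of learners.
#' @param lengths sequence length: a scalar (recycled), a vector of length
#'   `N`, or a function `(i) -> length`.
#' @param seed integer seed.
#' @param catalog optional [task_catalog]; defaults to one session of
#'   readings.
#' @return A list with `cohort` and `ground_truth` (`mode = "model"`).
#' @export
model_only_cohort <- function(theta, N, lengths = nrow(theta), seed,
                              catalog = NULL) {
  check_theta(theta)
  if (missing(seed)) stop("a seed is mandatory")
  T <- nrow(theta)
  if (is.null(catalog))
    catalog <- task_catalog(rep(1L, T), rep("reading_video", T))
  stopifnot(catalog$T == T)
  set.seed(seed)
  len_of <- if (is.function(lengths)) lengths
    else function(i) rep_len(lengths, N)[i]
  recs <- lapply(seq_len(N), function(i) {
    n <- len_of(i)
    if (n < 0 || n > T) stop("length rule must yield 0 <= n <= T")
    s <- if (n == 0) integer(0) else cpp_simulate_sequence(theta, as.integer(n)) + 1L
    learner_record(sprintf("L%03d", i), s)
  })
  list(cohort = cohort(catalog, recs),
       ground_truth = list(theta = list(all = theta),
                           group_of = setNames(rep("all", N),
                                               sprintf("L%03d", seq_len(N))),
                           mode = "model"))
}
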