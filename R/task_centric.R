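#' Per-task completion frequency and mean rank within a group
#'
#' For each task, over the learners carrying `label` (or the whole cohort if
#' no grouping is supplied): (1) the completion frequency — the fraction of
#' those learners who completed the task — and (2) the mean rank — the mean
#' 1-based position of the task within the completers' own sequences. Rank is
#' sequence position, not calendar time. Mean rank is `NA` for tasks nobody
#' in the group completed.
#'
#' @param x a [cohort].
#' @param group optional [group_labelling].
#' @param label group label to select when `group` is given.
#' @return An object of class `task_stats`: data.frame with columns
#'   `task_id`, `frequency`, `mean_rank`, plus attributes `n_learners` and
#'   `label`.
#' @export
task_completion_stats <- function(x, group = NULL, label = NULL) {
  stopifnot(inherits(x, "cohort"))
  recs <- x$learners
  if (!is.null(group)) {
    if (is.null(label)) stop("`label` is required when `group` is given")
    ids <- intersect(group_members(group, label), names(recs))
    if (!length(ids)) stop("group '", label, "' has no members in this cohort")
    recs <- recs[ids]
  }
  T <- x$catalog$T
  n_done <- integer(T)
  rank_sum <- numeric(T)
  for (l in recs) {
    s <- l$sequence
    if (length(s)) {
      n_done[s] <- n_done[s] + 1L
      rank_sum[s] <- rank_sum[s] + seq_along(s)
    }
  }
  out <- data.frame(task_id = seq_len(T),
                    frequency = n_done / length(recs),
                    mean_rank = ifelse(n_done > 0, rank_sum / n_done, NA_real_))
  attr(out, "n_learners") <- length(recs)
  attr(out, "label") <- label %||% "all"
  class(out) <- c("task_stats", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Contrast per-task statistics between two groups
#'
#' For each task computes `dfreq = frequency(HP) - frequency(LP)` and
#' `drank = mean_rank(LP) - mean_rank(HP)`, so that a task in the upper half
#' (`drank > 0`) was completed earlier on average by the high-performing
#' group, and a task in the right half (`dfreq > 0`) more frequently by them.
#' Tasks with a mean rank missing in either group get `drank = NA` and are
#' excluded from the per-type summaries. For each task type the median and
#' inter-quartile range of `(dfreq, drank)` are reported over tasks with both
#' coordinates defined.
#'
#' @param stats_hp,stats_lp [task_completion_stats()] results for the two
#'   groups, computed on the same catalog.
#' @param catalog the shared [task_catalog].
#' @return An object of class `task_contrast`: list with `tasks` (data.frame:
#'   task_id, type, dfreq, drank, quadrant) and `by_type` (data.frame of
#'   per-type medians and IQRs with the number of contributing tasks).
#' @export
group_task_contrast <- function(stats_hp, stats_lp, catalog) {
  stopifnot(inherits(catalog, "task_catalog"),
            nrow(stats_hp) == catalog$T, nrow(stats_lp) == catalog$T)
  dfreq <- stats_hp$frequency - stats_lp$frequency
  drank <- stats_lp$mean_rank - stats_hp$mean_rank
  quadrant <- ifelse(is.na(drank), NA_character_,
                     paste0(ifelse(drank >= 0, "upper", "lower"),
                            "-",
                            ifelse(dfreq >= 0, "right", "left")))
  tasks <- data.frame(task_id = catalog$task_ids, type = catalog$type,
                      dfreq = dfreq, drank = drank, quadrant = quadrant)
  ok <- !is.na(drank)
  by_type <- do.call(rbind, lapply(sort(unique(catalog$type)), function(tp) {
    sel <- ok & catalog$type == tp
    if (!any(sel))
      return(data.frame(type = tp, n = 0L, dfreq_median = NA_real_,
                        dfreq_iqr = NA_real_, drank_median = NA_real_,
                        drank_iqr = NA_real_))
    data.frame(type = tp, n = sum(sel),
               dfreq_median = median(dfreq[sel]),
               dfreq_iqr = stats::IQR(dfreq[sel]),
               drank_median = median(drank[sel]),
               drank_iqr = stats::IQR(drank[sel]))
  }))
  structure(list(tasks = tasks, by_type = by_type), class = "task_contrast")
}

#' @export
print.task_contrast <- function(x, ...) {
  cat("<task_contrast>\n")
  print(x$by_type, row.names = FALSE)
  invisible(x)
}

#' Student confidence scores
#'
#' For each student the confidence score is the fraction of their survey
#' responses that were 'confident':
#' `C = confident / (revisit + support + confident)`,
#' computed over the tasks the student actually answered; a larger value
#' indicates a more confident student. Also reports, per task, the proportion
#' of responding students who felt confident.
#'
#' @param x a [cohort] in which at least one learner carries confidence
#'   responses.
#' @return An object of class `confidence_report`: list with `student`
#'   (data.frame learner_id, n_responses, C — `NA` for students with no
#'   responses), `task` (data.frame task_id, n_responses, prop_confident) and
#'   `responses` (long data.frame learner_id, task_id, confident).
#' @export
confidence_scores <- function(x) {
  stopifnot(inherits(x, "cohort"))
  long <- do.call(rbind, lapply(x$learners, function(l) {
    if (is.null(l$confidence) || !length(l$confidence)) return(NULL)
    data.frame(learner_id = l$learner_id,
               task_id = as.integer(names(l$confidence)),
               confident = unname(l$confidence) == "confident")
  }))
  if (is.null(long)) stop("no learner carries confidence responses")
  ids <- names(x$learners)
  student <- do.call(rbind, lapply(ids, function(id) {
    sel <- long$learner_id == id
    data.frame(learner_id = id, n_responses = sum(sel),
               C = if (any(sel)) mean(long$confident[sel]) else NA_real_)
  }))
  task <- do.call(rbind, lapply(sort(unique(long$task_id)), function(t) {
    sel <- long$task_id == t
    data.frame(task_id = t, n_responses = sum(sel),
               prop_confident = mean(long$confident[sel]))
  }))
  structure(list(student = student, task = task, responses = long),
            class = "confidence_report")
}

#' @export
print.confidence_report <- function(x, ...) {
  cat(sprintf("<confidence_report> %d students with responses, %d tasks; mean C = %.3f\n",
              sum(!is.na(x$student$C)), nrow(x$task),
              mean(x$student$C, na.rm = TRUE)))
  invisible(x)
}

#' Compare confidence between two groups
#'
#' Default pairing unit is the task: for every task answered by members of
#' both groups, the group-mean proportion confident is computed, and the two
#' per-task vectors are compared with a two-sided paired t-test (tasks are
#' the natural index shared by both groups). With `pairing = "student"` the
#' per-student scores C are compared with a Welch two-sample t-test instead,
#' since students cannot be paired across groups.
#'
#' @param report a [confidence_scores()] result.
#' @param groups a [group_labelling] with exactly the two labels to compare.
#' @param labels character of length 2: the labels, first minus second.
#' @param pairing `"task"` (paired over tasks, default) or `"student"`.
#' @return An object of class `confidence_test`: list with `statistic`,
#'   `p_value`, `df`, `pairing`, `n_pairs` and `groups` (per-group mean and
#'   sd of the compared values).
#' @export
group_confidence_test <- function(report, groups, labels = c("g1", "g2"),
                                  pairing = c("task", "student")) {
  stopifnot(inherits(report, "confidence_report"),
            inherits(groups, "group_labelling"), length(labels) == 2)
  pairing <- match.arg(pairing)
  long <- report$responses
  m1 <- group_members(groups, labels[1])
  m2 <- group_members(groups, labels[2])
  if (!any(long$learner_id %in% m1) || !any(long$learner_id %in% m2))
    stop("both groups need at least one learner with confidence responses")

  if (pairing == "task") {
    tasks <- sort(unique(long$task_id))
    pm <- function(members) vapply(tasks, function(t) {
      sel <- long$task_id == t & long$learner_id %in% members
      if (any(sel)) mean(long$confident[sel]) else NA_real_
    }, numeric(1))
    v1 <- pm(m1)
    v2 <- pm(m2)
    ok <- !is.na(v1) & !is.na(v2)
    if (sum(ok) < 2) stop("fewer than 2 tasks answered by both groups")
    v1 <- v1[ok]
    v2 <- v2[ok]
    if (all(v1 == v2)) {
      tt <- list(statistic = c(t = 0), p.value = 1, parameter = c(df = sum(ok) - 1))
    } else {
      tt <- t.test(v1, v2, paired = TRUE)
    }
    n_pairs <- sum(ok)
  } else {
    v1 <- report$student$C[report$student$learner_id %in% m1]
    v2 <- report$student$C[report$student$learner_id %in% m2]
    v1 <- v1[!is.na(v1)]
    v2 <- v2[!is.na(v2)]
    if (length(v1) < 2 || length(v2) < 2)
      stop("need at least 2 scored students per group")
    tt <- t.test(v1, v2)
    n_pairs <- NA_integer_
  }
  grp <- data.frame(label = labels,
                    mean = c(mean(v1), mean(v2)),
                    sd = c(sd(v1), sd(v2)),
                    n = c(length(v1), length(v2)))
  structure(list(statistic = unname(tt$statistic), p_value = tt$p.value,
                 df = unname(tt$parameter), pairing = pairing,
                 n_pairs = n_pairs, groups = grp),
            class = "confidence_test")
}

#' @export
print.confidence_test <- function(x, ...) {
  cat(sprintf("<confidence_test> %s-paired: t = %.3f, p = %.4f\n",
              x$pairing, x$statistic, x$p_value))
  print(x$groups, row.names = FALSE)
  invisible(x)
}
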