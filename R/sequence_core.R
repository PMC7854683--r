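#' Task types recognised in a course catalog
#'
#' The six task categories used throughout: marked coursework and quizzes,
#' and unmarked multi-response polls, readings/videos, G-chart questions and
#' discussion posts.
#' @export
TASK_TYPES <- c("coursework", "quiz", "multi_response_poll",
                "reading_video", "g_chart", "discussion_post")

#' Construct a task catalog
#'
#' A catalog describes the nominal course design: tasks are identified by
#' integers `1..T` whose value is also the nominal completion rank, each task
#' belongs to exactly one session (a weekly block of consecutive tasks) and
#' has one of the six types in [TASK_TYPES].
#'
#' @param session integer vector of length `T`; `session[i]` is the session of
#'   task `i`. Must be non-decreasing in task order and cover `1..S` with no
#'   gaps.
#' @param type character vector of length `T` with values from [TASK_TYPES].
#' @return An object of class `task_catalog` with elements `task_ids`,
#'   `session`, `type`, `T` and `S`.
#' @examples
#' cat3 <- task_catalog(session = c(1, 1, 2),
#'                      type = rep("reading_video", 3))
#' cat3$T
#' @export
task_catalog <- function(session, type) {
  session <- as.integer(session)
  type <- as.character(type)
  T <- length(session)
  if (T < 1L) stop("catalog must contain at least one task")
  if (length(type) != T) stop("`session` and `type` must have equal length")
  if (any(diff(session) < 0L))
    stop("session indices must be non-decreasing in nominal task order")
  S <- max(session)
  if (!identical(sort(unique(session)), seq_len(S)))
    stop("sessions must be exactly 1..S with no gaps")
  bad <- setdiff(unique(type), TASK_TYPES)
  if (length(bad))
    stop("unknown task type(s): ", paste(bad, collapse = ", "))
  structure(list(task_ids = seq_len(T), session = session, type = type,
                 T = T, S = S),
            class = "task_catalog")
}

#' @export
print.task_catalog <- function(x, ...) {
  cat(sprintf("<task_catalog> %d tasks in %d sessions\n", x$T, x$S))
  tt <- table(x$type)
  cat("  types:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a learner record
#'
#' One learner's ordered completion sequence: the task IDs in the order the
#' learner completed them, plus optional grade, demographics and confidence
#' survey responses.
#'
#' @param learner_id character scalar.
#' @param sequence integer vector of distinct task IDs in completion order
#'   (may be empty; may omit tasks).
#' @param grade final course grade in `[0, 100]`, or `NA`.
#' @param demographics optional named list (e.g. gender, age).
#' @param confidence optional named character vector: names are task IDs,
#'   values one of `"confident"`, `"revisit"`, `"support"`.
#' @return An object of class `learner_record`.
#' @export
learner_record <- function(learner_id, sequence, grade = NA_real_,
                           demographics = NULL, confidence = NULL) {
  sequence <- as.integer(sequence)
  if (anyDuplicated(sequence))
    stop("learner ", learner_id, ": task(s) ",
         paste(unique(sequence[duplicated(sequence)]), collapse = ", "),
         " appear more than once in the sequence")
  if (!is.na(grade) && (grade < 0 || grade > 100))
    stop("grade must lie in [0, 100]")
  if (!is.null(confidence)) {
    bad <- setdiff(unique(confidence), c("confident", "revisit", "support"))
    if (length(bad))
      stop("invalid confidence response(s): ", paste(bad, collapse = ", "))
  }
  structure(list(learner_id = as.character(learner_id), sequence = sequence,
                 grade = as.numeric(grade), demographics = demographics,
                 confidence = confidence),
            class = "learner_record")
}

#' @export
print.learner_record <- function(x, ...) {
  cat(sprintf("<learner_record> %s: %d tasks completed, grade %s\n",
              x$learner_id, length(x$sequence),
              ifelse(is.na(x$grade), "NA", format(x$grade))))
  invisible(x)
}

#' Assemble a cohort from a catalog and learner records
#'
#' A cohort bundles the task catalog with the ensemble of learner sequences
#' and validates every record against the catalog.
#'
#' @param catalog a [task_catalog].
#' @param learners list of [learner_record] objects with unique IDs.
#' @return An object of class `cohort` with elements `catalog`, `learners`
#'   (named by learner ID) and `N`.
#' @export
cohort <- function(catalog, learners) {
  stopifnot(inherits(catalog, "task_catalog"))
  if (length(learners) < 1L) stop("a cohort needs at least one learner")
  ids <- vapply(learners, function(l) l$learner_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate learner ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (l in learners) {
    unknown <- setdiff(l$sequence, catalog$task_ids)
    if (length(unknown))
      stop("learner ", l$learner_id, ": unknown task ID(s) ",
           paste(unknown, collapse = ", "), " not in catalog (T = ",
           catalog$T, ")")
    if (!is.null(l$confidence)) {
      ct <- as.integer(names(l$confidence))
      unknown <- setdiff(ct, catalog$task_ids)
      if (length(unknown))
        stop("learner ", l$learner_id, ": confidence responses for unknown ",
             "task ID(s) ", paste(unknown, collapse = ", "))
    }
  }
  names(learners) <- ids
  structure(list(catalog = catalog, learners = learners, N = length(learners)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  lens <- vapply(x$learners, function(l) length(l$sequence), integer(1))
  cat(sprintf("<cohort> %d learners, %d tasks (%d sessions)\n",
              x$N, x$catalog$T, x$catalog$S))
  cat(sprintf("  completed tasks per learner: median %d, range %d-%d\n",
              as.integer(median(lens)), min(lens), max(lens)))
  invisible(x)
}

#' Completion sequences of a cohort as a plain list
#' @param x a `cohort` or list of `learner_record`s.
#' @return Named list of integer vectors.
#' @export
sequences <- function(x) {
  recs <- if (inherits(x, "cohort")) x$learners else x
  lapply(recs, function(l) l$sequence)
}

#' Build a cohort from a completion event log
#'
#' Orders each learner's completion events, deduplicates repeated completions
#' of the same task (keeping the earliest), validates task IDs against the
#' catalog, and optionally attaches grades and confidence responses.
#'
#' Ordering uses the `order_index` column when present; otherwise the
#' `timestamp` column. Two events of one learner with identical timestamps
#' and no order index are refused rather than broken arbitrarily, because
#' every downstream statistic is a function of the completion order.
#'
#' @param events data.frame with columns `learner_id`, `task_id` and at least
#'   one of `order_index` (integer) or `timestamp` (sortable, e.g. ISO-8601
#'   strings or POSIXct).
#' @param catalog a [task_catalog].
#' @param grades optional data.frame with columns `learner_id`, `grade`.
#' @param confidence optional data.frame with columns `learner_id`,
#'   `task_id`, `response`.
#' @return A [cohort].
#' @examples
#' cat3 <- task_catalog(c(1, 1, 2), rep("quiz", 3))
#' ev <- data.frame(learner_id = c("A", "A", "B"),
#'                  task_id = c(2, 1, 1),
#'                  order_index = c(1, 2, 1))
#' load_cohort(ev, cat3)
#' @export
load_cohort <- function(events, catalog, grades = NULL, confidence = NULL) {
  stopifnot(inherits(catalog, "task_catalog"))
  req <- c("learner_id", "task_id")
  if (!all(req %in% names(events)))
    stop("events must have columns learner_id and task_id")
  has_order <- "order_index" %in% names(events)
  has_time <- "timestamp" %in% names(events)
  if (!has_order && !has_time)
    stop("events need an order_index or timestamp column")

  events$task_id <- as.integer(events$task_id)
  bad <- which(!(events$task_id %in% catalog$task_ids))
  if (length(bad))
    stop("events row ", bad[1], ": unknown task_id ", events$task_id[bad[1]],
         " (catalog has tasks 1..", catalog$T, ")")

  grade_of <- NULL
  if (!is.null(grades))
    grade_of <- setNames(as.numeric(grades$grade), as.character(grades$learner_id))

  recs <- lapply(split(events, as.character(events$learner_id)), function(ev) {
    id <- as.character(ev$learner_id[1])
    if (has_order) {
      ev <- ev[order(as.integer(ev$order_index)), , drop = FALSE]
    } else {
      ts <- ev$timestamp
      if (anyDuplicated(ts))
        stop("learner ", id, ": tied timestamps with no order_index column; ",
             "supply an explicit order_index to disambiguate")
      ev <- ev[order(ts), , drop = FALSE]
    }
    seq <- ev$task_id[!duplicated(ev$task_id)] # keep earliest completion
    g <- if (!is.null(grade_of) && id %in% names(grade_of)) grade_of[[id]] else NA_real_
    learner_record(id, seq, grade = g)
  })

  # graded learners with no completion events still belong to the cohort;
  # the grades table also fixes the learner ordering
  if (!is.null(grade_of)) {
    for (id in setdiff(names(grade_of), names(recs)))
      recs[[id]] <- learner_record(id, integer(0), grade = grade_of[[id]])
    recs <- recs[unique(c(intersect(names(grade_of), names(recs)),
                          names(recs)))]
  }

  if (!is.null(confidence)) {
    confidence$learner_id <- as.character(confidence$learner_id)
    for (id in intersect(names(recs), unique(confidence$learner_id))) {
      cf <- confidence[confidence$learner_id == id, , drop = FALSE]
      recs[[id]]$confidence <-
        setNames(as.character(cf$response), as.character(cf$task_id))
    }
  }
  cohort(catalog, recs)
}

#' Write / read a cohort in the canonical CSV layout
#'
#' `write_cohort_csv()` emits `events.csv` (learner_id, task_id, order_index),
#' `catalog.csv` (task_id, session, type), `grades.csv` and `confidence.csv`
#' into `dir`; `read_cohort_csv()` loads them back through [load_cohort()].
#' The pair round-trips sequences, grades and confidence maps exactly.
#'
#' @param x a [cohort].
#' @param dir directory path.
#' @return `write_cohort_csv()` returns `dir` invisibly; `read_cohort_csv()`
#'   returns a [cohort].
#' @export
write_cohort_csv <- function(x, dir) {
  stopifnot(inherits(x, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ev <- do.call(rbind, lapply(x$learners, function(l) {
    if (!length(l$sequence)) return(NULL)
    data.frame(learner_id = l$learner_id, task_id = l$sequence,
               order_index = seq_along(l$sequence))
  }))
  write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  write.csv(data.frame(task_id = x$catalog$task_ids,
                       session = x$catalog$session,
                       type = x$catalog$type),
            file.path(dir, "catalog.csv"), row.names = FALSE)
  gr <- data.frame(learner_id = names(x$learners),
                   grade = vapply(x$learners, function(l) l$grade, numeric(1)))
  write.csv(gr, file.path(dir, "grades.csv"), row.names = FALSE)
  cf <- do.call(rbind, lapply(x$learners, function(l) {
    if (is.null(l$confidence)) return(NULL)
    data.frame(learner_id = l$learner_id,
               task_id = as.integer(names(l$confidence)),
               response = unname(l$confidence))
  }))
  if (!is.null(cf))
    write.csv(cf, file.path(dir, "confidence.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir) {
  cat_df <- read.csv(file.path(dir, "catalog.csv"))
  cat_df <- cat_df[order(cat_df$task_id), , drop = FALSE]
  catalog <- task_catalog(cat_df$session, cat_df$type)
  events <- read.csv(file.path(dir, "events.csv"),
                     colClasses = c(learner_id = "character"))
  gpath <- file.path(dir, "grades.csv")
  grades <- if (file.exists(gpath))
    read.csv(gpath, colClasses = c(learner_id = "character")) else NULL
  cpath <- file.path(dir, "confidence.csv")
  confidence <- if (file.exists(cpath))
    read.csv(cpath, colClasses = c(learner_id = "character")) else NULL
  load_cohort(events, catalog, grades = grades, confidence = confidence)
}

#' Construct a group labelling
#'
#' Maps a subset of learner IDs to group labels (e.g. `"g1"`/`"g2"` for the
#' top/bottom grade quantiles).
#'
#' @param group_of named character vector: names are learner IDs, values are
#'   labels.
#' @param description free-text description of how the groups were formed.
#' @return An object of class `group_labelling`.
#' @export
group_labelling <- function(group_of, description = "") {
  if (is.null(names(group_of)) || anyDuplicated(names(group_of)))
    stop("group_of must be named by unique learner IDs")
  structure(list(group_of = group_of, description = description),
            class = "group_labelling")
}

#' @export
print.group_labelling <- function(x, ...) {
  tt <- table(x$group_of)
  cat("<group_labelling>", paste(sprintf("%s: %d", names(tt), tt),
                                 collapse = ", "), "\n")
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  invisible(x)
}

#' Learner IDs carrying a given label
#' @param groups a [group_labelling].
#' @param label group label to select.
#' @return Character vector of learner IDs.
#' @export
group_members <- function(groups, label) {
  names(groups$group_of)[groups$group_of == label]
}

#' Split a cohort into top and bottom grade quantiles
#'
#' Labels the `floor(N * fraction)` highest-graded learners `g1` and the same
#' number of lowest-graded learners `g2` (the default quarter tails give a
#' clearly bimodal performance contrast). Learners are ranked by grade, ties
#' broken by learner ID lexicographically, so the split is deterministic.
#'
#' @param x a [cohort]; every learner must have a grade.
#' @param fraction tail fraction in `(0, 0.5]`; default `0.25`.
#' @return A [group_labelling] with labels `"g1"` (top) and `"g2"` (bottom).
#' @export
split_by_grade_quantile <- function(x, fraction = 0.25) {
  stopifnot(inherits(x, "cohort"))
  if (fraction <= 0 || fraction > 0.5)
    stop("fraction must lie in (0, 0.5]")
  grades <- vapply(x$learners, function(l) l$grade, numeric(1))
  ungraded <- names(grades)[is.na(grades)]
  if (length(ungraded))
    stop("learner(s) without grades: ", paste(ungraded, collapse = ", "))
  k <- floor(x$N * fraction)
  if (k < 1L) stop("fraction too small: floor(N * fraction) = 0")
  # one global ranking (grade desc, ID asc): g1 = head, g2 = tail => disjoint
  ord <- names(grades)[order(-grades, names(grades))]
  g1 <- ord[seq_len(k)]
  g2 <- rev(ord)[seq_len(k)]
  group_labelling(
    setNames(c(rep("g1", k), rep("g2", k)), c(g1, g2)),
    sprintf("top/bottom %.0f%% by grade (N = %d, %d per group)",
            100 * fraction, x$N, k))
}

#' First n completed tasks of a learner record
#'
#' @param record a [learner_record].
#' @param n non-negative prefix length; clamped to the sequence length.
#' @return A [learner_record] with the truncated sequence and all metadata
#'   carried over.
#' @export
prefix <- function(record, n) {
  stopifnot(inherits(record, "learner_record"), n >= 0)
  record$sequence <- head(record$sequence, n)
  record
}
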