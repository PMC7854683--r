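#' Position probability matrix P
#'
#' Counts, for every task `i` and sequence position `j`, the number of
#' learners `n_ij` who completed task `i` as their `j`th task, and normalises
#' each row to the probability `p_ij = n_ij / sum_j n_ij`. A cohort in which
#' every learner completes all tasks in nominal order yields the identity
#' matrix; off-diagonal mass measures departure from the nominal order.
#'
#' @param x a [cohort].
#' @return An object of class `position_matrix`: list with `P` (T x T row-
#'   stochastic matrix; all-zero rows for never-completed tasks), `counts`
#'   (`n_ij`) and `never_completed` (integer task IDs with no completions).
#' @export
position_probability_matrix <- function(x) {
  stopifnot(inherits(x, "cohort"))
  T <- x$catalog$T
  counts <- matrix(0L, T, T, dimnames = list(task = 1:T, position = 1:T))
  for (s in sequences(x)) {
    if (length(s))
      counts[cbind(s, seq_along(s))] <- counts[cbind(s, seq_along(s))] + 1L
  }
  rs <- rowSums(counts)
  P <- counts / ifelse(rs > 0, rs, 1)
  structure(list(P = P, counts = counts,
                 never_completed = which(rs == 0)),
            class = "position_matrix")
}

#' @export
print.position_matrix <- function(x, ...) {
  cat(sprintf("<position_matrix> %d tasks; diagonal mass %.3f; %d never completed\n",
              nrow(x$P), mean(diag(x$P)), length(x$never_completed)))
  invisible(x)
}

seq_to_states <- function(s, resolution, catalog, include_start) {
  st <- if (resolution == "session") catalog$session[s] else s
  if (include_start) c(0L, st) else st
}

#' Transition summary at task or session resolution
#'
#' Counts the immediate precedences `m_ij` (task or session `j` directly
#' following `i` in a learner sequence), the joint probabilities
#' `p_(i->j) = m_ij / sum m_ij` over all observed transitions, and the
#' conditional probabilities `pi_ij = p_(i->j) / sum_j p_(i->j)`. Note that
#' `pi` is not the transition matrix of a stochastic process: tasks are
#' acquired irreversibly, so `pi` only summarises observed successions.
#'
#' At session resolution the task IDs are replaced by their session IDs, so
#' within-session transitions appear as diagonal self-loops (retained here;
#' suppress them at plotting time if desired). An optional virtual `start`
#' state (state 0) makes the first completion itself a transition; it is off
#' by default at task resolution and on at session resolution.
#'
#' @param x a [cohort].
#' @param resolution `"task"` or `"session"`.
#' @param include_start logical; default `FALSE` for task resolution, `TRUE`
#'   for session resolution.
#' @return An object of class `transition_summary`: list with `states`
#'   (integer state IDs, 0 = start), `counts` (`m`), `joint`, `conditional`
#'   (rows with no outgoing transitions are `NA` and listed in
#'   `undefined_rows`), `resolution` and `include_start`.
#' @export
transition_summary <- function(x, resolution = c("task", "session"),
                               include_start = NULL) {
  stopifnot(inherits(x, "cohort"))
  resolution <- match.arg(resolution)
  if (is.null(include_start)) include_start <- resolution == "session"
  n_states <- if (resolution == "session") x$catalog$S else x$catalog$T
  states <- if (include_start) 0:n_states else 1:n_states
  labs <- as.character(states)
  k <- length(states)
  counts <- matrix(0L, k, k, dimnames = list(from = labs, to = labs))
  off <- if (include_start) 1L else 0L
  for (s in sequences(x)) {
    st <- seq_to_states(s, resolution, x$catalog, include_start)
    if (length(st) >= 2L) {
      idx <- cbind(st[-length(st)] + off, st[-1] + off)
      for (r in seq_len(nrow(idx)))
        counts[idx[r, 1], idx[r, 2]] <- counts[idx[r, 1], idx[r, 2]] + 1L
    }
  }
  tot <- sum(counts)
  joint <- if (tot > 0) counts / tot else counts * 0
  rs <- rowSums(joint)
  conditional <- joint / ifelse(rs > 0, rs, NA_real_)
  undefined <- states[rs == 0]
  structure(list(states = states, counts = counts, joint = joint,
                 conditional = conditional, undefined_rows = undefined,
                 resolution = resolution, include_start = include_start),
            class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  cat(sprintf("<transition_summary> %s resolution, %d states%s, %d transitions\n",
              x$resolution, length(x$states),
              if (x$include_start) " (incl. start)" else "", sum(x$counts)))
  if (length(x$undefined_rows))
    cat("  rows with no outgoing transitions:",
        paste(x$undefined_rows, collapse = ", "), "\n")
  invisible(x)
}

check_same_states <- function(a, b) {
  stopifnot(inherits(a, "transition_summary"), inherits(b, "transition_summary"))
  if (a$resolution != b$resolution || !identical(a$states, b$states))
    stop("transition summaries have mismatched resolution or state sets")
}

#' Signed difference between two conditional transition matrices
#'
#' Computes `delta = pi_A - pi_B` (e.g. high minus low performers) and splits
#' it into the positive part (transitions more probable in A) and negative
#' part (more probable in B). Rows undefined in either input (no outgoing
#' transitions) are `NA` throughout and listed in `missing_rows`.
#'
#' @param pi_A,pi_B [transition_summary] objects on the same state set.
#' @return An object of class `delta_transition`: list with `delta`,
#'   `positive`, `negative`, `missing_rows`, `states`, `resolution`.
#' @export
delta_transition <- function(pi_A, pi_B) {
  check_same_states(pi_A, pi_B)
  delta <- pi_A$conditional - pi_B$conditional
  pos <- pmax(delta, 0)
  neg <- pmax(-delta, 0)
  missing_rows <- union(pi_A$undefined_rows, pi_B$undefined_rows)
  structure(list(delta = delta, positive = pos, negative = neg,
                 missing_rows = missing_rows, states = pi_A$states,
                 resolution = pi_A$resolution),
            class = "delta_transition")
}

#' Jensen-Shannon divergence and distance between discrete distributions
#'
#' Base-2 Jensen-Shannon divergence
#' `JSD(p, q) = H((p + q)/2) - (H(p) + H(q))/2` (entropies in bits) and its
#' square root, the Jensen-Shannon distance, which is a metric bounded in
#' `[0, 1]`: 0 for identical distributions, 1 for distributions with disjoint
#' support. Zero probabilities follow the convention `0 log 0 = 0`; no
#' smoothing is applied.
#'
#' @param p,q non-negative numeric vectors of equal length; normalised to sum
#'   to 1 internally.
#' @return A single number.
#' @examples
#' js_distance(c(1, 0), c(0, 1))   # maximally different -> 1
#' js_distance(c(1, 0), c(1, 0))   # identical -> 0
#' @export
js_divergence <- function(p, q) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  if (sum(p) <= 0 || sum(q) <= 0) stop("distributions must have positive mass")
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  h <- function(v) {
    v <- v[v > 0]
    -sum(v * log2(v))
  }
  d <- h(m) - (h(p) + h(q)) / 2
  min(max(d, 0), 1) # clip floating-point excursions
}

#' @rdname js_divergence
#' @export
js_distance <- function(p, q) sqrt(js_divergence(p, q))

#' Jensen-Shannon profile between two transition summaries
#'
#' Compares two groups' transition structure row by row (outgoing: where do
#' learners go *from* each state) and column by column (incoming: where do
#' learners arrive at each state *from*), using the Jensen-Shannon distance.
#' Rows undefined in either summary are skipped and reported. Incoming
#' distributions are columns renormalised to sum to 1 — either columns of the
#' conditional matrix (default) or of the joint matrix.
#'
#' @param pi_A,pi_B [transition_summary] objects on the same state set.
#' @param incoming `"renormalised"` (columns of the conditional matrix) or
#'   `"joint"` (columns of the joint matrix); both are renormalised before
#'   comparison.
#' @return An object of class `js_profile`: list with `rows` and `cols`
#'   (named distance vectors, `NA` where skipped), `mean_outgoing`,
#'   `mean_incoming`, `skipped_rows`, `skipped_cols`.
#' @export
js_profile <- function(pi_A, pi_B, incoming = c("renormalised", "joint")) {
  check_same_states(pi_A, pi_B)
  incoming <- match.arg(incoming)
  states <- pi_A$states
  k <- length(states)

  rows <- setNames(rep(NA_real_, k), as.character(states))
  for (i in seq_len(k)) {
    a <- pi_A$conditional[i, ]
    b <- pi_B$conditional[i, ]
    if (!anyNA(a) && !anyNA(b) && sum(a) > 0 && sum(b) > 0)
      rows[i] <- js_distance(a, b)
  }

  colsrc_A <- if (incoming == "joint") pi_A$joint else pi_A$conditional
  colsrc_B <- if (incoming == "joint") pi_B$joint else pi_B$conditional
  # restrict incoming comparisons to origin states defined in both groups
  defined <- !(states %in% union(pi_A$undefined_rows, pi_B$undefined_rows))
  cols <- setNames(rep(NA_real_, k), as.character(states))
  for (j in seq_len(k)) {
    a <- colsrc_A[defined, j]
    b <- colsrc_B[defined, j]
    if (length(a) && sum(a) > 0 && sum(b) > 0)
      cols[j] <- js_distance(a, b)
  }

  structure(list(rows = rows, cols = cols,
                 mean_outgoing = mean(rows, na.rm = TRUE),
                 mean_incoming = mean(cols, na.rm = TRUE),
                 skipped_rows = states[is.na(rows)],
                 skipped_cols = states[is.na(cols)],
                 incoming = incoming),
            class = "js_profile")
}

#' @export
print.js_profile <- function(x, ...) {
  cat(sprintf("<js_profile> mean outgoing %.3f, mean incoming %.3f\n",
              x$mean_outgoing, x$mean_incoming))
  invisible(x)
}

#' Per-learner deviation matrix from the nominal order
#'
#' For learner `k` with sequence length `n_k`, the entry at sequence position
#' `j` is the signed normalised deviation
#' `d = j / n_k - r(t_j) / T`, where `r` is the nominal rank of the completed
#' task. Positive entries mean the task was completed later than its nominal
#' place (rendered red in heat maps), negative earlier (blue); a learner who
#' completes the full course exactly in nominal order has an all-zero (white)
#' row. Positions beyond `n_k` are `NA` (the black region after a learner
#' stops).
#'
#' @param x a [cohort].
#' @param order_by `"grade"` (descending, ties by learner ID) or `"id"`.
#' @return An object of class `deviation_matrix`: list with `D` (N x max
#'   sequence length), `completed_length` and `order` (learner IDs row order).
#' @export
deviation_matrix <- function(x, order_by = c("grade", "id")) {
  stopifnot(inherits(x, "cohort"))
  order_by <- match.arg(order_by)
  T <- x$catalog$T
  ids <- names(x$learners)
  if (order_by == "grade") {
    g <- vapply(x$learners, function(l) l$grade, numeric(1))
    ids <- ids[order(-g, ids)]
  } else ids <- sort(ids)
  lens <- vapply(x$learners[ids], function(l) length(l$sequence), integer(1))
  ncol_D <- max(lens, 1L)
  D <- matrix(NA_real_, length(ids), ncol_D,
              dimnames = list(learner = ids, position = seq_len(ncol_D)))
  for (id in ids) {
    s <- x$learners[[id]]$sequence
    n <- length(s)
    if (n > 0) D[id, 1:n] <- (1:n) / n - s / T
  }
  structure(list(D = D, completed_length = lens, order = ids,
                 order_by = order_by),
            class = "deviation_matrix")
}

#' @export
print.deviation_matrix <- function(x, ...) {
  cat(sprintf("<deviation_matrix> %d learners x %d positions; mean |d| = %.3f\n",
              nrow(x$D), ncol(x$D), mean(abs(x$D), na.rm = TRUE)))
  invisible(x)
}
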