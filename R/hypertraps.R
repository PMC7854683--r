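# Reduced hypercubic acquisition model.
#
# The general Markov model on acquired-task subsets has 2^T states and
# T * 2^(T-1) transition parameters, intractable at course scale. The
# reduction keeps T^2 parameters in a matrix theta: the log-propensity of
# acquiring task j next is theta[j,j] plus the sum of theta[i,j] over tasks i
# already acquired, and the next-task distribution is the softmax of these
# propensities over the not-yet-acquired tasks. The full hypercube is never
# materialised. Because completion order is fully observed, the likelihood of
# a sequence is the exact product of its step probabilities — no latent-path
# sampling is needed.

as_seq_list <- function(records) {
  if (inherits(records, "cohort")) return(sequences(records))
  if (inherits(records, "learner_record")) return(list(records$sequence))
  lapply(records, function(r) {
    if (inherits(r, "learner_record")) r$sequence else as.integer(r)
  })
}

check_theta <- function(theta) {
  if (!is.matrix(theta) || nrow(theta) != ncol(theta) || nrow(theta) < 2)
    stop("theta must be a square matrix with T >= 2")
  if (!all(is.finite(theta))) stop("theta must have finite entries")
  invisible(theta)
}

#' Next-task distribution of the hypercubic model
#'
#' Given the parameter matrix `theta` and the set of already-acquired tasks,
#' returns the probability of each not-yet-acquired task being completed
#' next: `P(j | A) = w_j / sum w`, with
#' `log w_j = theta[j,j] + sum_(i in A) theta[i,j]`, evaluated in log space.
#'
#' @param theta T x T numeric matrix (diagonal: basal log-propensities;
#'   off-diagonal `[i, j]`: log-influence of acquired `i` on `j`).
#' @param acquired integer vector of acquired task IDs (possibly empty); must
#'   not be the full task set.
#' @return Named numeric vector of probabilities over the unacquired tasks,
#'   summing to 1.
#' @examples
#' th <- matrix(0, 3, 3); th[1, 2] <- log(2)
#' next_task_distribution(th, acquired = 1)  # P(2) = 2/3, P(3) = 1/3
#' @export
next_task_distribution <- function(theta, acquired = integer(0)) {
  check_theta(theta)
  T <- nrow(theta)
  acquired <- as.integer(acquired)
  if (anyDuplicated(acquired) || any(acquired < 1 | acquired > T))
    stop("acquired must be distinct task IDs in 1..T")
  remaining <- setdiff(seq_len(T), acquired)
  if (!length(remaining)) stop("all tasks acquired: no next task exists")
  logw <- diag(theta)
  if (length(acquired) == 1L) {
    logw <- logw + theta[acquired, ]
  } else if (length(acquired) > 1L) {
    logw <- logw + colSums(theta[acquired, , drop = FALSE])
  }
  logw <- logw[remaining]
  w <- exp(logw - max(logw))
  setNames(w / sum(w), remaining)
}

#' Exact log-likelihood of an observed completion sequence
#'
#' Sum over steps of the log next-task probability; an empty sequence has
#' log-likelihood 0. Partial sequences contribute only their observed steps
#' (the model does not describe when a learner stops).
#'
#' @param theta parameter matrix (see [next_task_distribution()]).
#' @param record a [learner_record] or integer vector of distinct task IDs.
#' @return A single number.
#' @export
sequence_loglik <- function(theta, record) {
  check_theta(theta)
  s <- if (inherits(record, "learner_record")) record$sequence else as.integer(record)
  if (anyDuplicated(s)) stop("sequence contains a repeated task")
  if (any(s < 1 | s > nrow(theta))) stop("sequence contains task IDs outside 1..T")
  if (!length(s)) return(0)
  sum(cpp_step_logliks(theta, s - 1L))
}

#' Per-step log-likelihoods of a sequence
#'
#' The vector whose cumulative sum gives the log-likelihood of every prefix;
#' used by the prefix classifier.
#'
#' @inheritParams sequence_loglik
#' @return Numeric vector, one entry per completed task.
#' @export
step_logliks <- function(theta, record) {
  check_theta(theta)
  s <- if (inherits(record, "learner_record")) record$sequence else as.integer(record)
  if (!length(s)) return(numeric(0))
  cpp_step_logliks(theta, s - 1L)
}

#' Log-likelihood of a set of sequences
#'
#' @param theta parameter matrix.
#' @param records a [cohort], list of [learner_record]s, or list of integer
#'   vectors.
#' @return Sum of [sequence_loglik()] over the records (0 for an empty set).
#' @export
cohort_loglik <- function(theta, records) {
  check_theta(theta)
  seqs <- as_seq_list(records)
  if (!length(seqs)) return(0)
  for (s in seqs) if (anyDuplicated(s)) stop("a sequence contains a repeated task")
  cpp_cohort_loglik(theta, lapply(seqs, function(s) as.integer(s) - 1L))
}

#' Simulate a completion sequence from the model
#'
#' Draws tasks one at a time from [next_task_distribution()] until `n` tasks
#' are acquired. Uses R's RNG: set a seed with `set.seed()` (or pass `seed`)
#' for reproducibility.
#'
#' @param theta parameter matrix.
#' @param n sequence length, `0 <= n <= T`; defaults to the full length T.
#' @param learner_id ID for the returned record.
#' @param seed optional integer seed applied before drawing.
#' @return A [learner_record].
#' @export
simulate_sequence <- function(theta, n = nrow(theta), learner_id = "sim",
                              seed = NULL) {
  check_theta(theta)
  if (n < 0 || n > nrow(theta)) stop("n must lie in 0..T")
  if (!is.null(seed)) set.seed(seed)
  s <- if (n == 0) integer(0) else cpp_simulate_sequence(theta, as.integer(n)) + 1L
  learner_record(learner_id, s)
}

#' Exhaustive ordering probabilities (small-T oracle)
#'
#' Enumerates all `T!` full completion orderings and their exact model
#' probabilities via the step products. Intended as a brute-force oracle for
#' likelihood and simulation code; refuses `T > 8`.
#'
#' @param theta parameter matrix with `T <= 8`.
#' @return Named numeric vector: names are orderings like `"2-1-3"`, values
#'   their probabilities (summing to 1).
#' @export
enumerate_order_probabilities <- function(theta) {
  check_theta(theta)
  T <- nrow(theta)
  if (T > 8) stop("enumeration is limited to T <= 8 (T! orderings)")
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  ords <- perms(seq_len(T))
  probs <- vapply(ords, function(o) exp(sum(cpp_step_logliks(theta, o - 1L))),
                  numeric(1))
  setNames(probs, vapply(ords, paste, character(1), collapse = "-"))
}

#' MCMC configuration for the hypercubic model
#'
#' Random-walk Metropolis settings. The prior is independent uniform on
#' `[prior_lower, prior_upper]` per matrix entry; the proposal perturbs all
#' entries with a spherical Gaussian whose scale starts at `proposal_scale`
#' and is adapted towards ~23% acceptance during burn-in only. The seed is
#' mandatory: every fit is reproducible.
#'
#' @param n_steps total chain length (must exceed `burn_in`).
#' @param burn_in steps discarded (default half the chain).
#' @param thin keep every `thin`-th post-burn-in state.
#' @param proposal_scale initial Gaussian proposal standard deviation.
#' @param prior_lower,prior_upper uniform prior bounds per entry.
#' @param seed integer RNG seed.
#' @param adapt adapt the proposal scale during burn-in.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_steps = 20000, burn_in = floor(n_steps / 2),
                         thin = 50, proposal_scale = 0.1,
                         prior_lower = -10, prior_upper = 10,
                         seed, adapt = TRUE) {
  if (missing(seed)) stop("a seed is mandatory in model_config()")
  stopifnot(is.finite(prior_lower), is.finite(prior_upper),
            prior_lower < prior_upper, n_steps > burn_in, burn_in >= 0,
            thin >= 1, proposal_scale > 0)
  structure(list(n_steps = as.integer(n_steps), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), proposal_scale = proposal_scale,
                 prior_lower = prior_lower, prior_upper = prior_upper,
                 seed = as.integer(seed), adapt = isTRUE(adapt)),
            class = "model_config")
}

#' Fit the hypercubic model by Metropolis MCMC
#'
#' Random-walk Metropolis over the T x T parameter matrix with a uniform
#' prior per entry. Returns thinned post-burn-in draws with the
#' log-likelihood trace and acceptance rate. Fully reproducible given the
#' seed in `config`.
#'
#' @param records a [cohort], list of [learner_record]s or list of integer
#'   sequences; at least one must be non-empty for the data to inform the
#'   fit.
#' @param config a [model_config] (the seed lives here).
#' @param T task count; inferred from a supplied cohort, otherwise required
#'   when the records do not determine it.
#' @param theta_init optional starting matrix (default all zeros).
#' @return An object of class `posterior_samples`: list with `draws`
#'   (T x T x M array), `loglik` (per kept draw), `trace` (full-chain
#'   log-likelihood), `acceptance_rate`, `final_scale`, `config` and `T`.
#' @export
fit_mcmc <- function(records, config, T = NULL, theta_init = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (inherits(records, "cohort")) T <- records$catalog$T
  seqs <- as_seq_list(records)
  if (!length(seqs)) stop("no records supplied")
  if (is.null(T)) T <- max(unlist(seqs), 2L)
  if (is.null(theta_init)) theta_init <- matrix(0, T, T)
  check_theta(theta_init)
  for (s in seqs) {
    if (anyDuplicated(s)) stop("a sequence contains a repeated task")
    if (length(s) && max(s) > T) stop("sequence task IDs exceed T")
  }
  set.seed(config$seed)
  res <- cpp_fit_mcmc(theta_init,
                      lapply(seqs, function(s) as.integer(s) - 1L),
                      config$n_steps, config$burn_in, config$thin,
                      config$proposal_scale, config$prior_lower,
                      config$prior_upper, config$adapt)
  if (res$accepted == 0 && any(lengths(seqs) > 0))
    stop("MCMC accepted no proposals; try a smaller proposal_scale")
  m <- res$n_draws
  draws <- res$draws
  structure(list(draws = draws[, , seq_len(m), drop = FALSE],
                 loglik = res$loglik[seq_len(m)],
                 trace = res$trace,
                 acceptance_rate = res$accepted / config$n_steps,
                 final_scale = res$final_scale,
                 config = config, T = T),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("<posterior_samples> %d draws of a %dx%d matrix; acceptance %.1f%%\n",
              dim(x$draws)[3], x$T, x$T, 100 * x$acceptance_rate))
  cat(sprintf("  kept log-likelihood: mean %.2f, range [%.2f, %.2f]\n",
              mean(x$loglik), min(x$loglik), max(x$loglik)))
  invisible(x)
}

#' Project a parameter matrix onto its canonical gauge
#'
#' The likelihood of the hypercubic model is exactly invariant under two
#' families of shifts: adding a constant to every diagonal entry, and adding
#' a constant to all off-diagonal entries of any single row (once task `i`
#' is acquired, a uniform influence on every remaining candidate cancels in
#' the softmax). Individual matrix entries are therefore not identifiable;
#' only within-row contrasts are. This function picks the canonical
#' representative: the diagonal is centred to mean zero and each row's
#' off-diagonal influences are centred to mean zero. Apply it before
#' interpreting or comparing fitted entries.
#'
#' @param theta parameter matrix.
#' @return The gauge-fixed matrix, defining the same model.
#' @export
canonical_gauge <- function(theta) {
  check_theta(theta)
  T <- nrow(theta)
  d <- diag(theta)
  diag(theta) <- d - mean(d)
  for (i in seq_len(T)) {
    off <- setdiff(seq_len(T), i)
    theta[i, off] <- theta[i, off] - mean(theta[i, off])
  }
  theta
}

#' Posterior mean parameter matrix
#' @param x a `posterior_samples` object.
#' @param gauge if `TRUE`, project each draw onto the canonical gauge first
#'   (see [canonical_gauge()]); recommended when entries are interpreted.
#' @return T x T numeric matrix of entry-wise posterior means.
#' @export
posterior_mean <- function(x, gauge = FALSE) {
  stopifnot(inherits(x, "posterior_samples"))
  draws <- x$draws
  if (gauge)
    for (m in seq_len(dim(draws)[3]))
      draws[, , m] <- canonical_gauge(draws[, , m])
  apply(draws, c(1, 2), mean)
}

#' Posterior credible interval for one parameter entry
#' @param x a `posterior_samples` object.
#' @param i,j matrix entry indices.
#' @param level credible level (default 0.90).
#' @param gauge if `TRUE`, compute on canonical-gauge draws (the
#'   identifiable contrast; see [canonical_gauge()]).
#' @return Numeric vector of lower and upper quantiles.
#' @export
posterior_ci <- function(x, i, j, level = 0.90, gauge = FALSE) {
  stopifnot(inherits(x, "posterior_samples"))
  v <- if (gauge) {
    vapply(seq_len(dim(x$draws)[3]),
           function(m) canonical_gauge(x$draws[, , m])[i, j], numeric(1))
  } else x$draws[i, j, ]
  a <- (1 - level) / 2
  quantile(v, c(a, 1 - a), names = FALSE)
}
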