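# Naive-Bayes posterior-odds classification of learners from sequence
# prefixes. The evidence for group g is the posterior-predictive likelihood
# of the prefix: the average over posterior draws of the exact sequence
# likelihood (computed with log-sum-exp). The odds ratio
#   P(g1 | s) / P(g2 | s) = P(s | post_g1) P(g1) / (P(s | post_g2) P(g2))
# then gives the membership probability.

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# per-draw cumulative log-likelihood matrix (M draws x n prefix steps)
cum_loglik_matrix <- function(record, posterior) {
  s <- if (inherits(record, "learner_record")) record$sequence else as.integer(record)
  M <- dim(posterior$draws)[3]
  if (!length(s)) return(matrix(0, M, 0))
  t(vapply(seq_len(M), function(m) {
    cumsum(cpp_step_logliks(posterior$draws[, , m], s - 1L))
  }, numeric(length(s))))
}

marginal_from_draws <- function(ll_draws, average) {
  if (average == "likelihood") logsumexp(ll_draws) - log(length(ll_draws))
  else mean(ll_draws)
}

#' Posterior-predictive log-likelihood of a prefix under a fitted group model
#'
#' The log of the average over posterior draws of the exact sequence
#' likelihood (log-sum-exp; Monte-Carlo posterior predictive). With
#' `average = "loglik"` the log-likelihoods themselves are averaged instead.
#'
#' @param prefix a [learner_record] or integer task-ID vector.
#' @param posterior a `posterior_samples` object (see [fit_mcmc()]).
#' @param average `"likelihood"` (default) or `"loglik"`.
#' @return A single number.
#' @export
group_marginal_loglik <- function(prefix, posterior,
                                  average = c("likelihood", "loglik")) {
  stopifnot(inherits(posterior, "posterior_samples"))
  average <- match.arg(average)
  s <- if (inherits(prefix, "learner_record")) prefix$sequence else as.integer(prefix)
  if (!length(s)) return(0)
  ll <- vapply(seq_len(dim(posterior$draws)[3]), function(m) {
    sum(cpp_step_logliks(posterior$draws[, , m], s - 1L))
  }, numeric(1))
  marginal_from_draws(ll, average)
}

#' Membership probability of a learner prefix
#'
#' Converts the posterior-odds ratio between two fitted group models into
#' `P(g1 | prefix)`. With identical models and equal priors the result is
#' exactly 0.5; `P(g1) + P(g2) = 1` always holds.
#'
#' @inheritParams group_marginal_loglik
#' @param post_g1,post_g2 `posterior_samples` for the two groups.
#' @param prior_g1 prior probability of group 1, in (0, 1); default 1/2.
#' @return `P(g1 | prefix)`, a number in `[0, 1]`.
#' @export
membership_probability <- function(prefix, post_g1, post_g2, prior_g1 = 0.5,
                                   average = c("likelihood", "loglik")) {
  average <- match.arg(average)
  if (prior_g1 <= 0 || prior_g1 >= 1) stop("prior_g1 must lie in (0, 1)")
  ll1 <- group_marginal_loglik(prefix, post_g1, average)
  ll2 <- group_marginal_loglik(prefix, post_g2, average)
  log_odds <- (ll1 - ll2) + log(prior_g1) - log(1 - prior_g1)
  1 / (1 + exp(-log_odds))
}

#' Membership trajectories over all prefix lengths
#'
#' Evaluates `P(g1 | first n tasks)` for every learner at every prefix length
#' `n = 0..length(sequence)` (at `n = 0` the probability equals the prior),
#' and summarises per group the mean curve and the proportion of learners
#' above 0.5 at each n.
#'
#' @param records a [cohort] or list of [learner_record]s.
#' @param post_g1,post_g2 `posterior_samples` for the two groups.
#' @param prior_g1 prior probability of group 1.
#' @param groups optional [group_labelling] supplying true labels.
#' @param average see [group_marginal_loglik()].
#' @return An object of class `membership_trajectory`: list with
#'   `trajectories` (data.frame learner_id, true_label, n, p_g1) and
#'   `summary` (data.frame label, n, mean_p, prop_above_half, n_learners;
#'   learners contribute while `n` does not exceed their sequence length).
#' @export
classification_trajectories <- function(records, post_g1, post_g2,
                                        prior_g1 = 0.5, groups = NULL,
                                        average = c("likelihood", "loglik")) {
  average <- match.arg(average)
  if (prior_g1 <= 0 || prior_g1 >= 1) stop("prior_g1 must lie in (0, 1)")
  recs <- if (inherits(records, "cohort")) records$learners else records
  if (!length(recs)) stop("no records supplied")
  prior_lo <- log(prior_g1) - log(1 - prior_g1)

  traj <- do.call(rbind, lapply(recs, function(rec) {
    id <- if (inherits(rec, "learner_record")) rec$learner_id else "learner"
    lab <- if (!is.null(groups) && id %in% names(groups$group_of))
      groups$group_of[[id]] else NA_character_
    cl1 <- cum_loglik_matrix(rec, post_g1)
    cl2 <- cum_loglik_matrix(rec, post_g2)
    n_max <- ncol(cl1)
    p <- numeric(n_max + 1)
    p[1] <- prior_g1
    if (n_max > 0) {
      for (n in seq_len(n_max)) {
        lo <- marginal_from_draws(cl1[, n], average) -
          marginal_from_draws(cl2[, n], average) + prior_lo
        p[n + 1] <- 1 / (1 + exp(-lo))
      }
    }
    data.frame(learner_id = id, true_label = lab, n = 0:n_max, p_g1 = p)
  }))
  rownames(traj) <- NULL

  labs <- unique(traj$true_label)
  labs <- labs[!is.na(labs)]
  summary <- do.call(rbind, lapply(labs, function(lab) {
    sub <- traj[!is.na(traj$true_label) & traj$true_label == lab, ]
    do.call(rbind, lapply(sort(unique(sub$n)), function(n) {
      p <- sub$p_g1[sub$n == n]
      data.frame(label = lab, n = n, mean_p = mean(p),
                 prop_above_half = mean(p > 0.5), n_learners = length(p))
    }))
  }))
  structure(list(trajectories = traj, summary = summary,
                 prior_g1 = prior_g1, average = average),
            class = "membership_trajectory")
}

#' @export
print.membership_trajectory <- function(x, ...) {
  cat(sprintf("<membership_trajectory> %d learners, prior P(g1) = %.2f\n",
              length(unique(x$trajectories$learner_id)), x$prior_g1))
  if (!is.null(x$summary)) {
    last <- do.call(rbind, lapply(split(x$summary, x$summary$label), function(d)
      d[which.max(d$n), ]))
    cat("  final mean P(g1) per group:\n")
    print(last[, c("label", "n", "mean_p", "prop_above_half")], row.names = FALSE)
  }
  invisible(x)
}

#' In-sample and held-out classification experiments
#'
#' Two evaluation protocols for the prefix classifier. Protocol 1
#' (`insample`): fit each group model on all its members and evaluate the
#' same members — tests whether the model can learn parameterisations that
#' separate the groups. Protocol 2 (`holdout`): split each group into a
#' seeded, stratified train/test partition, fit on the training members only
#' and evaluate the held-out members — tests true predictive utility.
#'
#' @param x a [cohort].
#' @param groups a [group_labelling] with the two labels in `labels`.
#' @param config a [model_config] used for both group fits (group-specific
#'   seeds are derived from it).
#' @param train_fraction fraction of each group used for training in the
#'   held-out protocol.
#' @param seed integer seed for the train/test split.
#' @param labels the two group labels (first is "g1" in the odds ratio).
#' @param prior_g1 prior probability of the first label.
#' @param protocols which protocols to run.
#' @return An object of class `split_evaluation`: list with elements
#'   `insample` and/or `holdout` (each a `membership_trajectory`), `split`
#'   (train/test IDs per group) and `fits` (the `posterior_samples` used).
#' @export
evaluate_split <- function(x, groups, config, train_fraction = 0.7, seed = 1,
                           labels = c("g1", "g2"), prior_g1 = 0.5,
                           protocols = c("insample", "holdout")) {
  stopifnot(inherits(x, "cohort"), inherits(groups, "group_labelling"),
            inherits(config, "model_config"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  protocols <- match.arg(protocols, several.ok = TRUE)
  m1 <- intersect(group_members(groups, labels[1]), names(x$learners))
  m2 <- intersect(group_members(groups, labels[2]), names(x$learners))
  if (length(m1) < 2 || length(m2) < 2)
    stop("both groups need at least 2 members present in the cohort")

  cfg_for <- function(offset) {
    cfg <- config
    cfg$seed <- config$seed + offset
    cfg
  }
  out <- list(fits = list())

  if ("insample" %in% protocols) {
    f1 <- fit_mcmc(x$learners[m1], cfg_for(1L), T = x$catalog$T)
    f2 <- fit_mcmc(x$learners[m2], cfg_for(2L), T = x$catalog$T)
    out$insample <- classification_trajectories(
      x$learners[c(m1, m2)], f1, f2, prior_g1 = prior_g1, groups = groups)
    out$fits$insample <- list(g1 = f1, g2 = f2)
  }

  if ("holdout" %in% protocols) {
    set.seed(seed)
    take <- function(members) {
      k <- floor(length(members) * train_fraction)
      if (k < 1 || k >= length(members))
        stop("group too small to split at train_fraction = ", train_fraction)
      train <- sort(sample(members, k))
      list(train = train, test = setdiff(members, train))
    }
    s1 <- take(m1)
    s2 <- take(m2)
    f1 <- fit_mcmc(x$learners[s1$train], cfg_for(3L), T = x$catalog$T)
    f2 <- fit_mcmc(x$learners[s2$train], cfg_for(4L), T = x$catalog$T)
    out$holdout <- classification_trajectories(
      x$learners[c(s1$test, s2$test)], f1, f2, prior_g1 = prior_g1,
      groups = groups)
    out$split <- list(g1 = s1, g2 = s2)
    out$fits$holdout <- list(g1 = f1, g2 = f2)
  }
  structure(out, class = "split_evaluation")
}

#' @export
print.split_evaluation <- function(x, ...) {
  cat("<split_evaluation>\n")
  if (!is.null(x$insample)) { cat("-- protocol 1 (in-sample):\n"); print(x$insample) }
  if (!is.null(x$holdout)) { cat("-- protocol 2 (held-out):\n"); print(x$holdout) }
  invisible(x)
}
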