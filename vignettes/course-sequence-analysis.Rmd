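---
title: "Modelling task-completion sequences: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling task-completion sequences: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coursetrace)
```

## The data model

An online course presents `T` tasks in a designed *nominal order* `1..T`,
grouped into `S` weekly sessions. Each learner produces an ordered list of
the distinct tasks they completed — possibly skipping tasks and possibly
stopping early. `coursetrace` represents the course design as a
`task_catalog` (task IDs, session membership, one of six task types), one
learner as a `learner_record` (sequence, grade, confidence-survey
responses), and the ensemble as a `cohort`.

Order is the primitive here, not time. Ingestion (`load_cohort()`)
therefore refuses tied timestamps when no explicit order index is supplied:
silently breaking a tie would corrupt the very quantity every downstream
statistic is built on. Repeated completions of one task keep the earliest
event, because completion of a task is its first submission.

## Descriptive ensemble statistics

Three matrices summarise a cohort:

* The **position matrix** `P`, with `p_ij` the probability that task `i`
  was completed `j`th. A cohort that follows the nominal order exactly
  gives the identity matrix, so off-diagonal mass reads directly as
  departure from the design.
* The **transition summary**: counts `m_ij` of task (or session) `j`
  immediately following `i`, the joint probabilities
  `p_(i->j) = m_ij / sum(m)` and the conditionals
  `pi_ij = p_(i->j) / sum_j p_(i->j)`. `pi` is *not* a stochastic-process
  matrix — tasks are acquired irreversibly — it is a summary of observed
  successions. Session-level summaries substitute session IDs for task IDs
  before counting, so within-session transitions appear as diagonal
  self-loops; a virtual start state (default on at session resolution)
  makes the first completion itself a transition.
* The **deviation matrix**: for learner `k` at sequence position `j`, the
  signed quantity `d = j/n_k - r(t_j)/T` (fractional position minus
  fractional nominal rank). An exactly nominal full run is an all-zero
  row; `d > 0` means later than nominal, `d < 0` earlier; positions past
  the learner's last completion are missing. This normalisation was chosen
  over alternatives (e.g. raw rank differences) because it bounds entries
  in (−1, 1) and makes the all-nominal row exactly zero regardless of
  sequence length.

Group contrasts subtract two conditional matrices (`delta_transition()`)
and compare rows and columns by the **Jensen–Shannon distance**
(`js_profile()`): the square root of the base-2 Jensen–Shannon divergence,
a metric on `[0, 1]` that is 0 for identical distributions and 1 for
disjoint support. Zero probabilities use the convention `0 log 0 = 0`; no
smoothing is applied, so the bounds are attained exactly. For incoming
(column) comparisons the columns are renormalised to sum to one; columns of
the conditional matrix are the default, columns of the joint matrix an
option, since either reading of "columns of the transition matrix" is
defensible. Rows with no outgoing transitions in either group are skipped
and reported, never silently treated as uniform.

## The reduced hypercubic model

The most general Markov model of irreversible task acquisition lives on the
hypercube of acquired-task subsets: `2^T` states and `T 2^(T-1)` transition
parameters, hopeless at course scale. The reduction implemented here — the
HyperTraPS family's parameterisation — keeps a `T x T` matrix `theta`:
`theta[j, j]` is the basal log-propensity of acquiring task `j`, and
`theta[i, j]` the additive log-influence of already-acquired `i` on `j`.
Given acquired set `A`, the next task follows the softmax over unacquired
`j` of `theta[j,j] + sum_{i in A} theta[i,j]`. For `T = 123` that is
15,129 parameters; the hypercube is never materialised.

Because completion order is fully observed in this setting, the likelihood
of a sequence is the exact product of its step probabilities — no latent
path sampling is required, which is the defining simplification these data
permit. Partial sequences contribute only their observed steps: the model
deliberately does not describe *when* a learner stops, which keeps
likelihoods comparable across prefix lengths for the classifier.

Whether acquired tasks contribute additively in log space (multiplicative
propensities) or additively in probability is not fixed by the phrase
"independent contributions"; we use the log-additive convention of the
HyperTraPS lineage, isolated in one code path (`cpp_step_logliks`).

### Identifiability and the canonical gauge

The likelihood is exactly invariant under two families of shifts:

1. adding a constant to every diagonal entry (only differences of basal
   rates matter), and
2. adding a constant to all off-diagonal entries of any single row `i` —
   once `i` is acquired, a uniform influence on every remaining candidate
   cancels in the softmax.

Individual entries of `theta` are therefore not identified; only
within-row contrasts are. `canonical_gauge()` picks the representative
with mean-zero diagonal and mean-zero off-diagonal rows, and
`posterior_mean(x, gauge = TRUE)` / `posterior_ci(..., gauge = TRUE)`
summarise posteriors in that gauge. Interpreting raw fitted entries
without gauge fixing is a mistake: in simulation studies the raw marginal
of a planted influence can drift to the opposite sign while the
gauge-fixed contrast recovers it cleanly.

### Inference

`fit_mcmc()` runs random-walk Metropolis over all `T^2` entries with
independent uniform priors on `[-10, 10]` per entry (wide enough that a
propensity ratio of `e^20` separates any pair of tasks, i.e. effectively
unconstrained) and a spherical Gaussian proposal. The initial proposal
scale (0.1) is adapted towards ~23% acceptance during burn-in only, so the
post-burn-in chain is a valid fixed-kernel Metropolis sampler. Defaults:
20,000 steps, half burn-in, thinning 50. The seed is mandatory in
`model_config()`; every fit is bit-reproducible. A chain that accepts
nothing raises an error suggesting a smaller proposal scale rather than
returning a silently frozen posterior. The likelihood core and sampler are
compiled (Rcpp) and draw from R's RNG, so `set.seed()` semantics carry
through.

No convergence criterion is imposed automatically; the log-likelihood
trace is returned and should be inspected. For the problem sizes used in
the package's own experiments (`T` up to 40, 20,000 steps) the trace
plateaus well before burn-in ends.

## Posterior-odds classification

With posteriors fitted separately to a high- and a low-performing group,
a learner's prefix is classified by the odds ratio of posterior-predictive
likelihoods times prior odds. "Averaging across posterior samples" is read
as averaging *likelihoods* (a Monte-Carlo posterior predictive, computed
with log-sum-exp); averaging log-likelihoods is available as an option.
Complementarity (`P(g1) + P(g2) = 1`), exact prior-odds linearity and
label-swap antisymmetry hold by construction and are asserted in tests.

`evaluate_split()` implements the two standard protocols: in-sample
(train on all members, evaluate the same members — does the model *learn*
group differences?) and held-out (stratified seeded 70/30 split — does it
*predict* unseen learners?). Stratification is not optional: with groups
of ~20, an unstratified split can empty a training group.

## The synthetic cohort generator

Real records of this kind are private LMS data, so the generator is a
first-class module, not a test fixture. Its default scenario
(`scenario_config(seed = ...)`) encodes the study conditions the package
targets: `N = 81` learners, `T = 123` tasks in `S = 10` sessions with
coursework closing sessions 3, 4 and 9; top/bottom quartile groups of 20
with grade means 79.3 (sd 3.3) and 55.6 (sd 4.6) around a middle group at
68.4; per-group confident-response probabilities 0.76 / 0.65.

Generation is model-plus-post-processing. Sequences are drawn from a
group-specific `behavioural_theta()`: basal propensities decaying with
nominal rank, each task boosting its nominal successor (within-session and
between-session adherence separately, so high performers can track the
session sequence while low performers track within-session order), and a
basal boost on coursework for low-adherence groups. All terms scale with
adherence, so adherence 0 is the uniform model and large adherence pins
the nominal order. Post-processing then injects what the model cannot
express: a rising per-task skip curve (2% to 25% along the course —
skipped tasks shift every later completion, producing the broadening of
position histograms), a branching subgroup (40%) skipping two designated
tasks about two-thirds through (bimodal histograms), coursework pulled
forward in low performers' sequences, and truncation to a group-specific
completed fraction (censoring; the real distribution of sequence lengths
is unreported, so truncation is a configurable normal fraction per group).

Two generator modes matter for testing. *Model-only* cohorts
(`model_only_cohort()`) match the model assumptions exactly and are used
for parameter-recovery and classifier experiments — mixing in the
post-processing there would conflate inference quality with model
misspecification (the skip noise penalises the sharper group's model for
*every* learner and biases held-out membership towards the flatter group;
we verified this, and it is worth knowing when applying the classifier to
real data). *Behavioural* cohorts (`simulate_cohort()`) deliberately
violate the model and exercise the descriptive statistics.

What passing tests on synthetic data do **not** show: that real learners
follow a pairwise-influence acquisition process, that confidence responses
are independent across tasks, or that grades are normal within groups.
The generator reproduces the reported *statistical signatures*, not the
mechanisms behind them.

## Numerical and design choices

* All probability computations run in log space with log-sum-exp;
  next-task distributions sum to 1 within 1e-12 in tests.
* The grade-quantile split ranks by grade with lexicographic learner-ID
  tie-break — one global ranking, top `floor(N f)` versus bottom
  `floor(N f)`, so groups are always disjoint and deterministic, even with
  all grades equal. The split fraction defaults to quartile tails
  (`f = 0.25`); a median split is `f = 0.5`.
* The paired confidence comparison pairs by *task* (each task contributes
  one per-group mean): tasks are the only index shared by both groups. A
  per-student Welch test is available, since students cannot be paired.
* Degenerate inputs are contracts, not crashes: empty sequences have
  likelihood 0 and prior membership probability; single-task cohorts give
  all-zero transition matrices; rows without outgoing transitions are
  missing, never uniform.
* Exhaustive enumeration (`enumerate_order_probabilities()`) refuses
  `T > 8` (`8! = 40,320` orderings) — it is an oracle, not a method.

### Problem sizes in the package's experiments

The package's own simulation studies (tests and examples) use: exhaustive
oracles at `T <= 6`; a chi-square simulation check at `T = 3` with 1e5
draws; parameter recovery at `T = 5` with 200 sequences and 20,000-step
chains; and classification experiments at `T = 40`, 20 + 20 learners,
sequence length 34, 20,000-step chains — two groups differing *only* in
adherence for the separation experiment, and identical generators for the
null-calibration experiment, where held-out mean membership stays within
[0.35, 0.65] (no spurious separation). These sizes were chosen so the
full suite runs in minutes on a laptop while leaving each conclusion
clearly resolved (e.g. recovery CIs exclude zero by a wide margin).

## Known limitations

* The model is first-order in the acquired *set*: no higher-order
  interactions, no dependence on acquisition order, no forgetting or
  re-attempts, and no calendar time — continuous-time extensions would
  need timestamped rates.
* The classifier is two-group; multi-group classification would need a
  prior simplex and per-group fits.
* MCMC is plain Metropolis; at `T` much beyond ~50 the `T^2`-dimensional
  random walk mixes slowly, and a component-wise or gradient-based
  sampler would be the natural upgrade.
* Jensen–Shannon profiles compare distributions without any significance
  test; observed distances on small groups include substantial sampling
  noise.
* The behavioural generator's course start is more diffuse than real
  cohorts, whose first completions concentrate heavily on the first task:
  the gentle basal-rate decay spreads first picks over the opening
  session. Deviation growth, session concentration and the group
  contrasts are unaffected, but per-task position histograms near the
  very start of a generated course are flatter than real ones.

```{r}
# a compact end-to-end run at reduced size
sc <- scenario_config(T = 30, S = 3, N = 24, seed = 9,
                      groups = data.frame(
                        label = c("g1", "g2"), size = c(12, 12),
                        grade_mean = c(80, 55), grade_sd = c(3, 5),
                        adherence_within = c(2.5, 3.5),
                        adherence_between = c(3.5, 1.5),
                        coursework_boost = c(0, 1), coursework_pull = c(0, 3),
                        skip_multiplier = c(0.6, 1.4),
                        completion_mean = c(0.95, 0.75),
                        completion_sd = c(0.04, 0.1),
                        p_confident = c(0.76, 0.65)))
sim <- simulate_cohort(sc)
grp <- split_by_grade_quantile(sim$cohort, 0.25)
pi_g1 <- transition_summary(
  cohort(sim$cohort$catalog, sim$cohort$learners[group_members(grp, "g1")]),
  "session")
pi_g2 <- transition_summary(
  cohort(sim$cohort$catalog, sim$cohort$learners[group_members(grp, "g2")]),
  "session")
js_profile(pi_g1, pi_g2)
```
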