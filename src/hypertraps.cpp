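#include <Rcpp.h>
using namespace Rcpp;

// Core numerics for the reduced hypercubic acquisition model.
// theta is T x T: diagonal = basal log-propensities, off-diagonal theta(i,j) =
// additive log-influence of acquired task i on task j. The next-task
// distribution given acquired set A is softmax over unacquired j of
// theta(j,j) + sum_{i in A} theta(i,j). Sequences are 0-based here; the R
// layer owns the 1-based task-ID convention.

static double logsumexp_unacquired(const std::vector<double>& logw,
                                   const std::vector<char>& acq) {
  double mx = R_NegInf;
  const int T = (int)logw.size();
  for (int j = 0; j < T; ++j)
    if (!acq[j] && logw[j] > mx) mx = logw[j];
  if (mx == R_NegInf) return R_NegInf;
  double s = 0.0;
  for (int j = 0; j < T; ++j)
    if (!acq[j]) s += std::exp(logw[j] - mx);
  return mx + std::log(s);
}

// Per-step log-probabilities of one observed (possibly partial) sequence.
// [[Rcpp::export]]
NumericVector cpp_step_logliks(const NumericMatrix& theta,
                               const IntegerVector& seq0) {
  const int T = theta.nrow();
  const int n = seq0.size();
  NumericVector out(n);
  std::vector<double> logw(T);
  std::vector<char> acq(T, 0);
  for (int j = 0; j < T; ++j) logw[j] = theta(j, j);
  for (int m = 0; m < n; ++m) {
    const int t = seq0[m];
    out[m] = logw[t] - logsumexp_unacquired(logw, acq);
    acq[t] = 1;
    for (int j = 0; j < T; ++j) logw[j] += theta(t, j);
  }
  return out;
}

static double seq_loglik(const NumericMatrix& theta, const IntegerVector& s) {
  NumericVector v = cpp_step_logliks(theta, s);
  double tot = 0.0;
  for (double x : v) tot += x;
  return tot;
}

// [[Rcpp::export]]
double cpp_cohort_loglik(const NumericMatrix& theta, const List& seqs0) {
  double tot = 0.0;
  for (int k = 0; k < seqs0.size(); ++k)
    tot += seq_loglik(theta, as<IntegerVector>(seqs0[k]));
  return tot;
}

// Draw one sequence of length n step-by-step; uses R's RNG (seed with
// set.seed() on the R side).
// [[Rcpp::export]]
IntegerVector cpp_simulate_sequence(const NumericMatrix& theta, int n) {
  const int T = theta.nrow();
  IntegerVector out(n);
  std::vector<double> logw(T), w(T);
  std::vector<char> acq(T, 0);
  for (int j = 0; j < T; ++j) logw[j] = theta(j, j);
  for (int m = 0; m < n; ++m) {
    double mx = R_NegInf;
    for (int j = 0; j < T; ++j)
      if (!acq[j] && logw[j] > mx) mx = logw[j];
    double s = 0.0;
    for (int j = 0; j < T; ++j) {
      w[j] = acq[j] ? 0.0 : std::exp(logw[j] - mx);
      s += w[j];
    }
    double u = unif_rand() * s, c = 0.0;
    int pick = -1;
    for (int j = 0; j < T; ++j) {
      c += w[j];
      if (u <= c && !acq[j]) { pick = j; break; }
    }
    if (pick < 0) { // numerical edge: take last unacquired
      for (int j = T - 1; j >= 0; --j) if (!acq[j]) { pick = j; break; }
    }
    out[m] = pick;
    acq[pick] = 1;
    for (int j = 0; j < T; ++j) logw[j] += theta(pick, j);
  }
  return out;
}

// Random-walk Metropolis over all T^2 entries, uniform prior on
// [lower, upper] per entry, spherical Gaussian proposal. Scale is adapted
// towards an acceptance rate of ~0.234 during burn-in only. Uses R's RNG.
// [[Rcpp::export]]
List cpp_fit_mcmc(const NumericMatrix& theta_init, const List& seqs0,
                  int n_steps, int burn_in, int thin,
                  double prop_sd, double lower, double upper, bool adapt) {
  const int T = theta_init.nrow();
  NumericMatrix cur(clone(theta_init));
  NumericMatrix prop(T, T);
  double cur_ll = cpp_cohort_loglik(cur, seqs0);
  double scale = prop_sd;

  const int n_keep = burn_in < n_steps ? (n_steps - burn_in + thin - 1) / thin : 0;
  NumericVector draws(std::max(n_keep, 1) * T * T);
  NumericVector kept_ll(std::max(n_keep, 1));
  NumericVector trace(n_steps);
  int kept = 0, accepted = 0, window_acc = 0;
  const int window = 100;

  for (int step = 0; step < n_steps; ++step) {
    bool in_support = true;
    for (int i = 0; i < T; ++i) {
      for (int j = 0; j < T; ++j) {
        const double v = cur(i, j) + norm_rand() * scale;
        prop(i, j) = v;
        if (v < lower || v > upper) in_support = false;
      }
    }
    if (in_support) {
      const double prop_ll = cpp_cohort_loglik(prop, seqs0);
      if (std::log(unif_rand()) < prop_ll - cur_ll) {
        std::copy(prop.begin(), prop.end(), cur.begin());
        cur_ll = prop_ll;
        ++accepted;
        ++window_acc;
      }
    }
    trace[step] = cur_ll;
    if (adapt && step < burn_in && (step + 1) % window == 0) {
      const double rate = (double)window_acc / window;
      scale *= std::exp(0.6 * (rate - 0.234));
      scale = std::min(std::max(scale, 1e-5), 10.0);
      window_acc = 0;
    }
    if (step >= burn_in && (step - burn_in) % thin == 0 && kept < n_keep) {
      std::copy(cur.begin(), cur.end(), draws.begin() + (R_xlen_t)kept * T * T);
      kept_ll[kept] = cur_ll;
      ++kept;
    }
  }

  draws.attr("dim") = IntegerVector::create(T, T, std::max(n_keep, 1));
  return List::create(_["draws"] = draws,
                      _["n_draws"] = kept,
                      _["loglik"] = kept_ll,
                      _["trace"] = trace,
                      _["accepted"] = accepted,
                      _["final_scale"] = scale);
}
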