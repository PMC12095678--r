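#include <Rcpp.h>
using namespace Rcpp;

// Sequential trial-by-trial log-likelihoods for the four candidate
// reinforcement-learning models. Choices are coded 1 = good stimulus,
// 2 = bad stimulus, 0 = no response; pair indices are 1-based; outcomes
// are in {-1, 0, +1}. Model codes: 1..4 = M1..M4.
//
// M1-M3: delta rule on the chosen stimulus, V += a_eff * (rho*r - V),
// softmax with temperature 1 and stickiness bonus tau for repeating the
// previous choice within the pair (tau = 0 for M1).
// M4: experience-weighted attraction, n = rho_ew*n_prev + 1,
// V = (phi*n_prev*V + r)/n, softmax with inverse temperature beta.

static double loglik_one(int model, const int* pair, int n_trials,
                         int n_pairs, const int* choice,
                         const double* outcome, const int* responded,
                         const int* is_reward, const double* par) {
  std::vector<double> Vg(n_pairs, 0.0), Vb(n_pairs, 0.0);
  std::vector<double> Ng(n_pairs, 1.0), Nb(n_pairs, 1.0);
  std::vector<int> prev(n_pairs, 0);

  double alpha_rew = 0, alpha_pun = 0, rho = 1, tau = 0;
  double phi = 0, rho_ew = 0, beta = 1;
  switch (model) {
  case 1: alpha_rew = par[0]; alpha_pun = par[1]; rho = par[2]; tau = 0; break;
  case 2: alpha_rew = par[0]; alpha_pun = par[1]; rho = par[2]; tau = par[3]; break;
  case 3: alpha_rew = par[0]; alpha_pun = par[0]; rho = par[1]; tau = par[2]; break;
  case 4: phi = par[0]; rho_ew = par[1]; beta = par[2]; break;
  default: Rcpp::stop("unknown model code");
  }

  double ll = 0.0;
  for (int t = 0; t < n_trials; ++t) {
    if (!responded[t]) continue;
    int k = pair[t] - 1;
    double zg, zb;
    if (model == 4) {
      zg = beta * Vg[k];
      zb = beta * Vb[k];
    } else {
      zg = Vg[k] + (prev[k] == 1 ? tau : 0.0);
      zb = Vb[k] + (prev[k] == 2 ? tau : 0.0);
    }
    // log P(chosen)
    double d = (choice[t] == 1) ? (zb - zg) : (zg - zb);
    ll += -log1p(exp(d));

    double r = outcome[t];
    double* V = (choice[t] == 1) ? &Vg[k] : &Vb[k];
    if (model == 4) {
      double* N = (choice[t] == 1) ? &Ng[k] : &Nb[k];
      double n_prev = *N;
      double n_new = rho_ew * n_prev + 1.0;
      *V = (phi * n_prev * (*V) + r) / n_new;
      *N = n_new;
    } else {
      double a;
      if (r > 0) a = alpha_rew;
      else if (r < 0) a = alpha_pun;
      else a = is_reward[t] ? alpha_pun : alpha_rew;
      *V += a * (rho * r - *V);
    }
    prev[k] = choice[t];
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_subject_loglik(int model, IntegerVector pair, int n_pairs,
                          IntegerVector choice, NumericVector outcome,
                          IntegerVector responded, IntegerVector is_reward,
                          NumericVector params) {
  return loglik_one(model, pair.begin(), pair.size(), n_pairs,
                    choice.begin(), outcome.begin(), responded.begin(),
                    is_reward.begin(), params.begin());
}

// Per-subject log-likelihoods for a whole cohort. Trials are stored
// concatenated; `start` (1-based) and `len` delimit each subject's
// slice, `n_pairs` gives each subject's pair count, and `params` holds
// one row of natural-scale parameters per subject.
// [[Rcpp::export]]
NumericVector cpp_cohort_loglik(int model, IntegerVector start,
                                IntegerVector len, IntegerVector n_pairs,
                                IntegerVector pair, IntegerVector choice,
                                NumericVector outcome,
                                IntegerVector responded,
                                IntegerVector is_reward,
                                NumericMatrix params,
                                IntegerVector subset) {
  int P = params.ncol();
  std::vector<double> par(P);
  NumericVector out(subset.size());
  for (int s = 0; s < subset.size(); ++s) {
    int i = subset[s] - 1;
    for (int j = 0; j < P; ++j) par[j] = params(i, j);
    int off = start[i] - 1;
    out[s] = loglik_one(model, &pair[off], len[i], n_pairs[i], &choice[off],
                        &outcome[off], &responded[off], &is_reward[off],
                        par.data());
  }
  return out;
}
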