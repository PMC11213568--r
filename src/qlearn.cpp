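#include <Rcpp.h>
using namespace Rcpp;

// Negative log-likelihood of choices under the Q-learning model with
// softmax choice rule and perseveration bonus. Trials must be in temporal
// order; pair_key is a 0-based index unique per (subject, session, pair),
// so Q-values reset to 0 for every new pair. chosen is 1 (first cue of the
// pair, the favourable one) or 2. The choice probability is computed on the
// logit scale, P(a) = 1 / (1 + exp(-((za - zb) / beta))), which is stable
// for very small temperatures, and floored at p_floor before the log.
// [[Rcpp::export]]
double qlearn_nll_cpp(IntegerVector pair_key, IntegerVector chosen,
                      NumericVector outcome, double alpha, double beta,
                      double theta, double p_floor) {
  int n = pair_key.size();
  int n_pairs = 0;
  for (int i = 0; i < n; ++i)
    if (pair_key[i] + 1 > n_pairs) n_pairs = pair_key[i] + 1;
  std::vector<double> q1(n_pairs, 0.0), q2(n_pairs, 0.0);
  std::vector<int> prev(n_pairs, 0);  // 0 = none yet, else 1 or 2
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    int k = pair_key[i];
    double za = q1[k] + (prev[k] == 1 ? theta : 0.0);
    double zb = q2[k] + (prev[k] == 2 ? theta : 0.0);
    double d = (za - zb) / beta;
    double pa = 1.0 / (1.0 + std::exp(-d));
    double p = (chosen[i] == 1) ? pa : 1.0 - pa;
    if (p < p_floor) p = p_floor;
    nll -= std::log(p);
    if (chosen[i] == 1) q1[k] += alpha * (outcome[i] - q1[k]);
    else                q2[k] += alpha * (outcome[i] - q2[k]);
    prev[k] = chosen[i];
  }
  return nll;
}
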