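#include <Rcpp.h>
using namespace Rcpp;

// Sequential negative log-likelihood of a two-armed delta-rule/softmax agent.
// choice: 0 = arm A, 1 = arm B; reward in {0, 1}. Both values start at 0, so
// the first-trial choice probability is exactly 0.5 for each arm. Only the
// chosen arm's value is updated; the learning rate is eta_win after a win and
// eta_lose otherwise (pass eta_win == eta_lose for the single-rate model).
// The per-trial log-probability is computed by log-sum-exp so large beta
// cannot overflow.
// [[Rcpp::export]]
double rw_nll_cpp(IntegerVector choice, NumericVector reward,
                  double eta_win, double eta_lose, double beta) {
  int n = choice.size();
  double vA = 0.0, vB = 0.0, nll = 0.0;
  for (int i = 0; i < n; ++i) {
    double a = beta * vA, b = beta * vB;
    double m = a > b ? a : b;
    double lse = m + std::log(std::exp(a - m) + std::exp(b - m));
    double chosen = (choice[i] == 0) ? a : b;
    nll -= chosen - lse;
    double eta = (reward[i] > 0.0) ? eta_win : eta_lose;
    if (choice[i] == 0) {
      vA += eta * (reward[i] - vA);
    } else {
      vB += eta * (reward[i] - vB);
    }
  }
  return nll;
}
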