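#include <Rcpp.h>
using namespace Rcpp;

// Per-run log-likelihood of the four-parameter reinforcement-learning model.
//
// The agent tracks a single belief p about option A's win probability
// (B's is its complement, full feedback is given every trial). Per trial:
//   W(A)  = lam * (2p - 1) + (1 - lam) * (f_A - f_B) * scale,  W(B) = -W(A)
//   P(A)  = 1 / (1 + exp(-2 * beta * W(A)))            (softmax over A, B)
//   p    <- p + alpha * (r_A - p), alpha keyed to whether the CHOSEN option
//           won (alpha_win) or lost (alpha_loss)
// Beliefs are reconstructed from the full outcome sequence r_A, exactly as
// in forward simulation. Per-trial choice probabilities are floored at eps
// before taking logs.
//
// choice_a: 1 if option A was chosen, 0 otherwise.
// r_a:      1 if option A was the effective option, 0 otherwise.
// scale:    1/100 when magnitudes are rescaled to [0, 1], 1 otherwise.

// [[Rcpp::export]]
double cpp_run_loglik(const IntegerVector& choice_a,
                      const IntegerVector& r_a,
                      const NumericVector& f_a,
                      const NumericVector& f_b,
                      const double alpha_win,
                      const double alpha_loss,
                      const double beta,
                      const double lam,
                      const double scale,
                      const double eps) {
  const int n = choice_a.size();
  double p = 0.5;   // symmetric prior belief at run start
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    const double w = lam * (2.0 * p - 1.0)
                   + (1.0 - lam) * (f_a[t] - f_b[t]) * scale;
    // logit of the CHOSEN option's probability; evaluating the logistic at
    // the signed logit avoids the cancellation of 1 - P(A) when P(A) ~ 1
    const double x = (choice_a[t] == 1 ? 2.0 : -2.0) * beta * w;
    double pc = (x >= 0.0) ? 1.0 / (1.0 + std::exp(-x))
                           : std::exp(x) / (1.0 + std::exp(x));
    if (pc < eps) pc = eps;
    ll += std::log(pc);
    const bool chosen_won = (choice_a[t] == 1) == (r_a[t] == 1);
    const double alpha = chosen_won ? alpha_win : alpha_loss;
    p += alpha * (static_cast<double>(r_a[t]) - p);
  }
  return ll;
}
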