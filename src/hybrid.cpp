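#include <Rcpp.h>
using namespace Rcpp;

// Sequential log-likelihood of the hybrid model-free / model-based learner
// on a two-stage trial sequence.
//
// Per trial t (after the likelihood of the observed choice is accumulated
// from the values carried into the trial):
//   MF:  V(B_obs) += alpha1 * (r - V(B_obs))
//        V(A_cho) += alpha1 * lambda * deltaV(B_obs)
//   MB:  V(B_obs) += alpha2 * (r - V(B_obs))
//        V(A_i)    = P(A_i->B1) V(B1) + P(A_i->B2) V(B2)   (both options)
//   V_net = w * V_MB + (1 - w) * V_MF  (A-stage values)
//   p(choose A1) = softmax(beta * V_net + persev * rep)
//
// choices, intermediates are 1/2 coded; rewards 0/1.
//
// The first-stage model-free update propagates the eligibility-discounted
// prediction error, alpha1 * lambda * (r - V(B_obs)).  When literal_mf is
// set, the nested printed form alpha1 * lambda * (alpha1 * (r - V(B_obs)))
// is used instead (the value *change* in place of the prediction error),
// under which first-stage model-free learning is second order in alpha1.
// [[Rcpp::export(name = ".hybrid_loglik_cpp")]]
double hybrid_loglik_cpp(double alpha1, double alpha2, double lambda, double w,
                         IntegerVector choice, IntegerVector intermediate,
                         NumericVector reward,
                         double common_prob, double beta, double persev,
                         double eps, bool literal_mf) {
  int n = choice.size();
  double vmf_a[2] = {0.0, 0.0}, vmf_b[2] = {0.0, 0.0};
  double vmb_a[2] = {0.0, 0.0}, vmb_b[2] = {0.0, 0.0};
  // transition matrix P[a][b], fixed by the task
  double P[2][2] = {{common_prob, 1.0 - common_prob},
                    {1.0 - common_prob, common_prob}};
  double ll = 0.0;
  int prev = -1;
  for (int t = 0; t < n; ++t) {
    int a = choice[t] - 1, b = intermediate[t] - 1;
    if (a < 0 || a > 1 || b < 0 || b > 1) stop("choices/intermediates must be 1 or 2");
    // likelihood of this trial's choice given values carried in
    double vnet0 = w * vmb_a[0] + (1.0 - w) * vmf_a[0];
    double vnet1 = w * vmb_a[1] + (1.0 - w) * vmf_a[1];
    double u0 = beta * vnet0 + (prev == 0 ? persev : 0.0);
    double u1 = beta * vnet1 + (prev == 1 ? persev : 0.0);
    double m = u0 > u1 ? u0 : u1;
    double z = std::exp(u0 - m) + std::exp(u1 - m);
    double p = std::exp((a == 0 ? u0 : u1) - m) / z;
    if (p < eps) p = eps;
    ll += std::log(p);
    // updates from this trial's observations
    double r = reward[t];
    double dvb = r - vmf_b[b];
    vmf_b[b] += alpha1 * dvb;
    vmf_a[a] += alpha1 * lambda * (literal_mf ? alpha1 * dvb : dvb);
    vmb_b[b] += alpha2 * (r - vmb_b[b]);
    vmb_a[0] = P[0][0] * vmb_b[0] + P[0][1] * vmb_b[1];
    vmb_a[1] = P[1][0] * vmb_b[0] + P[1][1] * vmb_b[1];
    prev = a;
  }
  return ll;
}
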