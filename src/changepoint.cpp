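#include <Rcpp.h>
using namespace Rcpp;

// NB2 log pmf: mean mu, dispersion phi (variance mu + mu^2/phi).
static inline double nb_lpmf(double y, double mu, double phi) {
  return R::dnbinom_mu(y, phi, mu, 1);
}

static inline double logsumexp(const std::vector<double>& v) {
  double m = v[0];
  for (size_t i = 1; i < v.size(); ++i) if (v[i] > m) m = v[i];
  if (!R_FINITE(m)) return m;
  double s = 0.0;
  for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// Per-candidate log joint (up to the shared tau prior constant):
// candidate t (1-based index of the first "late" month, t = 2..n) has
// log L(t) = sum_{i < t} nb_lpmf(y_i; early) + sum_{i >= t} nb_lpmf(y_i; late)
static std::vector<double> tau_logliks(const IntegerVector& y,
                                       double mu_e, double mu_l,
                                       double phi_e, double phi_l) {
  int n = y.size();
  std::vector<double> le(n), ll(n);
  for (int i = 0; i < n; ++i) {
    le[i] = nb_lpmf(y[i], mu_e, phi_e);
    ll[i] = nb_lpmf(y[i], mu_l, phi_l);
  }
  std::vector<double> ce(n), cl(n);
  ce[0] = le[0]; cl[0] = ll[0];
  for (int i = 1; i < n; ++i) { ce[i] = ce[i-1] + le[i]; cl[i] = cl[i-1] + ll[i]; }
  double total_l = cl[n-1];
  std::vector<double> lt(n - 1);
  for (int t = 2; t <= n; ++t)  // early block 1..t-1 => ce[t-2]
    lt[t-2] = ce[t-2] + (total_l - cl[t-2]);
  return lt;
}

// Log posterior density (up to a constant) of theta = log(mu_e, mu_l,
// phi_e, phi_l) with tau marginalized out by log-sum-exp over all interior
// candidates. Priors: exponential with means mu_mean (both mu's) and
// phi_mean (both phi's); includes the log-Jacobian of the log transform.
// [[Rcpp::export]]
double cp_logpost_cpp(IntegerVector y, NumericVector theta,
                      double mu_mean, double phi_mean) {
  double mu_e = std::exp(theta[0]), mu_l = std::exp(theta[1]);
  double phi_e = std::exp(theta[2]), phi_l = std::exp(theta[3]);
  if (!R_FINITE(mu_e) || !R_FINITE(mu_l) || !R_FINITE(phi_e) || !R_FINITE(phi_l) ||
      mu_e <= 0 || mu_l <= 0 || phi_e <= 0 || phi_l <= 0)
    return R_NegInf;
  std::vector<double> lt = tau_logliks(y, mu_e, mu_l, phi_e, phi_l);
  double marg = logsumexp(lt) - std::log((double)lt.size());
  double lprior =
    R::dexp(mu_e, mu_mean, 1) + R::dexp(mu_l, mu_mean, 1) +
    R::dexp(phi_e, phi_mean, 1) + R::dexp(phi_l, phi_mean, 1);
  // Jacobian of x = exp(theta): log|dx/dtheta| = theta
  double jac = theta[0] + theta[1] + theta[2] + theta[3];
  return marg + lprior + jac;
}

// Conditional changepoint distribution P(tau | params, y): softmax of the
// per-candidate log joints (uniform tau prior cancels).
// [[Rcpp::export]]
NumericVector cp_tau_probs_cpp(IntegerVector y, NumericVector theta) {
  double mu_e = std::exp(theta[0]), mu_l = std::exp(theta[1]);
  double phi_e = std::exp(theta[2]), phi_l = std::exp(theta[3]);
  std::vector<double> lt = tau_logliks(y, mu_e, mu_l, phi_e, phi_l);
  double lse = logsumexp(lt);
  NumericVector out(lt.size());
  for (size_t i = 0; i < lt.size(); ++i) out[i] = std::exp(lt[i] - lse);
  return out;
}

// Prefix/suffix log-likelihood table used by the exact quadrature oracle.
// For G (mu, phi) grid points returns:
//   prefix(g, t): sum_{i <= t} nb_lpmf(y_i; mu_g, phi_g), t = 1..n-1
//   suffix(g, t): sum_{i >= t} nb_lpmf(y_i; mu_g, phi_g), t = 2..n
// [[Rcpp::export]]
List cp_grid_blocks_cpp(IntegerVector y, NumericVector mu, NumericVector phi) {
  int n = y.size(), G = mu.size();
  NumericMatrix prefix(G, n - 1), suffix(G, n - 1);
  std::vector<double> l(n);
  for (int g = 0; g < G; ++g) {
    for (int i = 0; i < n; ++i) l[i] = nb_lpmf(y[i], mu[g], phi[g]);
    double acc = 0.0;
    for (int t = 0; t < n - 1; ++t) { acc += l[t]; prefix(g, t) = acc; }
    acc = 0.0;
    for (int t = n - 1; t >= 1; --t) { acc += l[t]; suffix(g, t - 1) = acc; }
  }
  return List::create(_["prefix"] = prefix, _["suffix"] = suffix);
}
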