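#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward recursion (Rabiner-style per-step normalization) on a
// precomputed log emission-density matrix logB (T x S). Each step subtracts
// the row maximum of logB before exponentiating, so arbitrarily peaked
// densities cannot overflow; the offsets are restored in the returned
// log-likelihood.
// [[Rcpp::export(name = ".forward_loglik_cpp")]]
double forward_loglik_cpp(NumericMatrix logB, NumericVector pi,
                          NumericMatrix A) {
  const int T = logB.nrow(), S = logB.ncol();
  std::vector<double> alpha(S), tmp(S);
  double ll = 0.0;

  double m = logB(0, 0);
  for (int s = 1; s < S; ++s) m = std::max(m, logB(0, s));
  double c = 0.0;
  for (int s = 0; s < S; ++s) {
    alpha[s] = pi[s] * std::exp(logB(0, s) - m);
    c += alpha[s];
  }
  if (c <= 0.0) return R_NegInf;
  for (int s = 0; s < S; ++s) alpha[s] /= c;
  ll += std::log(c) + m;

  for (int t = 1; t < T; ++t) {
    m = logB(t, 0);
    for (int s = 1; s < S; ++s) m = std::max(m, logB(t, s));
    c = 0.0;
    for (int s = 0; s < S; ++s) {
      double acc = 0.0;
      for (int r = 0; r < S; ++r) acc += alpha[r] * A(r, s);
      tmp[s] = acc * std::exp(logB(t, s) - m);
      c += tmp[s];
    }
    if (c <= 0.0) return R_NegInf;
    for (int s = 0; s < S; ++s) alpha[s] = tmp[s] / c;
    ll += std::log(c) + m;
  }
  return ll;
}

// Scaled backward recursion; returns the same total log-likelihood as the
// forward pass. Kept as an internal consistency check.
// [[Rcpp::export(name = ".backward_loglik_cpp")]]
double backward_loglik_cpp(NumericMatrix logB, NumericVector pi,
                           NumericMatrix A) {
  const int T = logB.nrow(), S = logB.ncol();
  std::vector<double> beta(S, 1.0), tmp(S);
  double ll = 0.0;

  for (int t = T - 2; t >= 0; --t) {
    double m = logB(t + 1, 0);
    for (int s = 1; s < S; ++s) m = std::max(m, logB(t + 1, s));
    double c = 0.0;
    for (int s = 0; s < S; ++s) {
      double acc = 0.0;
      for (int r = 0; r < S; ++r)
        acc += A(s, r) * std::exp(logB(t + 1, r) - m) * beta[r];
      tmp[s] = acc;
      c += acc;
    }
    if (c <= 0.0) return R_NegInf;
    for (int s = 0; s < S; ++s) beta[s] = tmp[s] / c;
    ll += std::log(c) + m;
  }

  double m = logB(0, 0);
  for (int s = 1; s < S; ++s) m = std::max(m, logB(0, s));
  double c = 0.0;
  for (int s = 0; s < S; ++s) c += pi[s] * std::exp(logB(0, s) - m) * beta[s];
  if (c <= 0.0) return R_NegInf;
  return ll + std::log(c) + m;
}
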