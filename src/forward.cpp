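#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward recursion for one track.
//
// dens  : T x N matrix, joint state-dependent densities P(z_t | state)
// tpm   : T x (N*N) matrix; row t holds Gamma_t in column-major order
//         (entry [i,j] at column i + N*j), i.e. the matrix governing the
//         transition into time t. Row 1 is ignored (delta applies there).
// delta : length-N initial distribution.
//
// Returns the log-likelihood, or -Inf with the 1-based index of the first
// time point where the total forward mass vanished.
// [[Rcpp::export(name = ".forward_ll_cpp")]]
List forward_ll_cpp(NumericMatrix dens, NumericMatrix tpm, NumericVector delta) {
  const int T = dens.nrow(), N = dens.ncol();
  std::vector<double> phi(N), nxt(N);
  double ll = 0.0;

  double s = 0.0;
  for (int i = 0; i < N; ++i) { phi[i] = delta[i] * dens(0, i); s += phi[i]; }
  if (!(s > 0.0) || !R_finite(s))
    return List::create(_["loglik"] = R_NegInf, _["bad_t"] = 1);
  for (int i = 0; i < N; ++i) phi[i] /= s;
  ll += std::log(s);

  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < N; ++j) {
      double a = 0.0;
      for (int i = 0; i < N; ++i) a += phi[i] * tpm(t, i + N * j);
      nxt[j] = a * dens(t, j);
      s += nxt[j];
    }
    if (!(s > 0.0) || !R_finite(s))
      return List::create(_["loglik"] = R_NegInf, _["bad_t"] = t + 1);
    for (int j = 0; j < N; ++j) phi[j] = nxt[j] / s;
    ll += std::log(s);
  }
  return List::create(_["loglik"] = ll, _["bad_t"] = -1);
}

// Pooled variant: rows of dens/tpm hold several tracks back to back;
// starts (1-based) marks the first row of each track. The recursion
// restarts from delta at each track boundary and the log-likelihoods
// add across tracks.
// [[Rcpp::export(name = ".forward_ll_multi_cpp")]]
List forward_ll_multi_cpp(NumericMatrix dens, NumericMatrix tpm,
                          NumericVector delta, IntegerVector starts) {
  const int N = dens.ncol(), K = starts.size(), Tall = dens.nrow();
  std::vector<double> phi(N), nxt(N);
  double ll = 0.0;
  for (int k = 0; k < K; ++k) {
    const int t0 = starts[k] - 1;
    const int t1 = (k + 1 < K) ? starts[k + 1] - 1 : Tall;
    double s = 0.0;
    for (int i = 0; i < N; ++i) { phi[i] = delta[i] * dens(t0, i); s += phi[i]; }
    if (!(s > 0.0) || !R_finite(s))
      return List::create(_["loglik"] = R_NegInf, _["track"] = k + 1,
                          _["bad_t"] = 1);
    for (int i = 0; i < N; ++i) phi[i] /= s;
    ll += std::log(s);
    for (int t = t0 + 1; t < t1; ++t) {
      s = 0.0;
      for (int j = 0; j < N; ++j) {
        double a = 0.0;
        for (int i = 0; i < N; ++i) a += phi[i] * tpm(t, i + N * j);
        nxt[j] = a * dens(t, j);
        s += nxt[j];
      }
      if (!(s > 0.0) || !R_finite(s))
        return List::create(_["loglik"] = R_NegInf, _["track"] = k + 1,
                            _["bad_t"] = t - t0 + 1);
      for (int j = 0; j < N; ++j) phi[j] = nxt[j] / s;
      ll += std::log(s);
    }
  }
  return List::create(_["loglik"] = ll, _["track"] = -1, _["bad_t"] = -1);
}
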