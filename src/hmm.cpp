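#include <Rcpp.h>
using namespace Rcpp;

// Gaussian log-density
static inline double ldnorm(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.5 * z * z - std::log(sd) - 0.918938533204672742; // log(sqrt(2*pi))
}

// Scaled forward-backward pass for a Gaussian-emission HMM.
// Returns the log-likelihood, the posterior state probabilities gamma (T x K)
// and the summed transition posteriors xi (K x K).
// [[Rcpp::export]]
List hmm_estep(NumericVector e, NumericVector pi, NumericMatrix A,
               NumericVector mu, NumericVector sigma) {
  const int T = e.size(), K = pi.size();
  NumericMatrix B(T, K), alpha(T, K), beta(T, K), gamma(T, K), xi(K, K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      B(t, k) = std::exp(ldnorm(e[t], mu[k], sigma[k]));

  std::vector<double> c(T);
  double ll = 0.0;
  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * B(0, k); s += alpha(0, k); }
  if (s <= 0) s = 1e-300;
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  ll += std::log(s);
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      alpha(t, k) = a * B(t, k);
      s += alpha(t, k);
    }
    if (s <= 0) s = 1e-300;
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
    ll += std::log(s);
  }
  // backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += A(k, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, k) = b / c[t + 1];
    }
  }
  // posteriors
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    if (g > 0) for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }
  for (int t = 0; t < T - 1; ++t) {
    double s2 = 0.0;
    NumericMatrix x(K, K);
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) {
        x(j, k) = alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k);
        s2 += x(j, k);
      }
    if (s2 > 0)
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k) xi(j, k) += x(j, k) / s2;
  }
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// Most probable state sequence (1-based states).
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericVector e, NumericVector pi, NumericMatrix A,
                          NumericVector mu, NumericVector sigma) {
  const int T = e.size(), K = pi.size();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  const double NEG = -1e300;
  for (int k = 0; k < K; ++k)
    delta(0, k) = (pi[k] > 0 ? std::log(pi[k]) : NEG) + ldnorm(e[0], mu[k], sigma[k]);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = NEG; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + (A(j, k) > 0 ? std::log(A(j, k)) : NEG);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + ldnorm(e[t], mu[k], sigma[k]);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  int arg = 0; double best = NEG;
  for (int k = 0; k < K; ++k) if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}

// Full EM fit: iterates scaled forward-backward E-steps and closed-form
// M-steps in-place until the log-likelihood stabilises.
// [[Rcpp::export]]
List hmm_fit(NumericVector e, NumericVector pi0, NumericMatrix A0,
             NumericVector mu0, NumericVector sigma0, int maxIter,
             double tol, double sdFloor) {
  const int T = e.size(), K = pi0.size();
  std::vector<double> pi(pi0.begin(), pi0.end());
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sigma(sigma0.begin(), sigma0.end());
  NumericMatrix A(clone(A0));
  NumericMatrix B(T, K), alpha(T, K), beta(T, K);
  std::vector<double> c(T);
  double ll = 0.0, llPrev = R_NegInf;
  int iter = 0;
  for (iter = 0; iter < maxIter; ++iter) {
    // emissions
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < K; ++k)
        B(t, k) = std::exp(ldnorm(e[t], mu[k], sigma[k]));
    // forward
    ll = 0.0;
    double s = 0.0;
    for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * B(0, k); s += alpha(0, k); }
    if (s <= 0) s = 1e-300;
    c[0] = s; ll += std::log(s);
    for (int k = 0; k < K; ++k) alpha(0, k) /= s;
    for (int t = 1; t < T; ++t) {
      s = 0.0;
      for (int k = 0; k < K; ++k) {
        double a = 0.0;
        for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
        alpha(t, k) = a * B(t, k);
        s += alpha(t, k);
      }
      if (s <= 0) s = 1e-300;
      c[t] = s; ll += std::log(s);
      for (int k = 0; k < K; ++k) alpha(t, k) /= s;
    }
    if (R_finite(llPrev) && std::fabs(ll - llPrev) < tol * (std::fabs(llPrev) + 1.0))
      break;
    llPrev = ll;
    // backward
    for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
    for (int t = T - 2; t >= 0; --t)
      for (int k = 0; k < K; ++k) {
        double b = 0.0;
        for (int j = 0; j < K; ++j) b += A(k, j) * B(t + 1, j) * beta(t + 1, j);
        beta(t, k) = b / c[t + 1];
      }
    // accumulate statistics
    std::vector<double> occ(K, 0.0), me(K, 0.0), xr(K, 0.0);
    std::vector<double> xi(K * K, 0.0);
    std::vector<double> g0(K, 0.0);
    std::vector<double> m2(K, 0.0);
    // gamma-based sums (means first, then variances with new means)
    for (int t = 0; t < T; ++t) {
      double gs = 0.0;
      for (int k = 0; k < K; ++k) gs += alpha(t, k) * beta(t, k);
      if (gs <= 0) gs = 1e-300;
      for (int k = 0; k < K; ++k) {
        double g = alpha(t, k) * beta(t, k) / gs;
        occ[k] += g;
        me[k] += g * e[t];
        if (t == 0) g0[k] = g;
      }
    }
    for (int t = 0; t < T - 1; ++t) {
      double s2 = 0.0;
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k)
          s2 += alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k);
      if (s2 <= 0) continue;
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k)
          xi[j * K + k] += alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k) / s2;
    }
    std::vector<double> muNew(mu);
    for (int k = 0; k < K; ++k)
      if (occ[k] > 1e-8) muNew[k] = me[k] / occ[k];
    for (int t = 0; t < T; ++t) {
      double gs = 0.0;
      for (int k = 0; k < K; ++k) gs += alpha(t, k) * beta(t, k);
      if (gs <= 0) gs = 1e-300;
      for (int k = 0; k < K; ++k) {
        double g = alpha(t, k) * beta(t, k) / gs;
        double d = e[t] - muNew[k];
        m2[k] += g * d * d;
      }
    }
    // M-step
    double ps = 0.0;
    for (int k = 0; k < K; ++k) { pi[k] = std::max(g0[k], 1e-12); ps += pi[k]; }
    for (int k = 0; k < K; ++k) pi[k] /= ps;
    for (int j = 0; j < K; ++j) {
      double rs = 0.0;
      for (int k = 0; k < K; ++k) rs += xi[j * K + k];
      if (rs > 0)
        for (int k = 0; k < K; ++k) A(j, k) = xi[j * K + k] / rs;
      double rows = 0.0;
      for (int k = 0; k < K; ++k) { A(j, k) = std::max(A(j, k), 1e-12); rows += A(j, k); }
      for (int k = 0; k < K; ++k) A(j, k) /= rows;
    }
    for (int k = 0; k < K; ++k) {
      mu[k] = muNew[k];
      if (occ[k] > 1e-8) sigma[k] = std::max(std::sqrt(m2[k] / occ[k]), sdFloor);
    }
  }
  return List::create(_["pi"] = NumericVector(pi.begin(), pi.end()),
                      _["A"] = A,
                      _["mu"] = NumericVector(mu.begin(), mu.end()),
                      _["sigma"] = NumericVector(sigma.begin(), sigma.end()),
                      _["loglik"] = ll, _["iter"] = iter);
}
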