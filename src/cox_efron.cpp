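#include <Rcpp.h>
using namespace Rcpp;

// Log partial likelihood, score and observed information for the Cox model
// with Efron's tie correction. Inputs must be sorted by DECREASING time so
// the risk set at each event time is a running prefix sum; ties (events and
// censored at the same time) form contiguous groups and censored subjects at
// an event time are kept in that time's risk set.
//
// The linear predictor is centred before exponentiation; the centring cancels
// exactly in the log likelihood, score and information.
// [[Rcpp::export]]
List cox_efron_stats(const NumericMatrix& X, const NumericVector& time,
                     const IntegerVector& status, const NumericVector& beta) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> eta(n), w(n);
  double etabar = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < p; ++k) s += X(i, k) * beta[k];
    eta[i] = s;
    etabar += s;
  }
  etabar /= n;
  for (int i = 0; i < n; ++i) w[i] = std::exp(eta[i] - etabar);

  double ll = 0.0;
  NumericVector grad(p);
  std::vector<double> I(p * p, 0.0);     // upper triangle accumulated
  double S0 = 0.0;
  std::vector<double> S1(p, 0.0), S2(p * p, 0.0);
  std::vector<double> D1(p), D2(p * p), m(p);

  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && time[j] == time[i]) ++j;   // tie group [i, j)

    for (int g = i; g < j; ++g) {              // enter risk set
      const double wg = w[g];
      S0 += wg;
      for (int k = 0; k < p; ++k) {
        const double xk = X(g, k);
        S1[k] += wg * xk;
        for (int l = k; l < p; ++l) S2[k * p + l] += wg * xk * X(g, l);
      }
    }

    int d = 0;
    double D0 = 0.0;
    std::fill(D1.begin(), D1.end(), 0.0);
    std::fill(D2.begin(), D2.end(), 0.0);
    for (int g = i; g < j; ++g) {
      if (status[g] != 1) continue;
      ++d;
      const double wg = w[g];
      D0 += wg;
      ll += eta[g] - etabar;
      for (int k = 0; k < p; ++k) {
        const double xk = X(g, k);
        grad[k] += xk;
        D1[k] += wg * xk;
        for (int l = k; l < p; ++l) D2[k * p + l] += wg * xk * X(g, l);
      }
    }

    for (int r = 0; r < d; ++r) {
      const double f = (double)r / d;
      const double denom = S0 - f * D0;
      ll -= std::log(denom);
      for (int k = 0; k < p; ++k) {
        m[k] = (S1[k] - f * D1[k]) / denom;
        grad[k] -= m[k];
      }
      for (int k = 0; k < p; ++k)
        for (int l = k; l < p; ++l)
          I[k * p + l] += (S2[k * p + l] - f * D2[k * p + l]) / denom
                          - m[k] * m[l];
    }
    i = j;
  }

  NumericMatrix info(p, p);
  for (int k = 0; k < p; ++k)
    for (int l = k; l < p; ++l) {
      info(k, l) = I[k * p + l];
      info(l, k) = I[k * p + l];
    }

  return List::create(_["loglik"] = ll, _["gradient"] = grad,
                      _["information"] = info);
}
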