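#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward recursion for a discrete-state HMM.
// logdens: T x N matrix of per-time emission log-densities,
// gamma:   N x N transition matrix (row = state at t, col = state at t+1),
// omega:   initial state distribution.
// Returns the log marginal likelihood; -Inf when the recursion degenerates.
// [[Rcpp::export]]
double fwd_loglik_cpp(NumericMatrix logdens, NumericMatrix gamma,
                      NumericVector omega) {
  const int T = logdens.nrow(), N = logdens.ncol();
  std::vector<double> phi(N), nxt(N);
  double ll = 0.0;

  double m = logdens(0, 0);
  for (int j = 1; j < N; ++j) m = std::max(m, logdens(0, j));
  double c = 0.0;
  for (int j = 0; j < N; ++j) {
    phi[j] = omega[j] * std::exp(logdens(0, j) - m);
    c += phi[j];
  }
  if (!(c > 0.0) || !std::isfinite(c)) return R_NegInf;
  ll += std::log(c) + m;
  for (int j = 0; j < N; ++j) phi[j] /= c;

  for (int t = 1; t < T; ++t) {
    m = logdens(t, 0);
    for (int j = 1; j < N; ++j) m = std::max(m, logdens(t, j));
    c = 0.0;
    for (int j = 0; j < N; ++j) {
      double s = 0.0;
      for (int k = 0; k < N; ++k) s += phi[k] * gamma(k, j);
      nxt[j] = s * std::exp(logdens(t, j) - m);
      c += nxt[j];
    }
    if (!(c > 0.0) || !std::isfinite(c)) return R_NegInf;
    ll += std::log(c) + m;
    for (int j = 0; j < N; ++j) phi[j] = nxt[j] / c;
  }
  return ll;
}

// Forward-backward smoothing with per-step scaling.
// Returns a T x N matrix of P(S_t = j | x_{1:T}); each row sums to 1.
// [[Rcpp::export]]
NumericMatrix fwd_bwd_cpp(NumericMatrix logdens, NumericMatrix gamma,
                          NumericVector omega) {
  const int T = logdens.nrow(), N = logdens.ncol();
  NumericMatrix alpha(T, N), out(T, N);
  std::vector<double> cvec(T), mvec(T);

  double m = logdens(0, 0);
  for (int j = 1; j < N; ++j) m = std::max(m, logdens(0, j));
  double c = 0.0;
  for (int j = 0; j < N; ++j) {
    alpha(0, j) = omega[j] * std::exp(logdens(0, j) - m);
    c += alpha(0, j);
  }
  if (!(c > 0.0) || !std::isfinite(c)) stop("forward recursion degenerated");
  for (int j = 0; j < N; ++j) alpha(0, j) /= c;
  cvec[0] = c; mvec[0] = m;

  for (int t = 1; t < T; ++t) {
    m = logdens(t, 0);
    for (int j = 1; j < N; ++j) m = std::max(m, logdens(t, j));
    c = 0.0;
    for (int j = 0; j < N; ++j) {
      double s = 0.0;
      for (int k = 0; k < N; ++k) s += alpha(t - 1, k) * gamma(k, j);
      alpha(t, j) = s * std::exp(logdens(t, j) - m);
      c += alpha(t, j);
    }
    if (!(c > 0.0) || !std::isfinite(c)) stop("forward recursion degenerated");
    for (int j = 0; j < N; ++j) alpha(t, j) /= c;
    cvec[t] = c; mvec[t] = m;
  }

  // scaled backward pass: beta_T = 1, then
  // beta_t(k) = sum_j gamma(k,j) * exp(logdens(t+1,j) - m_{t+1}) * beta_{t+1}(j) / c_{t+1}
  std::vector<double> beta(N, 1.0), bnxt(N);
  for (int j = 0; j < N; ++j) out(T - 1, j) = alpha(T - 1, j);
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < N; ++k) {
      double s = 0.0;
      for (int j = 0; j < N; ++j)
        s += gamma(k, j) * std::exp(logdens(t + 1, j) - mvec[t + 1]) * beta[j];
      bnxt[k] = s / cvec[t + 1];
    }
    double rs = 0.0;
    for (int k = 0; k < N; ++k) {
      beta[k] = bnxt[k];
      out(t, k) = alpha(t, k) * beta[k];
      rs += out(t, k);
    }
    for (int k = 0; k < N; ++k) out(t, k) /= rs;
  }
  return out;
}

// One-step-ahead predicted state probabilities P(S_t = j | x_{1:t-1}),
// used for forecast pseudo-residuals. Row t of the result conditions on
// observations strictly before t; row 1 is omega.
// [[Rcpp::export]]
NumericMatrix fwd_predict_cpp(NumericMatrix logdens, NumericMatrix gamma,
                              NumericVector omega) {
  const int T = logdens.nrow(), N = logdens.ncol();
  NumericMatrix out(T, N);
  std::vector<double> phi(N), nxt(N);
  for (int j = 0; j < N; ++j) out(0, j) = omega[j];

  double m = logdens(0, 0);
  for (int j = 1; j < N; ++j) m = std::max(m, logdens(0, j));
  double c = 0.0;
  for (int j = 0; j < N; ++j) {
    phi[j] = omega[j] * std::exp(logdens(0, j) - m);
    c += phi[j];
  }
  if (!(c > 0.0) || !std::isfinite(c)) stop("forward recursion degenerated");
  for (int j = 0; j < N; ++j) phi[j] /= c;

  for (int t = 1; t < T; ++t) {
    double rs = 0.0;
    for (int j = 0; j < N; ++j) {
      double s = 0.0;
      for (int k = 0; k < N; ++k) s += phi[k] * gamma(k, j);
      out(t, j) = s;
      rs += s;
    }
    for (int j = 0; j < N; ++j) out(t, j) /= rs;
    m = logdens(t, 0);
    for (int j = 1; j < N; ++j) m = std::max(m, logdens(t, j));
    c = 0.0;
    for (int j = 0; j < N; ++j) {
      nxt[j] = out(t, j) * std::exp(logdens(t, j) - m);
      c += nxt[j];
    }
    if (!(c > 0.0) || !std::isfinite(c)) stop("forward recursion degenerated");
    for (int j = 0; j < N; ++j) phi[j] = nxt[j] / c;
  }
  return out;
}

// Negative log posterior of the bivariate two-state model, computed
// directly from the working-scale parameter vector:
// (logit gRR, logit gMM, muRH, muRV, muMH, muMV,
//  log sRH, log sRV, log sMH, log sMV, atanh rhoR, atanh rhoM).
// Emission densities are evaluated in the forward loop to avoid
// allocations; returns 1e10 when the posterior is not finite.
// [[Rcpp::export]]
double nll_bivariate_cpp(NumericVector par, NumericVector h, NumericVector v,
                         double alpha, double beta, NumericMatrix pm,
                         NumericMatrix pdelta, bool use_mp) {
  const int T = h.size();
  const double gRR = 1.0 / (1.0 + std::exp(-par[0]));
  const double gMM = 1.0 / (1.0 + std::exp(-par[1]));
  double mu[2][2] = {{par[2], par[3]}, {par[4], par[5]}};
  double sg[2][2] = {{std::exp(par[6]), std::exp(par[7])},
                     {std::exp(par[8]), std::exp(par[9])}};
  double rho[2] = {std::tanh(par[10]), std::tanh(par[11])};
  double G[2][2] = {{gRR, 1.0 - gRR}, {1.0 - gMM, gMM}};

  double cst[2], om[2];
  for (int j = 0; j < 2; ++j) {
    om[j] = 1.0 - rho[j] * rho[j];
    cst[j] = -std::log(2.0 * M_PI) - std::log(sg[j][0]) -
             std::log(sg[j][1]) - 0.5 * std::log(om[j]);
  }
  double phi[2], nxt[2], ld[2];
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    for (int j = 0; j < 2; ++j) {
      const double zh = (h[t] - mu[j][0]) / sg[j][0];
      const double zv = (v[t] - mu[j][1]) / sg[j][1];
      ld[j] = cst[j] -
        (zh * zh - 2.0 * rho[j] * zh * zv + zv * zv) / (2.0 * om[j]);
    }
    const double m = std::max(ld[0], ld[1]);
    double c = 0.0;
    if (t == 0) {
      for (int j = 0; j < 2; ++j) {
        phi[j] = 0.5 * std::exp(ld[j] - m);
        c += phi[j];
      }
    } else {
      for (int j = 0; j < 2; ++j) {
        nxt[j] = (phi[0] * G[0][j] + phi[1] * G[1][j]) * std::exp(ld[j] - m);
        c += nxt[j];
      }
      phi[0] = nxt[0]; phi[1] = nxt[1];
    }
    if (!(c > 0.0) || !std::isfinite(c)) return 1e10;
    ll += std::log(c) + m;
    phi[0] /= c; phi[1] /= c;
  }
  double lp = ll + R::dbeta(gRR, alpha, beta, 1) +
              R::dbeta(gMM, alpha, beta, 1);
  if (use_mp) {
    for (int j = 0; j < 2; ++j)
      for (int d = 0; d < 2; ++d)
        lp += R::dnorm(mu[j][d], pm(j, d), std::sqrt(pdelta(j, d)), 1);
  }
  if (!std::isfinite(lp)) return 1e10;
  return -lp;
}

// Univariate (horizontal-only) counterpart; working scale
// (logit gRR, logit gMM, muR, muM, log sR, log sM).
// [[Rcpp::export]]
double nll_univariate_cpp(NumericVector par, NumericVector h, double alpha,
                          double beta) {
  const int T = h.size();
  const double gRR = 1.0 / (1.0 + std::exp(-par[0]));
  const double gMM = 1.0 / (1.0 + std::exp(-par[1]));
  double mu[2] = {par[2], par[3]};
  double sg[2] = {std::exp(par[4]), std::exp(par[5])};
  double G[2][2] = {{gRR, 1.0 - gRR}, {1.0 - gMM, gMM}};
  double phi[2], nxt[2], ld[2];
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    for (int j = 0; j < 2; ++j) ld[j] = R::dnorm(h[t], mu[j], sg[j], 1);
    const double m = std::max(ld[0], ld[1]);
    double c = 0.0;
    if (t == 0) {
      for (int j = 0; j < 2; ++j) {
        phi[j] = 0.5 * std::exp(ld[j] - m);
        c += phi[j];
      }
    } else {
      for (int j = 0; j < 2; ++j) {
        nxt[j] = (phi[0] * G[0][j] + phi[1] * G[1][j]) * std::exp(ld[j] - m);
        c += nxt[j];
      }
      phi[0] = nxt[0]; phi[1] = nxt[1];
    }
    if (!(c > 0.0) || !std::isfinite(c)) return 1e10;
    ll += std::log(c) + m;
    phi[0] /= c; phi[1] /= c;
  }
  double lp = ll + R::dbeta(gRR, alpha, beta, 1) +
              R::dbeta(gMM, alpha, beta, 1);
  if (!std::isfinite(lp)) return 1e10;
  return -lp;
}
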