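#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step simulators for mass-action reaction networks, driven by a
// supplied uniform stream via inverse-transform sampling.
//
// Per time step j (step length tau, with the final step truncated to hit T
// exactly) and reaction channel k, the uniform at flat position j*K + k is
// mapped through the Poisson quantile (tau-leap) or the standard normal
// quantile (Euler-Maruyama discretisation of the chemical Langevin
// equation). One stream row of length K * ceil(T / tau) drives one path.

// Combinatorial mass-action propensity: a_k = c_k * prod_i C(x_i, alpha_ik).
// In discrete mode the count is zero when any reactant is insufficient; in
// continuous (CLE) mode the falling-factorial polynomial extension
// x(x-1)...(x-a+1)/a! is evaluated as-is on real-valued states.
static void propensities_cpp(const double* x, int n, int K,
                             const IntegerMatrix& alpha,
                             const NumericVector& rate,
                             bool continuous, double* a) {
  for (int k = 0; k < K; ++k) {
    double prod = rate[k];
    for (int i = 0; i < n && prod != 0.0; ++i) {
      int al = alpha(i, k);
      if (al == 0) continue;
      if (!continuous && x[i] < al) { prod = 0.0; break; }
      double fact = 1.0, ff = 1.0;
      for (int r = 0; r < al; ++r) { ff *= (x[i] - r); fact *= (r + 1); }
      prod *= ff / fact;
    }
    a[k] = prod;
  }
}

static void step_state(double* x, int n, int K, const IntegerMatrix& alpha,
                       const IntegerMatrix& zeta, const NumericVector& rate,
                       const LogicalVector& frozen, const double* u,
                       double tau_j, bool cle, bool clamp_negative,
                       double* a) {
  propensities_cpp(x, n, K, alpha, rate, cle, a);
  if (!cle) {
    for (int k = 0; k < K; ++k) {
      double lambda = a[k] * tau_j;
      if (lambda < 0.0) lambda = 0.0;
      double p = (lambda > 0.0) ? R::qpois(u[k], lambda, 1, 0) : 0.0;
      if (p > 0.0)
        for (int i = 0; i < n; ++i)
          if (!frozen[i]) x[i] += p * zeta(i, k);
    }
    if (clamp_negative)
      for (int i = 0; i < n; ++i)
        if (!frozen[i] && x[i] < 0.0) x[i] = 0.0;
  } else {
    for (int k = 0; k < K; ++k) {
      double uk = u[k];
      if (uk < 1e-16) uk = 1e-16;
      if (uk > 1.0 - 1e-16) uk = 1.0 - 1e-16;
      double z = R::qnorm(uk, 0.0, 1.0, 1, 0);
      double diff = (a[k] > 0.0) ? std::sqrt(a[k] * tau_j) : 0.0;
      double incr = a[k] * tau_j + diff * z;
      for (int i = 0; i < n; ++i)
        if (!frozen[i]) x[i] += incr * zeta(i, k);
    }
  }
}

// One path, full trajectory on the tau-grid: (steps+1) x n matrix.
// [[Rcpp::export(name = ".simulate_traj_cpp")]]
NumericMatrix simulate_traj_cpp(NumericVector u, NumericVector x0,
                                IntegerMatrix alpha, IntegerMatrix zeta,
                                NumericVector rate, LogicalVector frozen,
                                double tau, double T, int steps, bool cle,
                                bool clamp_negative) {
  int n = x0.size(), K = rate.size();
  if (u.size() != (R_xlen_t)steps * K)
    stop("uniform stream has length %d, expected %d", (int)u.size(), steps * K);
  NumericMatrix out(steps + 1, n);
  std::vector<double> x(x0.begin(), x0.end()), a(K);
  for (int i = 0; i < n; ++i) out(0, i) = x[i];
  for (int j = 0; j < steps; ++j) {
    double tau_j = (j == steps - 1) ? T - (steps - 1) * tau : tau;
    step_state(x.data(), n, K, alpha, zeta, rate, frozen, &u[(R_xlen_t)j * K],
               tau_j, cle, clamp_negative, a.data());
    for (int i = 0; i < n; ++i) out(j + 1, i) = x[i];
  }
  return out;
}

// Many paths, final state only: one row of U per path, N x n matrix out.
// [[Rcpp::export(name = ".simulate_batch_cpp")]]
NumericMatrix simulate_batch_cpp(NumericMatrix U, NumericVector x0,
                                 IntegerMatrix alpha, IntegerMatrix zeta,
                                 NumericVector rate, LogicalVector frozen,
                                 double tau, double T, int steps, bool cle,
                                 bool clamp_negative) {
  int n = x0.size(), K = rate.size();
  if (U.ncol() != steps * K)
    stop("uniform stream has %d columns, expected %d", U.ncol(), steps * K);
  int N = U.nrow();
  NumericMatrix out(N, n);
  std::vector<double> x(n), a(K), u(K);
  for (int p = 0; p < N; ++p) {
    for (int i = 0; i < n; ++i) x[i] = x0[i];
    for (int j = 0; j < steps; ++j) {
      double tau_j = (j == steps - 1) ? T - (steps - 1) * tau : tau;
      for (int k = 0; k < K; ++k) u[k] = U(p, j * K + k);
      step_state(x.data(), n, K, alpha, zeta, rate, frozen, u.data(), tau_j,
                 cle, clamp_negative, a.data());
    }
    for (int i = 0; i < n; ++i) out(p, i) = x[i];
  }
  return out;
}
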