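#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integrator for N Kuramoto oscillators on a ring with the
// nonlocal kernel (1/N) * [1 + A cos(2*pi*(i-j)/N)] and phase lag beta:
//
//   dphi_i/dt = rho - (1/N) sum_j [1 + A cos(2*pi*(i-j)/N)] cos(phi_i - phi_j - beta)
//
// The kernel is rank-3: 1 + A[cos t_i cos t_j + sin t_i sin t_j] with
// t_i = 2*pi*i/N, and cos(phi_i - phi_j - beta) expands into products of
// per-i and per-j trigonometric terms, so each step costs O(N) instead of
// O(N^2). Optional white noise enters as Euler-Maruyama increments
// sqrt(2*D*dt) * N(0,1), drawn from R's RNG so set.seed() governs.
//
// Phases are kept unwrapped (cumulative). Rows of the returned matrix are
// the state at steps 0, record_every, 2*record_every, ...
// [[Rcpp::export]]
List sim_ring_cpp(NumericVector phi0, double A, double beta, double rho,
                  double dt, int n_steps, int record_every, double D) {
  const int N = phi0.size();
  const int n_rec = n_steps / record_every;
  NumericMatrix out(n_rec + 1, N);

  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<double> ct(N), st(N), c(N), s(N), drift(N);
  for (int i = 0; i < N; ++i) {
    ct[i] = std::cos(2.0 * M_PI * i / N);
    st[i] = std::sin(2.0 * M_PI * i / N);
  }
  const double cosb = std::cos(beta), sinb = std::sin(beta);
  const double sig = (D > 0.0) ? std::sqrt(2.0 * D * dt) : 0.0;
  const double invN = 1.0 / N;

  for (int i = 0; i < N; ++i) out(0, i) = phi[i];

  for (int k = 0; k < n_steps; ++k) {
    double Sc = 0, Ss = 0, P1 = 0, P2 = 0, P3 = 0, P4 = 0;
    for (int i = 0; i < N; ++i) {
      c[i] = std::cos(phi[i]);
      s[i] = std::sin(phi[i]);
      Sc += c[i];
      Ss += s[i];
      P1 += ct[i] * c[i];
      P2 += st[i] * c[i];
      P3 += ct[i] * s[i];
      P4 += st[i] * s[i];
    }
    for (int i = 0; i < N; ++i) {
      // cos/sin of (phi_i - beta)
      const double ca = c[i] * cosb + s[i] * sinb;
      const double sa = s[i] * cosb - c[i] * sinb;
      const double Kc = Sc + A * (ct[i] * P1 + st[i] * P2);
      const double Ks = Ss + A * (ct[i] * P3 + st[i] * P4);
      drift[i] = rho - invN * (ca * Kc + sa * Ks);
    }
    if (sig > 0.0) {
      for (int i = 0; i < N; ++i) phi[i] += dt * drift[i] + sig * norm_rand();
    } else {
      for (int i = 0; i < N; ++i) phi[i] += dt * drift[i];
    }
    if ((k & 1023) == 0) {
      for (int i = 0; i < N; ++i)
        if (!std::isfinite(phi[i]))
          stop("non-finite phase for oscillator %d at integration step %d", i + 1, k + 1);
    }
    if ((k + 1) % record_every == 0) {
      const int row = (k + 1) / record_every;
      for (int i = 0; i < N; ++i) out(row, i) = phi[i];
    }
  }
  for (int i = 0; i < N; ++i)
    if (!std::isfinite(phi[i]))
      stop("non-finite phase for oscillator %d at integration step %d", i + 1, n_steps);

  NumericVector fin(phi.begin(), phi.end());
  return List::create(_["phases"] = out, _["final"] = fin);
}

// Forward-Euler integrator for the two-population chimera:
//
//   tau * dgamma_i/dt = rho - mu sum_j cos(gamma_i - gamma_j - beta)
//                           - nu sum_j cos(gamma_i - phi_j  - beta)
//   tau * dphi_i/dt   = rho - mu sum_j cos(phi_i  - phi_j  - beta)
//                           - nu sum_j cos(phi_i  - gamma_j - beta)
//
// Within-group sums include j = i (the printed self-term is retained).
// The state vector is (gamma_1..n, phi_1..n), unwrapped.
// [[Rcpp::export]]
List sim_twopop_cpp(NumericVector gamma0, NumericVector phi0, double mu,
                    double nu, double beta, double rho, double tau,
                    double dt, int n_steps, int record_every) {
  const int n = gamma0.size();
  const int M = 2 * n;
  const int n_rec = n_steps / record_every;
  NumericMatrix out(n_rec + 1, M);

  std::vector<double> th(M);
  for (int i = 0; i < n; ++i) th[i] = gamma0[i];
  for (int i = 0; i < n; ++i) th[n + i] = phi0[i];

  const double cosb = std::cos(beta), sinb = std::sin(beta);
  const double inv_tau = 1.0 / tau;
  std::vector<double> c(M), s(M);

  for (int i = 0; i < M; ++i) out(0, i) = th[i];

  for (int k = 0; k < n_steps; ++k) {
    double Scg = 0, Ssg = 0, Scp = 0, Ssp = 0;
    for (int i = 0; i < M; ++i) {
      c[i] = std::cos(th[i]);
      s[i] = std::sin(th[i]);
      if (i < n) { Scg += c[i]; Ssg += s[i]; } else { Scp += c[i]; Ssp += s[i]; }
    }
    // sum_j cos(x_i - x_j - beta) = cos(x_i - beta) * sum_j cos(x_j)
    //                             + sin(x_i - beta) * sum_j sin(x_j)
    const double Cg = mu * Scg + nu * Scp, Sg = mu * Ssg + nu * Ssp;  // for gamma units
    const double Cp = mu * Scp + nu * Scg, Sp = mu * Ssp + nu * Ssg;  // for phi units
    for (int i = 0; i < M; ++i) {
      const double ca = c[i] * cosb + s[i] * sinb;
      const double sa = s[i] * cosb - c[i] * sinb;
      const double coup = (i < n) ? (ca * Cg + sa * Sg) : (ca * Cp + sa * Sp);
      th[i] += dt * inv_tau * (rho - coup);
    }
    if ((k & 4095) == 0) {
      for (int i = 0; i < M; ++i)
        if (!std::isfinite(th[i]))
          stop("non-finite phase for oscillator %d at integration step %d", i + 1, k + 1);
    }
    if ((k + 1) % record_every == 0) {
      const int row = (k + 1) / record_every;
      for (int i = 0; i < M; ++i) out(row, i) = th[i];
    }
  }
  for (int i = 0; i < M; ++i)
    if (!std::isfinite(th[i]))
      stop("non-finite phase for oscillator %d at integration step %d", i + 1, n_steps);

  NumericVector fin(th.begin(), th.end());
  return List::create(_["phases"] = out, _["final"] = fin);
}
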