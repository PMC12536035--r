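// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// One phase of an Izhikevich-network simulation, optionally with online FORCE
// (recursive-least-squares) decoder updates.
//
// Neuron model (forward Euler, hard reset):
//   C dv/dt = k (v - v_r)(v - v_t) - u + I_bias + s
//   du/dt   = a (b (v - v_r) - u)
//   v >= v_peak: spike; v -> v_reset, u -> u + d_u
// Synapses are double exponentials, advanced by their exact exponential
// solution between spikes; a spike adds 1/(tau_r * tau_d) to h:
//   dr/dt = -r/tau_d + h,  dh/dt = -h/tau_r
// Currents: s = G * (W0 r) + Q * eta_fb * xhat with xhat = d^T r.
//
// RLS (when rls = true), every rls_every steps against supervisor column k:
//   P <- P - (P r)(P r)^T / (1 + r^T P r)
//   d <- d - (P_new r) e^T,   e = xhat - x_k
// With dale_project, decoder rows are projected onto their neuron's sign
// (excitatory rows >= 0, inhibitory rows <= 0) after every update, so every
// column of the effective weight G*W0 + Q*eta_fb*d^T stays sign-definite.
// fb_offset subtracts a uniform (neuron-independent) feedback current
// Q * fb_offset * sum(xhat): with a non-negative encoder eta_fb = |eta| this
// removes the common mode of the feedback while the synaptic weights keep
// their Dale sign structure.
//
// supervisor is m x n_steps (column k = target at step k); pass a 0 x 0
// matrix when unused. probe_units are 0-based indices.
// [[Rcpp::export]]
List izh_force_cpp(const arma::sp_mat& W0, const arma::mat& eta_fb,
                   arma::mat d, arma::mat P, const arma::mat& supervisor,
                   List prm, double G, double Q, double dt, int n_steps,
                   bool rls, int rls_every, const arma::ivec& neuron_sign,
                   int dale_mode, double fb_offset, int record_stride,
                   const IntegerVector& probe_units, bool record_spikes,
                   double t0, arma::vec v0, arma::vec u0, arma::vec r0,
                   arma::vec h0, arma::mat d_free) {
  // dale_mode: 0 = unconstrained; 1 = hard projection of d after each RLS
  // update; 2 = lazy projection (an unconstrained shadow decoder d_free is
  // updated by RLS against its own error, and d is its sign projection)
  arma::vec v = v0, u = u0, r = r0, h = h0;
  const int N = W0.n_rows;
  const int m = d.n_cols;
  const double Cm = prm["C"], vr = prm["v_r"], vt = prm["v_t"];
  const double vpeak = prm["v_peak"], vreset = prm["v_reset"];
  const double a = prm["a"], b = prm["b"], kk = prm["k"], du = prm["d_u"];
  const double Ibias = prm["I_bias"], taur = prm["tau_r"], taud = prm["tau_d"];

  const bool have_sup = supervisor.n_cols > 0;
  if (rls && (!have_sup || (int)supervisor.n_cols < n_steps))
    stop("supervisor must provide one column per step when RLS is on");

  const double ed = std::exp(-dt / taud);
  const double er = std::exp(-dt / taur);
  const double cf = (er - ed) / (1.0 / taud - 1.0 / taur);
  const double h_inc = 1.0 / (taur * taud);

  const int n_rec = n_steps / record_stride;
  arma::mat xhat_rec(m, n_rec);
  arma::vec t_rec(n_rec);
  const int n_probe = probe_units.size();
  arma::mat v_probe(n_probe, n_rec), u_probe(n_probe, n_rec), r_probe(n_probe, n_rec);

  std::vector<int> sp_unit;
  std::vector<double> sp_time;
  std::vector<double> err_trace;
  bool dale_ok = true;
  int rec = 0;

  arma::vec xhat(m), I(N), e(m), Pr(N);

  for (int k = 0; k < n_steps; ++k) {
    xhat = d.t() * r;
    I = Ibias + G * (W0 * r);
    if (Q != 0.0) {
      I += Q * (eta_fb * xhat);
      if (fb_offset != 0.0) I -= Q * fb_offset * arma::accu(xhat);
    }

    if (k % record_stride == 0 && rec < n_rec) {
      xhat_rec.col(rec) = xhat;
      t_rec(rec) = t0 + k * dt;
      for (int j = 0; j < n_probe; ++j) {
        v_probe(j, rec) = v(probe_units[j]);
        u_probe(j, rec) = u(probe_units[j]);
        r_probe(j, rec) = r(probe_units[j]);
      }
      ++rec;
    }

    if (rls && (k % rls_every == 0)) {
      e = xhat - supervisor.col(k);
      Pr = P * r;
      const double denom = 1.0 + arma::dot(r, Pr);
      if (!std::isfinite(denom))
        stop("non-finite RLS denominator at step %d; reduce dt or increase lambda", k + 1);
      P -= (Pr * Pr.t()) / denom;
      if (dale_mode == 2) {
        const arma::vec e_free = d_free.t() * r - supervisor.col(k);
        d_free -= (Pr / denom) * e_free.t();
        d = d_free;
      } else {
        d -= (Pr / denom) * e.t();
      }
      if (dale_mode > 0) {
        for (int i = 0; i < N; ++i) {
          if (neuron_sign(i) > 0) {
            for (int c2 = 0; c2 < m; ++c2) if (d(i, c2) < 0) d(i, c2) = 0;
          } else {
            for (int c2 = 0; c2 < m; ++c2) if (d(i, c2) > 0) d(i, c2) = 0;
          }
        }
      }
      err_trace.push_back(arma::norm(e));
      if (err_trace.size() % 500 == 0) P = 0.5 * (P + P.t());
    }

    // membrane update
    v += dt * (kk * (v - vr) % (v - vt) - u + I) / Cm;
    u += dt * a * (b * (v - vr) - u);

    // synaptic decay (exact), then spike handling
    r = r * ed + h * cf;
    h = h * er;
    for (int i = 0; i < N; ++i) {
      if (v(i) >= vpeak) {
        if (record_spikes) {
          sp_unit.push_back(i + 1);
          sp_time.push_back(t0 + (k + 1) * dt);
        }
        v(i) = vreset;
        u(i) += du;
        h(i) += h_inc;
      }
    }
    if ((k & 2047) == 0 && !v.is_finite())
      stop("non-finite membrane state at integration step %d", k + 1);
  }
  if (!v.is_finite() || !u.is_finite())
    stop("non-finite membrane state at integration step %d", n_steps);

  return List::create(
      _["xhat"] = xhat_rec, _["times"] = t_rec, _["spike_unit"] = sp_unit,
      _["spike_time"] = sp_time, _["v_probe"] = v_probe, _["u_probe"] = u_probe,
      _["r_probe"] = r_probe, _["d"] = d, _["P"] = P, _["v"] = v, _["u"] = u,
      _["r"] = r, _["h"] = h, _["rls_error"] = err_trace, _["dale_ok"] = dale_ok,
      _["d_free"] = d_free);
}
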