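#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Explicit-Euler integrator for the four-dimensional mean-field equations of
// an Izhikevich population with Lorentzian spike-threshold disorder,
// generalized to several populations coupled through conductance-based
// synapse groups. Per population the state is (r, v, u); each synapse group m
// carries its own activation s_m driven by the presynaptic rate:
//
//   C r' = Delta k^2 sgn(v - vr) (v - vr) / (pi C)
//          + r [ k (2 v - vr - vtheta) - sum_m g_m s_m ]
//   C v' = k v (v - vr - vtheta) - pi C r (Delta sgn(v - vr) + pi C r / k)
//          + k vr vtheta - u + I + sum_m g_m s_m (E_m - v)
//   tau_u u' = b (v - vr) - u + tau_u kappa r
//   tau_s s_m' = -s_m + tau_s J_m r_pre(m)
//
// All afferent conductances enter both the r and the v equation, as each
// g s (E - v) membrane current contributes a -g s v term whose population
// average generates the -r g s term of the rate equation.
//
// pops[p]: list(C, k, vr, vtheta, kappa, b, tau_u, delta,
//               I[n_steps], r0, v0, u0)
// syns[m]: list(pre, post (0-based), J, g, E, tau_s, s0)
// [[Rcpp::export]]
List mf_sim_cpp(List pops, List syns, double dt, int n_steps,
                int record_every) {
  const int P = pops.size();
  const int M = syns.size();

  std::vector<double> C(P), k(P), vr(P), vth(P), kap(P), b(P), tau_u(P),
      del(P), r(P), v(P), u(P);
  std::vector<NumericVector> I(P);
  for (int p = 0; p < P; ++p) {
    List pp = pops[p];
    C[p] = as<double>(pp["C"]); k[p] = as<double>(pp["k"]);
    vr[p] = as<double>(pp["vr"]); vth[p] = as<double>(pp["vtheta"]);
    kap[p] = as<double>(pp["kappa"]); b[p] = as<double>(pp["b"]);
    tau_u[p] = as<double>(pp["tau_u"]); del[p] = as<double>(pp["delta"]);
    I[p] = as<NumericVector>(pp["I"]);
    r[p] = as<double>(pp["r0"]); v[p] = as<double>(pp["v0"]);
    u[p] = as<double>(pp["u0"]);
  }

  std::vector<int> pre(M), post(M);
  std::vector<double> J(M), g(M), E(M), tau_s(M), s(M);
  std::vector<std::vector<int>> aff(P);
  for (int m = 0; m < M; ++m) {
    List sm = syns[m];
    pre[m] = as<int>(sm["pre"]); post[m] = as<int>(sm["post"]);
    J[m] = as<double>(sm["J"]); g[m] = as<double>(sm["g"]);
    E[m] = as<double>(sm["E"]); tau_s[m] = as<double>(sm["tau_s"]);
    s[m] = as<double>(sm["s0"]);
    aff[post[m]].push_back(m);
  }

  const int n_rec = n_steps / record_every;
  NumericMatrix rec_r(n_rec, P), rec_v(n_rec, P), rec_u(n_rec, P),
      rec_s(n_rec, M);
  NumericVector rec_t(n_rec);

  std::vector<double> dr(P), dv(P), du(P), ds(M);
  const double PI = M_PI;

  // derivative of the full coupled system at the current state
  auto derivs = [&](int t) {
    for (int p = 0; p < P; ++p) {
      double Gs = 0.0, GsE = 0.0;
      for (size_t a = 0; a < aff[p].size(); ++a) {
        int m = aff[p][a];
        Gs += g[m] * s[m];
        GsE += g[m] * s[m] * E[m];
      }
      double sv = (v[p] > vr[p]) ? 1.0 : ((v[p] < vr[p]) ? -1.0 : 0.0);
      dr[p] = (del[p] * k[p] * k[p] * sv * (v[p] - vr[p]) / (PI * C[p])
               + r[p] * (k[p] * (2.0 * v[p] - vr[p] - vth[p]) - Gs)) / C[p];
      dv[p] = (k[p] * v[p] * (v[p] - vr[p] - vth[p])
               - PI * C[p] * r[p] * (del[p] * sv + PI * C[p] * r[p] / k[p])
               + k[p] * vr[p] * vth[p] - u[p] + I[p][t]
               + GsE - Gs * v[p]) / C[p];
      du[p] = (b[p] * (v[p] - vr[p]) - u[p]) / tau_u[p] + kap[p] * r[p];
    }
    for (int m = 0; m < M; ++m)
      ds[m] = -s[m] / tau_s[m] + J[m] * r[pre[m]];
  };

  for (int t = 0; t < n_steps; ++t) {
    derivs(t);
    // stability safeguard: when a stiff relaxation spike would move the
    // state too far in one step, refine that step locally (plain Euler at
    // the nominal dt everywhere else; thresholds 2 mV / 0.02 spikes/ms per
    // step are far above any smooth trajectory's per-step motion)
    double excess = 0.0;
    for (int p = 0; p < P; ++p) {
      excess = std::max(excess, std::abs(dv[p]) * dt / 2.0);
      excess = std::max(excess, std::abs(dr[p]) * dt / 0.02);
    }
    int nsub = excess > 1.0 ? std::min(1000, (int)std::ceil(excess)) : 1;
    double h = dt / nsub;
    for (int sub = 0; sub < nsub; ++sub) {
      if (sub > 0) derivs(t);
      for (int p = 0; p < P; ++p) {
        r[p] += h * dr[p];
        v[p] += h * dv[p];
        u[p] += h * du[p];
        if (!R_finite(v[p]) || std::abs(v[p]) > 1e8)
          stop("mean-field state blew up (population %d, step %d, t=%.3f ms)",
               p + 1, t + 1, t * dt);
      }
      for (int m = 0; m < M; ++m) s[m] += h * ds[m];
    }

    if ((t + 1) % record_every == 0) {
      int bi = (t + 1) / record_every - 1;
      rec_t[bi] = (t + 1) * dt;
      for (int p = 0; p < P; ++p) {
        rec_r(bi, p) = r[p]; rec_v(bi, p) = v[p]; rec_u(bi, p) = u[p];
      }
      for (int m = 0; m < M; ++m) rec_s(bi, m) = s[m];
    }
  }

  return List::create(
    _["time"] = rec_t, _["r"] = rec_r, _["v"] = rec_v, _["u"] = rec_u,
    _["s"] = rec_s,
    _["r_final"] = wrap(r), _["v_final"] = wrap(v), _["u_final"] = wrap(u),
    _["s_final"] = wrap(s));
}
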