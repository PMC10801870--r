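#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Explicit-Euler simulator for networks of Izhikevich neurons with quenched
// spike thresholds. Supports multiple populations coupled through synapse
// groups that are either "shared" (all-to-all: one synaptic activation per
// group, driven by the presynaptic population rate) or "sparse" (one
// activation per postsynaptic neuron, kicked by presynaptic spikes through an
// explicit weight list). The recovery variable u is either global per
// population (driven by the population-mean voltage and rate) or per neuron.
//
// pops[p]: list(n, C, k, vr, kappa, b, tau_u, vp, v0, u_per_neuron,
//               vtheta[n], I_common[n_steps], I_extra (n_steps x K or NULL),
//               masks (n x K or NULL), v_init[n], u_init (1 or n))
// syns[m]: list(pre, post (0-based), tau_s, g, E, shared (bool), J,
//               src_ptr[n_pre+1], tgt[], w[], s_init (1 or n_post))
// [[Rcpp::export]]
List snn_sim_cpp(List pops, List syns, double dt, int n_steps,
                 int record_every, bool record_raster) {
  const int P = pops.size();
  const int M = syns.size();

  // unpack populations
  std::vector<int> n(P);
  std::vector<double> C(P), k(P), vr(P), kappa(P), b(P), tau_u(P), vp(P), v0(P);
  std::vector<bool> u_per(P);
  std::vector<NumericVector> vtheta(P), Icom(P), v(P), u(P);
  std::vector<NumericMatrix> Iextra(P), masks(P);
  std::vector<bool> has_extra(P);
  for (int p = 0; p < P; ++p) {
    List pp = pops[p];
    n[p] = as<int>(pp["n"]);
    C[p] = as<double>(pp["C"]); k[p] = as<double>(pp["k"]);
    vr[p] = as<double>(pp["vr"]); kappa[p] = as<double>(pp["kappa"]);
    b[p] = as<double>(pp["b"]); tau_u[p] = as<double>(pp["tau_u"]);
    vp[p] = as<double>(pp["vp"]); v0[p] = as<double>(pp["v0"]);
    u_per[p] = as<bool>(pp["u_per_neuron"]);
    vtheta[p] = clone(as<NumericVector>(pp["vtheta"]));
    Icom[p] = as<NumericVector>(pp["I_common"]);
    v[p] = clone(as<NumericVector>(pp["v_init"]));
    u[p] = clone(as<NumericVector>(pp["u_init"]));
    has_extra[p] = !Rf_isNull(pp["I_extra"]);
    if (has_extra[p]) {
      Iextra[p] = as<NumericMatrix>(pp["I_extra"]);
      masks[p] = as<NumericMatrix>(pp["masks"]);
    }
  }

  // unpack synapse groups
  std::vector<int> pre(M), post(M);
  std::vector<double> tau_s(M), g(M), E(M), J(M);
  std::vector<bool> shared(M);
  std::vector<IntegerVector> src_ptr(M), tgt(M);
  std::vector<NumericVector> w(M), s(M);
  std::vector<std::vector<int>> aff(P);  // afferent synapse groups per pop
  for (int m = 0; m < M; ++m) {
    List sm = syns[m];
    pre[m] = as<int>(sm["pre"]); post[m] = as<int>(sm["post"]);
    tau_s[m] = as<double>(sm["tau_s"]); g[m] = as<double>(sm["g"]);
    E[m] = as<double>(sm["E"]); shared[m] = as<bool>(sm["shared"]);
    J[m] = as<double>(sm["J"]);
    if (!shared[m]) {
      src_ptr[m] = as<IntegerVector>(sm["src_ptr"]);
      tgt[m] = as<IntegerVector>(sm["tgt"]);
      w[m] = as<NumericVector>(sm["w"]);
    }
    s[m] = clone(as<NumericVector>(sm["s_init"]));
    aff[post[m]].push_back(m);
  }

  // recording buffers
  const int n_rec = n_steps / record_every;
  NumericMatrix rec_r(n_rec, P), rec_v(n_rec, P), rec_u(n_rec, P);
  NumericMatrix rec_s(n_rec, M);
  NumericVector rec_t(n_rec);
  std::vector<double> count_acc(P, 0.0);

  std::vector<std::vector<int>> rast_id(P);
  std::vector<std::vector<double>> rast_t(P);

  std::vector<std::vector<int>> spikers(P);
  std::vector<double> dv(0);

  for (int t = 0; t < n_steps; ++t) {
    // population-mean voltages at step start (drive the global u)
    std::vector<double> vbar(P, 0.0);
    for (int p = 0; p < P; ++p) {
      double acc = 0.0;
      const double* vv = v[p].begin();
      for (int i = 0; i < n[p]; ++i) acc += vv[i];
      vbar[p] = acc / n[p];
      if (!R_finite(vbar[p]) || std::abs(vbar[p]) > 1e7)
        stop("SNN state blew up (population %d, step %d, t=%.3f ms)",
             p + 1, t + 1, t * dt);
    }

    // membrane update, spike detection
    for (int p = 0; p < P; ++p) {
      double* vv = v[p].begin();
      double* uu = u[p].begin();
      const double* vt = vtheta[p].begin();
      const double Ic = Icom[p][t];
      const double invC = dt / C[p];
      spikers[p].clear();

      // neuron-specific extra input this step (masked segments)
      int K = has_extra[p] ? Iextra[p].ncol() : 0;

      for (int i = 0; i < n[p]; ++i) {
        double Ii = Ic;
        for (int kk = 0; kk < K; ++kk) {
          double a = Iextra[p](t, kk);
          if (a != 0.0) Ii += a * masks[p](i, kk);
        }
        double Isyn = 0.0;
        for (size_t a = 0; a < aff[p].size(); ++a) {
          int m = aff[p][a];
          double sm = shared[m] ? s[m][0] : s[m][i];
          Isyn += g[m] * sm * (E[m] - vv[i]);
        }
        double ui = u_per[p] ? uu[i] : uu[0];
        vv[i] += invC * (k[p] * (vv[i] - vr[p]) * (vv[i] - vt[i]) - ui + Ii + Isyn);
        if (vv[i] >= vp[p]) {
          vv[i] = v0[p];
          spikers[p].push_back(i);
        }
      }

      // recovery variable
      int cnt = (int)spikers[p].size();
      count_acc[p] += cnt;
      if (u_per[p]) {
        for (int i = 0; i < n[p]; ++i)
          uu[i] += dt * (-uu[i] + b[p] * (vv[i] - vr[p])) / tau_u[p];
        for (int si = 0; si < cnt; ++si) uu[spikers[p][si]] += kappa[p];
      } else {
        uu[0] += dt * (-uu[0] + b[p] * (vbar[p] - vr[p])) / tau_u[p]
                 + kappa[p] * ((double)cnt / n[p]);
      }

      if (record_raster && cnt > 0) {
        double ts = (t + 1) * dt;
        for (int si = 0; si < cnt; ++si) {
          rast_id[p].push_back(spikers[p][si] + 1);
          rast_t[p].push_back(ts);
        }
      }
    }

    // synaptic activations: exponential decay plus spike kicks
    for (int m = 0; m < M; ++m) {
      double* ss = s[m].begin();
      const double dec = dt / tau_s[m];
      if (shared[m]) {
        ss[0] -= dec * ss[0];
        int cnt = (int)spikers[pre[m]].size();
        if (cnt > 0) ss[0] += J[m] * ((double)cnt / n[pre[m]]);
      } else {
        const int np = s[m].size();
        for (int i = 0; i < np; ++i) ss[i] -= dec * ss[i];
        const int* sp = src_ptr[m].begin();
        const int* tg = tgt[m].begin();
        const double* ww = w[m].begin();
        for (size_t si = 0; si < spikers[pre[m]].size(); ++si) {
          int j = spikers[pre[m]][si];
          for (int e = sp[j]; e < sp[j + 1]; ++e) ss[tg[e]] += ww[e];
        }
      }
    }

    // recording at bin end
    if ((t + 1) % record_every == 0) {
      int bi = (t + 1) / record_every - 1;
      rec_t[bi] = (t + 1) * dt;
      for (int p = 0; p < P; ++p) {
        rec_r(bi, p) = count_acc[p] / (n[p] * record_every * dt);
        count_acc[p] = 0.0;
        double acc = 0.0;
        for (int i = 0; i < n[p]; ++i) acc += v[p][i];
        rec_v(bi, p) = acc / n[p];
        double ua = 0.0;
        if (u_per[p]) {
          for (int i = 0; i < n[p]; ++i) ua += u[p][i];
          ua /= n[p];
        } else ua = u[p][0];
        rec_u(bi, p) = ua;
      }
      for (int m = 0; m < M; ++m) {
        double acc = 0.0;
        for (int i = 0; i < (int)s[m].size(); ++i) acc += s[m][i];
        rec_s(bi, m) = acc / s[m].size();
      }
    }
  }

  List rasters(P);
  for (int p = 0; p < P; ++p) {
    rasters[p] = List::create(_["neuron"] = wrap(rast_id[p]),
                              _["time"] = wrap(rast_t[p]));
  }
  List v_fin(P), u_fin(P), s_fin(M);
  for (int p = 0; p < P; ++p) { v_fin[p] = v[p]; u_fin[p] = u[p]; }
  for (int m = 0; m < M; ++m) s_fin[m] = s[m];

  return List::create(
    _["time"] = rec_t, _["r"] = rec_r, _["vbar"] = rec_v, _["u"] = rec_u,
    _["s"] = rec_s, _["rasters"] = rasters,
    _["v_final"] = v_fin, _["u_final"] = u_fin, _["s_final"] = s_fin);
}
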