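#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 integrator for the coupled cable network.
//
// State layout (documented in R/assemble.R): the first nv entries are
// membrane potentials in cable-major, compartment-minor order (compartment
// n_passive + 1 of each cable is the active one); the last n_cables entries
// are the Morris-Lecar recovery variables w, one per cable.
//
// The linear part of dV/dt (leak, axial, gap-junction coupling) is supplied
// as a sparse operator in triplet form: dV_lin[i] = sum_k A_x[k] * V[A_j[k]]
// for rows A_i[k] == i, plus the constant term b0 (leak driving force).
// Morris-Lecar currents of the active compartments and the rectangular
// stimulus are added on top.  All currents are divided by the per-compartment
// capacitance at the end.

struct MLp {
  double gca, gk, gl, eca, ek, el, v1, v2, v3, v4, phi;
};

struct Net {
  int nv, ncab, nnz;
  std::vector<int> ai, aj, act;
  std::vector<double> ax, b0, stim, inv_cm;
  MLp p;
};

static inline void rhs(const Net &N,
                       const std::vector<double> &v,
                       const std::vector<double> &w,
                       std::vector<double> &dv, std::vector<double> &dw,
                       const bool stim_on) {
  const int nv = N.nv;
  for (int i = 0; i < nv; ++i) dv[i] = N.b0[i];
  for (int k = 0; k < N.nnz; ++k) dv[N.ai[k]] += N.ax[k] * v[N.aj[k]];
  if (stim_on)
    for (int i = 0; i < nv; ++i) dv[i] += N.stim[i];
  const MLp &p = N.p;
  for (int c = 0; c < N.ncab; ++c) {
    const int a = N.act[c];
    const double V = v[a];
    const double minf = 0.5 * (1.0 + std::tanh((V - p.v1) / p.v2));
    const double winf = 0.5 * (1.0 + std::tanh((V - p.v3) / p.v4));
    const double lam  = std::cosh((V - p.v3) / (2.0 * p.v4)); // 1 / tau_w
    dv[a] += -p.gca * minf * (V - p.eca) - p.gk * w[c] * (V - p.ek)
             - p.gl * (V - p.el);
    dw[c] = p.phi * (winf - w[c]) * lam;
  }
  for (int i = 0; i < nv; ++i) dv[i] *= N.inv_cm[i];
}

// [[Rcpp::export(name = ".rk4_network_cpp")]]
List rk4_network_cpp(IntegerVector Ai, IntegerVector Aj, NumericVector Ax,
                     NumericVector b0, NumericVector stim,
                     double stim_onset, double stim_offset,
                     IntegerVector active_idx, List ml,
                     NumericVector cm_v, NumericVector v0, NumericVector w0,
                     double t0, double t1, double dt, int record_every) {
  Net N;
  N.nv = v0.size(); N.ncab = w0.size(); N.nnz = Ai.size();
  N.ai.assign(Ai.begin(), Ai.end());
  N.aj.assign(Aj.begin(), Aj.end());
  N.ax.assign(Ax.begin(), Ax.end());
  N.b0.assign(b0.begin(), b0.end());
  N.stim.assign(stim.begin(), stim.end());
  N.act.assign(active_idx.begin(), active_idx.end());
  N.p.gca = ml["g_ca"]; N.p.gk = ml["g_k"]; N.p.gl = ml["g_l"];
  N.p.eca = ml["e_ca"]; N.p.ek = ml["e_k"]; N.p.el = ml["e_l"];
  N.p.v1 = ml["v1"]; N.p.v2 = ml["v2"]; N.p.v3 = ml["v3"]; N.p.v4 = ml["v4"];
  N.p.phi = ml["phi"];
  const double cm_active = ml["c_m"];
  N.inv_cm.resize(N.nv);
  for (int i = 0; i < N.nv; ++i) N.inv_cm[i] = 1.0 / cm_v[i];
  for (int c = 0; c < N.ncab; ++c) N.inv_cm[N.act[c]] = 1.0 / cm_active;

  const int nv = N.nv, ncab = N.ncab;
  const int n_steps = (int) std::llround((t1 - t0) / dt);
  const int n_rec = n_steps / record_every + 1;
  NumericMatrix Vout(n_rec, nv), Wout(n_rec, ncab);
  NumericVector times(n_rec);

  std::vector<double> v(v0.begin(), v0.end()), w(w0.begin(), w0.end());
  std::vector<double> k1v(nv), k2v(nv), k3v(nv), k4v(nv);
  std::vector<double> k1w(ncab), k2w(ncab), k3w(ncab), k4w(ncab);
  std::vector<double> tv(nv), tw(ncab);

  times[0] = t0;
  for (int i = 0; i < nv; ++i) Vout(0, i) = v[i];
  for (int c = 0; c < ncab; ++c) Wout(0, c) = w[c];
  int rec = 1;

  for (int s = 0; s < n_steps; ++s) {
    const double t = t0 + s * dt;
    // stimulus gate evaluated at the sub-step times of the RK4 stages
    const bool on1 = (t >= stim_onset && t < stim_offset);
    const double th = t + 0.5 * dt;
    const bool on2 = (th >= stim_onset && th < stim_offset);
    const double tf = t + dt;
    const bool on4 = (tf >= stim_onset && tf < stim_offset);

    rhs(N, v, w, k1v, k1w, on1);
    for (int i = 0; i < nv; ++i) tv[i] = v[i] + 0.5 * dt * k1v[i];
    for (int c = 0; c < ncab; ++c) tw[c] = w[c] + 0.5 * dt * k1w[c];
    rhs(N, tv, tw, k2v, k2w, on2);
    for (int i = 0; i < nv; ++i) tv[i] = v[i] + 0.5 * dt * k2v[i];
    for (int c = 0; c < ncab; ++c) tw[c] = w[c] + 0.5 * dt * k2w[c];
    rhs(N, tv, tw, k3v, k3w, on2);
    for (int i = 0; i < nv; ++i) tv[i] = v[i] + dt * k3v[i];
    for (int c = 0; c < ncab; ++c) tw[c] = w[c] + dt * k3w[c];
    rhs(N, tv, tw, k4v, k4w, on4);

    for (int i = 0; i < nv; ++i)
      v[i] += dt / 6.0 * (k1v[i] + 2.0 * k2v[i] + 2.0 * k3v[i] + k4v[i]);
    for (int c = 0; c < ncab; ++c)
      w[c] += dt / 6.0 * (k1w[c] + 2.0 * k2w[c] + 2.0 * k3w[c] + k4w[c]);

    for (int i = 0; i < nv; ++i)
      if (!std::isfinite(v[i]))
        stop("integration diverged (non-finite membrane potential) at t = %f ms",
             t + dt);

    if ((s + 1) % record_every == 0) {
      times[rec] = t0 + (s + 1) * dt;
      for (int i = 0; i < nv; ++i) Vout(rec, i) = v[i];
      for (int c = 0; c < ncab; ++c) Wout(rec, c) = w[c];
      ++rec;
    }
  }

  return List::create(_["times"] = times, _["V"] = Vout, _["W"] = Wout);
}
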