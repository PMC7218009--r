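// Branched-cable integrator: Crank-Nicolson voltage solve on the Hines
// (tree-ordered) matrix with exponential-Euler gate updates from
// precomputed voltage tables. Units: mV, ms, nA, uS, uF, mM.
#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
using namespace Rcpp;

namespace {

struct GateTab {
  std::vector<double> inf, expdt;
  double v0, dv;
  int n, expo;
  inline void look(double v, double &mi, double &ed) const {
    double u = (v - v0) / dv;
    if (u <= 0) { mi = inf[0]; ed = expdt[0]; return; }
    if (u >= n - 1) { mi = inf[n - 1]; ed = expdt[n - 1]; return; }
    int i = (int)u;
    double f = u - i;
    mi = inf[i] + f * (inf[i + 1] - inf[i]);
    ed = expdt[i] + f * (expdt[i + 1] - expdt[i]);
  }
};

struct Chan {
  std::vector<int> comp;          // compartment indices (0-based)
  std::vector<double> g;          // uS per compartment entry
  double e_rev;
  bool ca_gated, ca_source;
  double hill_n, kd;
  std::vector<GateTab> gates;
  std::vector<std::vector<double>> state;  // gate x comp-entry
};

struct Drive {                    // time-varying conductance drive
  std::vector<int> comp;
  std::vector<double> mult;       // uS per unit of waveform value
  double e_rev;
  std::vector<double> t, y;       // piecewise-linear waveform
  size_t cur = 0;
  inline double at(double tt) {
    if (t.empty()) return 0.0;
    if (tt <= t.front()) return y.front();
    if (tt >= t.back()) return y.back();
    while (cur + 1 < t.size() && t[cur + 1] < tt) ++cur;
    while (cur > 0 && t[cur] > tt) --cur;
    double f = (tt - t[cur]) / (t[cur + 1] - t[cur]);
    return y[cur] + f * (y[cur + 1] - y[cur]);
  }
};

GateTab make_gate(const List &g) {
  GateTab gt;
  NumericVector inf = g["inf"], expdt = g["expdt"];
  gt.inf.assign(inf.begin(), inf.end());
  gt.expdt.assign(expdt.begin(), expdt.end());
  gt.v0 = as<double>(g["v0"]);
  gt.dv = as<double>(g["dv"]);
  gt.n = inf.size();
  gt.expo = as<int>(g["exponent"]);
  return gt;
}

Drive make_drive(const List &d) {
  Drive dr;
  IntegerVector comp = d["comp"];
  NumericVector mult = d["mult"], t = d["t"], y = d["y"];
  dr.comp.assign(comp.begin(), comp.end());
  dr.mult.assign(mult.begin(), mult.end());
  dr.e_rev = as<double>(d["e_rev"]);
  dr.t.assign(t.begin(), t.end());
  dr.y.assign(y.begin(), y.end());
  return dr;
}

inline double gate_pow(double m, int e) {
  double me = m;
  for (int q = 1; q < e; ++q) me *= m;
  return me;
}

} // namespace

// [[Rcpp::export]]
List engine_run(List model, double duration, double dt, int record_every,
                bool record_full = false) {
  IntegerVector parent_r = model["parent"];
  NumericVector cm_r = model["cm_nF"], gl_r = model["g_leak_uS"],
                el_r = model["e_leak"], gax_r = model["g_ax_uS"],
                v0_r = model["v_init"];
  const int n = parent_r.size();
  std::vector<int> parent(parent_r.begin(), parent_r.end());
  std::vector<double> v(v0_r.begin(), v0_r.end());

  // static conductance (leak + any constant drives folded in by the caller)
  std::vector<double> gm0(n), bc0(n);
  for (int i = 0; i < n; ++i) {
    gm0[i] = gl_r[i];
    bc0[i] = gl_r[i] * el_r[i];
  }
  if (model.containsElementNamed("g_static_uS") &&
      !Rf_isNull(model["g_static_uS"])) {
    NumericVector gs = model["g_static_uS"], es = model["e_static"];
    for (int i = 0; i < n; ++i) {
      gm0[i] += gs[i];
      bc0[i] += gs[i] * es[i];
    }
  }

  // precomputed Hines-matrix pieces: off-diagonals are constant
  std::vector<double> gax_sum(n, 0.0);
  for (int i = 1; i < n; ++i) {
    gax_sum[i] += gax_r[i];
    gax_sum[parent[i]] += gax_r[i];
  }
  // theta-method weighting: 1 = implicit Euler (default; damps the
  // numerical ringing a symmetric scheme shows at spike peaks),
  // 0.5 = Crank-Nicolson
  double theta = 1.0;
  if (model.containsElementNamed("theta") && !Rf_isNull(model["theta"]))
    theta = as<double>(model["theta"]);
  const double th1 = 1.0 - theta;
  std::vector<double> bq(n), gaxh(n), dstat(n), astat(n);
  for (int i = 0; i < n; ++i) {
    double cdt = cm_r[i] / dt;
    gaxh[i] = th1 * gax_r[i];
    bq[i] = -theta * gax_r[i];
    dstat[i] = cdt + theta * gax_sum[i];
    astat[i] = cdt - th1 * gax_sum[i];
  }

  // channels
  List chans_r = model["channels"];
  std::vector<Chan> chans;
  int cal_idx = -1;  // channel named ca_l, for m_CaL recording
  for (int c = 0; c < chans_r.size(); ++c) {
    List cl = chans_r[c];
    Chan ch;
    IntegerVector comp = cl["comp"];
    NumericVector g = cl["g_uS"];
    ch.comp.assign(comp.begin(), comp.end());
    ch.g.assign(g.begin(), g.end());
    ch.e_rev = as<double>(cl["e_rev"]);
    ch.ca_gated = as<bool>(cl["ca_gated"]);
    ch.ca_source = as<bool>(cl["ca_source"]);
    ch.hill_n = as<double>(cl["ca_hill_n"]);
    ch.kd = as<double>(cl["ca_kd"]);
    List gates = cl["gates"];
    for (int k = 0; k < gates.size(); ++k) ch.gates.push_back(make_gate(gates[k]));
    ch.state.resize(ch.gates.size());
    for (size_t k = 0; k < ch.gates.size(); ++k) {
      ch.state[k].resize(ch.comp.size());
      for (size_t j = 0; j < ch.comp.size(); ++j) {
        double mi, ed;
        ch.gates[k].look(v[ch.comp[j]], mi, ed);
        ch.state[k][j] = mi;
      }
    }
    if (as<std::string>(cl["name"]) == "ca_l") cal_idx = (int)chans.size();
    chans.push_back(std::move(ch));
  }

  // time-varying drives and stimuli
  List drives_r = model["drives"];
  std::vector<Drive> drives;
  for (int d = 0; d < drives_r.size(); ++d) drives.push_back(make_drive(drives_r[d]));
  Drive istim;
  int istim_comp = 0;
  bool has_istim = model.containsElementNamed("istim") &&
                   !Rf_isNull(model["istim"]);
  if (has_istim) {
    List is_r = model["istim"];
    istim = make_drive(is_r);
    if (is_r.containsElementNamed("comp_at")) istim_comp = as<int>(is_r["comp_at"]);
  }
  Drive clampw;
  bool clamped = model.containsElementNamed("clamp") &&
                 !Rf_isNull(model["clamp"]);
  if (clamped) clampw = make_drive(model["clamp"]);

  // calcium pool at the soma (compartment 0)
  List pool = model["ca_pool"];
  double ca_f = as<double>(pool["f_influx"]),
         ca_tau = as<double>(pool["tau_ms"]),
         ca_rest = as<double>(pool["ca_rest"]);
  double ca = ca_rest;
  const double ca_decay = std::exp(-dt / ca_tau);

  IntegerVector band_r = model["band_comp"];
  std::vector<int> band(band_r.begin(), band_r.end());

  const long nsteps = (long)std::llround(duration / dt);
  const int nrec = (int)(nsteps / record_every) + 1;
  NumericVector rt(nrec), rv_soma(nrec), rv_band(nrec), rm_cal(nrec),
      rca(nrec), ri_stim(nrec), ri_clamp(nrec);
  NumericMatrix vfull = record_full ? NumericMatrix(nrec, n) : NumericMatrix(1, 1);
  std::vector<double> spikes;
  spikes.reserve(4096);

  std::vector<double> gm(n), bcur(n), d(n), r(n), vn(n);
  double last_spike = -1e9;
  bool spike_armed = true;  // re-armed once the soma repolarizes below -20 mV

  auto record = [&](int k, double t, double istim_val, double iclamp) {
    rt[k] = t;
    rv_soma[k] = v[0];
    double vb = 0.0;
    if (!band.empty()) {
      for (int i : band) vb += v[i];
      vb /= band.size();
    }
    rv_band[k] = vb;
    double mc = 0.0;
    if (cal_idx >= 0 && !chans[cal_idx].comp.empty()) {
      const auto &st = chans[cal_idx].state[0];
      for (double m : st) mc += m;
      mc /= st.size();
    }
    rm_cal[k] = mc;
    rca[k] = ca;
    ri_stim[k] = istim_val;
    ri_clamp[k] = iclamp;
    if (record_full) for (int i = 0; i < n; ++i) vfull(k, i) = v[i];
  };
  record(0, 0.0, has_istim ? istim.at(0.0) : 0.0, 0.0);

  int krec = 1;
  for (long s = 0; s < nsteps; ++s) {
    const double t = s * dt, tmid = t + dt / 2, tnew = t + dt;

    std::memcpy(gm.data(), gm0.data(), n * sizeof(double));
    std::memcpy(bcur.data(), bc0.data(), n * sizeof(double));

    // gate updates (exponential Euler at current voltage), then currents
    for (auto &ch : chans) {
      const size_t nc = ch.comp.size();
      if (nc == 0) continue;
      if (!ch.ca_gated) {
        for (size_t k = 0; k < ch.gates.size(); ++k) {
          auto &st = ch.state[k];
          const GateTab &gt = ch.gates[k];
          for (size_t j = 0; j < nc; ++j) {
            double mi, ed;
            gt.look(v[ch.comp[j]], mi, ed);
            st[j] = mi + (st[j] - mi) * ed;
          }
        }
        for (size_t j = 0; j < nc; ++j) {
          double open = 1.0;
          for (size_t k = 0; k < ch.gates.size(); ++k)
            open *= gate_pow(ch.state[k][j], ch.gates[k].expo);
          const double gg = ch.g[j] * open;
          gm[ch.comp[j]] += gg;
          bcur[ch.comp[j]] += gg * ch.e_rev;
        }
      } else {
        const double can = std::pow(ca, ch.hill_n);
        const double open = can / (can + std::pow(ch.kd, ch.hill_n));
        for (size_t j = 0; j < nc; ++j) {
          const double gg = ch.g[j] * open;
          gm[ch.comp[j]] += gg;
          bcur[ch.comp[j]] += gg * ch.e_rev;
        }
      }
    }
    for (auto &dr : drives) {
      const double w = dr.at(tmid);
      if (w != 0.0) {
        for (size_t j = 0; j < dr.comp.size(); ++j) {
          const double gg = w * dr.mult[j];
          gm[dr.comp[j]] += gg;
          bcur[dr.comp[j]] += gg * dr.e_rev;
        }
      }
    }
    const double is_val = has_istim ? istim.at(tmid) : 0.0;
    if (has_istim) bcur[istim_comp] += is_val;

    // Crank-Nicolson tree solve (leaf -> root elimination, root -> leaf
    // back-substitution); off-diagonals bq are constant
    for (int i = 0; i < n; ++i) {
      d[i] = dstat[i] + theta * gm[i];
      r[i] = (astat[i] - th1 * gm[i]) * v[i] + bcur[i];
    }
    if (th1 != 0.0) {
      for (int i = 1; i < n; ++i) {
        const int p = parent[i];
        r[i] += gaxh[i] * v[p];
        r[p] += gaxh[i] * v[i];
      }
    }
    for (int i = n - 1; i >= 1; --i) {
      const int p = parent[i];
      const double f = bq[i] / d[i];
      d[p] -= f * bq[i];
      r[p] -= f * r[i];
    }
    double iclamp = 0.0;
    vn[0] = clamped ? clampw.at(tnew) : r[0] / d[0];
    for (int i = 1; i < n; ++i) vn[i] = (r[i] - bq[i] * vn[parent[i]]) / d[i];

    if (clamped) {
      // electrode current required to hold the command
      const double vm0 = theta * vn[0] + th1 * v[0];
      iclamp = cm_r[0] * (vn[0] - v[0]) / dt + gm[0] * vm0 - bcur[0];
      if (has_istim && istim_comp == 0) iclamp += is_val;
      for (int i = 1; i < n; ++i) {
        if (parent[i] == 0)
          iclamp += gax_r[i] * (vm0 - (theta * vn[i] + th1 * v[i]));
      }
    }

    // calcium pool driven by flagged channels at the soma
    double ica = 0.0;
    for (auto &ch : chans) {
      if (!ch.ca_source) continue;
      for (size_t j = 0; j < ch.comp.size(); ++j) {
        if (ch.comp[j] != 0) continue;
        double open = 1.0;
        for (size_t k = 0; k < ch.gates.size(); ++k)
          open *= gate_pow(ch.state[k][j], ch.gates[k].expo);
        ica += ch.g[j] * open * (theta * vn[0] + th1 * v[0] - ch.e_rev);
      }
    }
    const double ca_target = ca_rest + ca_tau * (-ca_f * ica);
    ca = ca_target + (ca - ca_target) * ca_decay;
    if (ca < ca_rest) ca = ca_rest;

    // spike detection at the soma: upward 0 mV crossing with 1 ms lockout;
    // the detector re-arms only after repolarization below -20 mV so that
    // numerical ripple on the falling phase is never double-counted
    if (!clamped && spike_armed && v[0] < 0.0 && vn[0] >= 0.0 &&
        tnew - last_spike >= 1.0) {
      spikes.push_back(tnew);
      last_spike = tnew;
      spike_armed = false;
    }
    if (!spike_armed && vn[0] < -20.0) spike_armed = true;

    std::swap(v, vn);
    if ((s + 1) % record_every == 0) {
      if (!std::isfinite(v[0]) || !std::isfinite(v[n / 2])) {
        stop("integration failure: non-finite voltage at t = %f ms", tnew);
      }
      record(krec++, tnew, is_val, iclamp);
    }
  }

  List out = List::create(
      _["time"] = rt, _["v_soma"] = rv_soma, _["v_band"] = rv_band,
      _["m_cal"] = rm_cal, _["ca"] = rca, _["i_stim"] = ri_stim,
      _["i_clamp"] = ri_clamp,
      _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
      _["v_final"] = NumericVector(v.begin(), v.end()));
  if (record_full) out["v_full"] = vfull;
  return out;
}
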