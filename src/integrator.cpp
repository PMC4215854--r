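// Compartmental conductance-based integrator.
//
// Crank-Nicolson on the cable/axial terms with staggered exponential gate
// updates; tree-ordered (Hines) direct solve of the tridiagonal-on-a-tree
// linear system.  Units: mV, ms, pA, nS, pF, mM.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Gate {
  int chan;        // owning channel index
  double exponent;
  int type;        // 0 = voltage, 1 = calcium (Hill)
  // voltage gate params
  double vh, k;                      // steady state Boltzmann
  double tmin, tamp, tv1, k1, tv2, k2;  // tau(V) = tmin + tamp/(e1+e2)
  // calcium gate params
  double kd, hill, tau;
  // lookup tables (voltage gates)
  std::vector<double> tab_inf, tab_exp;
};

const double V_LO = -150.0, V_HI = 100.0, V_STEP = 0.05;

inline double boltz(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vh) / k));
}

inline double tau_bell(const Gate &g, double v) {
  if (g.tamp <= 0.0) return g.tmin;
  double e1 = std::exp((v - g.tv1) / g.k1);
  double e2 = std::exp(-(v - g.tv2) / g.k2);
  return g.tmin + g.tamp / (e1 + e2);
}

inline double powi(double x, double p) {
  if (p == 1.0) return x;
  if (p == 2.0) return x * x;
  if (p == 3.0) return x * x * x;
  if (p == 4.0) { double x2 = x * x; return x2 * x2; }
  return std::pow(x, p);
}

} // namespace

// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(List cable, List proto) {
  // ---- cable geometry / passive ----
  IntegerVector parent = cable["parent"];        // 0-based, -1 at root
  NumericVector g_ax   = cable["g_ax"];          // nS, comp <-> parent
  NumericVector cm     = cable["cm"];            // pF
  NumericVector g_pas  = cable["g_pas"];         // nS
  NumericVector g_kl   = cable["g_kl"];          // nS
  double e_pas = as<double>(cable["e_pas"]);
  double e_k   = as<double>(cable["e_k"]);
  NumericMatrix gdens  = cable["g_chan"];        // ncomp x nchan, nS
  List channels        = cable["channels"];
  NumericVector ca_phi = cable["ca_phi"];        // mM / (pA * ms)
  double tau_ca  = as<double>(cable["tau_ca"]);
  double ca_rest = as<double>(cable["ca_rest"]);

  const int ncomp = parent.size();
  const int nchan = channels.size();

  // ---- protocol ----
  double t_total = as<double>(proto["t_total"]);
  double dt      = as<double>(proto["dt"]);
  double dt_save = as<double>(proto["dt_save"]);
  NumericMatrix inj = proto["inj"];              // comp(1-based), t0, t1, amp
  List vc = proto["vc"];
  bool vc_on = as<bool>(vc["on"]);
  int vc_comp = vc_on ? as<int>(vc["comp"]) - 1 : 0;
  double vc_level = vc_on ? as<double>(vc["level"]) : 0.0;
  double vc_g = vc_on ? as<double>(vc["g_clamp"]) : 0.0;
  IntegerVector record = proto["record"];        // 1-based comp indices
  double v_init = as<double>(proto["v_init"]);

  if (dt <= 0 || dt_save < dt) stop("invalid dt/dt_save");

  // ---- channels -> flat gate list ----
  std::vector<Gate> gates;
  std::vector<double> erev(nchan);
  std::vector<int> is_ca(nchan);
  std::vector<int> gate_from(nchan), gate_n(nchan);
  for (int c = 0; c < nchan; ++c) {
    List ch = channels[c];
    erev[c] = as<double>(ch["erev"]);
    is_ca[c] = as<bool>(ch["ca_current"]) ? 1 : 0;
    List gl = ch["gates"];
    gate_from[c] = gates.size();
    gate_n[c] = gl.size();
    for (int j = 0; j < gl.size(); ++j) {
      List gd = gl[j];
      Gate g;
      g.chan = c;
      g.exponent = as<double>(gd["exponent"]);
      g.type = as<int>(gd["type"]);
      if (g.type == 0) {
        g.vh = as<double>(gd["vh"]);   g.k  = as<double>(gd["k"]);
        g.tmin = as<double>(gd["tmin"]); g.tamp = as<double>(gd["tamp"]);
        g.tv1 = as<double>(gd["tv1"]); g.k1 = as<double>(gd["k1"]);
        g.tv2 = as<double>(gd["tv2"]); g.k2 = as<double>(gd["k2"]);
        int nt = (int)((V_HI - V_LO) / V_STEP) + 2;
        g.tab_inf.resize(nt);
        g.tab_exp.resize(nt);
        for (int t = 0; t < nt; ++t) {
          double v = V_LO + t * V_STEP;
          g.tab_inf[t] = boltz(v, g.vh, g.k);
          g.tab_exp[t] = std::exp(-dt / tau_bell(g, v));
        }
      } else {
        g.kd = as<double>(gd["kd"]); g.hill = as<double>(gd["hill"]);
        g.tau = as<double>(gd["tau"]);
      }
      gates.push_back(g);
    }
  }
  const int ngates = gates.size();
  std::vector<double> ca_exp(1, std::exp(-dt / tau_ca));

  // per-channel active compartments (non-zero maximal conductance)
  std::vector<std::vector<int>> active(nchan);
  for (int c = 0; c < nchan; ++c)
    for (int i = 0; i < ncomp; ++i)
      if (gdens(i, c) > 0.0) active[c].push_back(i);

  // ---- state ----
  std::vector<double> V(ncomp, v_init);
  std::vector<double> ca(ncomp, ca_rest);
  std::vector<std::vector<double>> gs(ngates, std::vector<double>(ncomp));
  for (int gidx = 0; gidx < ngates; ++gidx) {
    Gate &g = gates[gidx];
    for (int i = 0; i < ncomp; ++i) {
      if (g.type == 0) gs[gidx][i] = boltz(v_init, g.vh, g.k);
      else {
        double cr = powi(ca_rest / g.kd, g.hill);
        gs[gidx][i] = cr / (1.0 + cr);
      }
    }
  }

  // ---- output buffers ----
  const int nstep = (int)std::round(t_total / dt);
  const int save_every = (int)std::round(dt_save / dt);
  const int nsave = nstep / save_every + 1;
  NumericMatrix out(nsave, record.size());
  NumericVector out_t(nsave);
  NumericVector out_iclamp(vc_on ? nsave : 1);
  for (int r = 0; r < record.size(); ++r) out(0, r) = V[record[r] - 1];
  out_t[0] = 0.0;
  if (vc_on) out_iclamp[0] = vc_g * (vc_level - V[vc_comp]);

  // work arrays for the Hines solve
  std::vector<double> d(ncomp), b(ncomp), gax_sum(ncomp, 0.0);
  for (int i = 1; i < ncomp; ++i) {
    gax_sum[i] += g_ax[i];
    gax_sum[parent[i]] += g_ax[i];
  }
  std::vector<double> Gtot(ncomp), GE(ncomp), Iinj(ncomp), ica(ncomp);

  const int ninj = inj.nrow();
  int isave = 1;

  for (int step = 0; step < nstep; ++step) {
    double t = step * dt;

    // 1. gate update (exponential, V at t) on active compartments only
    for (int gidx = 0; gidx < ngates; ++gidx) {
      Gate &g = gates[gidx];
      std::vector<double> &x = gs[gidx];
      const std::vector<int> &act = active[g.chan];
      if (g.type == 0) {
        for (int a = 0; a < (int)act.size(); ++a) {
          int i = act[a];
          double v = V[i];
          if (v < V_LO) v = V_LO;
          if (v > V_HI) v = V_HI;
          double fi = (v - V_LO) / V_STEP;
          int i0 = (int)fi;
          double w = fi - i0;
          double xinf = g.tab_inf[i0] * (1 - w) + g.tab_inf[i0 + 1] * w;
          double xexp = g.tab_exp[i0] * (1 - w) + g.tab_exp[i0 + 1] * w;
          x[i] = xinf + (x[i] - xinf) * xexp;
        }
      } else {
        double ex = std::exp(-dt / g.tau);
        for (int a = 0; a < (int)act.size(); ++a) {
          int i = act[a];
          double cr = powi(ca[i] / g.kd, g.hill);
          double xinf = cr / (1.0 + cr);
          x[i] = xinf + (x[i] - xinf) * ex;
        }
      }
    }

    // 2. conductances and driving terms
    for (int i = 0; i < ncomp; ++i) {
      Gtot[i] = g_pas[i] + g_kl[i];
      GE[i] = g_pas[i] * e_pas + g_kl[i] * e_k;
      Iinj[i] = 0.0;
      ica[i] = 0.0;
    }
    for (int c = 0; c < nchan; ++c) {
      const std::vector<int> &act = active[c];
      for (int a = 0; a < (int)act.size(); ++a) {
        int i = act[a];
        double gmax = gdens(i, c);
        double open = 1.0;
        for (int j = 0; j < gate_n[c]; ++j) {
          Gate &g = gates[gate_from[c] + j];
          open *= powi(gs[gate_from[c] + j][i], g.exponent);
        }
        double gk = gmax * open;
        Gtot[i] += gk;
        GE[i] += gk * erev[c];
        if (is_ca[c]) ica[i] += gk * (V[i] - erev[c]); // pA, inward < 0
      }
    }

    // 3. calcium pool (exponential toward instantaneous equilibrium)
    for (int i = 0; i < ncomp; ++i) {
      if (ca_phi[i] > 0.0) {
        double ca_inf = ca_rest - ca_phi[i] * tau_ca * ica[i];
        if (ca_inf < 0.0) ca_inf = 0.0;
        ca[i] = ca_inf + (ca[i] - ca_inf) * ca_exp[0];
      }
    }

    // 4. injected currents active on (t, t+dt]
    double tm = t + 0.5 * dt;
    for (int r = 0; r < ninj; ++r) {
      if (tm >= inj(r, 1) && tm < inj(r, 2)) Iinj[(int)inj(r, 0) - 1] += inj(r, 3);
    }

    // 5. Crank-Nicolson assembly
    for (int i = 0; i < ncomp; ++i) {
      double gc = (vc_on && i == vc_comp) ? vc_g : 0.0;
      double diag_m = 0.5 * (Gtot[i] + gc + gax_sum[i]);
      d[i] = cm[i] / dt + diag_m;
      b[i] = (cm[i] / dt - diag_m) * V[i] + GE[i] + Iinj[i] + gc * vc_level;
    }
    for (int i = 1; i < ncomp; ++i) {
      int p = parent[i];
      b[i] += 0.5 * g_ax[i] * V[p];
      b[p] += 0.5 * g_ax[i] * V[i];
    }
    // Hines elimination (children ordered after parents)
    for (int i = ncomp - 1; i >= 1; --i) {
      int p = parent[i];
      double off = -0.5 * g_ax[i];
      double f = off / d[i];
      d[p] -= f * off;
      b[p] -= f * b[i];
    }
    V[0] = b[0] / d[0];
    for (int i = 1; i < ncomp; ++i) {
      double off = -0.5 * g_ax[i];
      V[i] = (b[i] - off * V[parent[i]]) / d[i];
    }

    if (V[0] > 200.0 || V[0] < -200.0 || !std::isfinite(V[0]))
      stop("numerical instability (|V| > 200 mV) at t = %.3f ms; dt = %g ms",
           t, dt);

    // 6. save
    if ((step + 1) % save_every == 0 && isave < nsave) {
      for (int r = 0; r < record.size(); ++r) out(isave, r) = V[record[r] - 1];
      out_t[isave] = (step + 1) * dt;
      if (vc_on) out_iclamp[isave] = vc_g * (vc_level - V[vc_comp]);
      ++isave;
    }
  }

  List res = List::create(_["t"] = out_t, _["v"] = out,
                          _["i_clamp"] = vc_on ? out_iclamp : NumericVector(0));
  return res;
}
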