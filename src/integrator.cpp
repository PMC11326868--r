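// Backward-Euler cable-equation integrator for a branched neuron with
// auditory-brainstem voltage-gated channels (high- and low-threshold K+,
// fast transient Na+, HCN) and double-exponential conductance synapses.
//
// Units follow the NEURON convention: mV, ms, uS, uF, nA.  Segment i is
// coupled to parent[i] (parent[i] < i, root = -1) by axial conductance
// g_axial[i] (uS).  The voltage step is implicit (unconditionally stable);
// gating states advance by exact exponential relaxation against the
// voltage at the start of the step (staggered scheme).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct InfTau { double inf, tau; };

// Kinetics of the classic ventral-cochlear-nucleus channel set
// (Rothman & Manis 2003 rate equations, defined at 22 C), divided by a
// Q10 rate factor `q` supplied by the caller.

inline InfTau kht_n(double v, double q) {
  InfTau g;
  g.inf = std::pow(1.0 + std::exp(-(v + 15.0) / 5.0), -0.5);
  g.tau = (100.0 / (11.0 * std::exp((v + 60.0) / 24.0) +
                    21.0 * std::exp(-(v + 60.0) / 23.0)) + 0.7) / q;
  return g;
}
inline InfTau kht_p(double v, double q) {
  InfTau g;
  g.inf = 1.0 / (1.0 + std::exp(-(v + 23.0) / 6.0));
  g.tau = (100.0 / (4.0 * std::exp((v + 60.0) / 32.0) +
                    5.0 * std::exp(-(v + 60.0) / 22.0)) + 5.0) / q;
  return g;
}
inline InfTau klt_w(double v, double q, double wscale) {
  InfTau g;
  g.inf = std::pow(1.0 + std::exp(-(v + 48.0) / 6.0), -0.25);
  g.tau = (100.0 / (6.0 * std::exp((v + 60.0) / 6.0) +
                    16.0 * std::exp(-(v + 60.0) / 45.0)) + 1.5) / (q * wscale);
  return g;
}
inline InfTau klt_z(double v, double q) {
  InfTau g;
  g.inf = 0.5 + 0.5 / (1.0 + std::exp((v + 71.0) / 10.0));
  g.tau = (1000.0 / (std::exp((v + 60.0) / 20.0) +
                     std::exp(-(v + 60.0) / 8.0)) + 50.0) / q;
  return g;
}
inline InfTau na_m(double v, double q) {
  InfTau g;
  g.inf = 1.0 / (1.0 + std::exp(-(v + 38.0) / 7.0));
  g.tau = (10.0 / (5.0 * std::exp((v + 60.0) / 18.0) +
                   36.0 * std::exp(-(v + 60.0) / 25.0)) + 0.04) / q;
  return g;
}
inline InfTau na_h(double v, double q) {
  InfTau g;
  g.inf = 1.0 / (1.0 + std::exp((v + 65.0) / 6.0));
  g.tau = (100.0 / (7.0 * std::exp((v + 60.0) / 11.0) +
                    10.0 * std::exp(-(v + 60.0) / 25.0)) + 0.6) / q;
  return g;
}
inline InfTau ih_r(double v, double q) {
  InfTau g;
  g.inf = 1.0 / (1.0 + std::exp((v + 76.0) / 7.0));
  g.tau = (10000.0 / (237.0 * std::exp((v + 60.0) / 12.0) +
                      17.0 * std::exp(-(v + 60.0) / 14.0)) + 25.0) / q;
  return g;
}

inline double relax(double x, double inf, double tau, double dt) {
  return inf + (x - inf) * std::exp(-dt / tau);
}

} // namespace

// [[Rcpp::export]]
List simulate_cable(IntegerVector parent,     // 0-based, parent[0] == -1
                    NumericVector g_axial,    // uS, link i <-> parent[i]
                    NumericVector cm,         // nF per segment (nF/ms = uS)
                    NumericMatrix gbar,       // n x 5: leak, kht, klt, na, ih (uS)
                    NumericVector e_leak,     // mV per segment
                    double e_k, double e_na, double e_h,
                    double q_rate, double klt_wscale,
                    NumericVector na_mshift, // mV per segment: Na activation shift
                    NumericVector na_hshift, // mV per segment: Na inactivation shift
                    NumericMatrix syn,        // k x 6: seg, onset, tau_r, tau_d, gmax*norm, e_rev
                    NumericVector i_bias,     // nA per segment, constant
                    double dt, int n_steps,
                    double v_init,
                    Nullable<List> state0 = R_NilValue,
                    bool record_all = false) {
  const int n = parent.size();
  const int ns = syn.nrow();

  NumericVector V(n, v_init);
  NumericVector gn(n), gp(n), gw(n), gz(n), gm(n), gh_(n), gr(n);
  NumericVector synA(ns, 0.0), synB(ns, 0.0);

  if (state0.isNotNull()) {
    List s(state0);
    V = clone(as<NumericVector>(s["v"]));
    gn = clone(as<NumericVector>(s["n"])); gp = clone(as<NumericVector>(s["p"]));
    gw = clone(as<NumericVector>(s["w"])); gz = clone(as<NumericVector>(s["z"]));
    gm = clone(as<NumericVector>(s["m"])); gh_ = clone(as<NumericVector>(s["h"]));
    gr = clone(as<NumericVector>(s["r"]));
  } else {
    for (int i = 0; i < n; ++i) {
      gn[i] = kht_n(v_init, q_rate).inf;  gp[i] = kht_p(v_init, q_rate).inf;
      gw[i] = klt_w(v_init, q_rate, klt_wscale).inf; gz[i] = klt_z(v_init, q_rate).inf;
      gm[i] = na_m(v_init - na_mshift[i], q_rate).inf;
      gh_[i] = na_h(v_init - na_hshift[i], q_rate).inf;
      gr[i] = ih_r(v_init, q_rate).inf;
    }
  }

  // synapse onset step indices and per-event exp decay factors
  std::vector<int> onset_step(ns);
  std::vector<double> decA(ns), decB(ns);
  for (int s = 0; s < ns; ++s) {
    onset_step[s] = (int)std::lround(syn(s, 1) / dt);
    decA[s] = std::exp(-dt / syn(s, 2));
    decB[s] = std::exp(-dt / syn(s, 3));
  }

  NumericVector vtrace(n_steps + 1);
  NumericMatrix vall;
  if (record_all) vall = NumericMatrix(n_steps + 1, n);
  vtrace[0] = V[0];
  if (record_all) for (int i = 0; i < n; ++i) vall(0, i) = V[i];

  std::vector<double> d(n), b(n), ga(n);
  for (int i = 0; i < n; ++i) ga[i] = (i > 0) ? g_axial[i] : 0.0;

  for (int step = 1; step <= n_steps; ++step) {
    // 1. gating update against current V
    for (int i = 0; i < n; ++i) {
      const double v = V[i];
      if (gbar(i, 1) > 0) {
        InfTau a = kht_n(v, q_rate); gn[i] = relax(gn[i], a.inf, a.tau, dt);
        InfTau c = kht_p(v, q_rate); gp[i] = relax(gp[i], c.inf, c.tau, dt);
      }
      if (gbar(i, 2) > 0) {
        InfTau a = klt_w(v, q_rate, klt_wscale); gw[i] = relax(gw[i], a.inf, a.tau, dt);
        InfTau c = klt_z(v, q_rate); gz[i] = relax(gz[i], c.inf, c.tau, dt);
      }
      if (gbar(i, 3) > 0) {
        InfTau a = na_m(v - na_mshift[i], q_rate);
        gm[i] = relax(gm[i], a.inf, a.tau, dt);
        InfTau c = na_h(v - na_hshift[i], q_rate);
        gh_[i] = relax(gh_[i], c.inf, c.tau, dt);
      }
      if (gbar(i, 4) > 0) {
        InfTau a = ih_r(v, q_rate); gr[i] = relax(gr[i], a.inf, a.tau, dt);
      }
    }

    // 2. synapse state update (exact exponential + onset increments)
    for (int s = 0; s < ns; ++s) {
      synA[s] *= decA[s];
      synB[s] *= decB[s];
      if (step == onset_step[s]) {
        synA[s] += syn(s, 4);
        synB[s] += syn(s, 4);
      }
    }

    // 3. assemble and solve the implicit voltage system (Hines order)
    for (int i = 0; i < n; ++i) {
      const double gl = gbar(i, 0);
      const double gkht = gbar(i, 1) * (0.85 * gn[i] * gn[i] + 0.15 * gp[i]);
      const double gklt = gbar(i, 2) * gw[i] * gw[i] * gw[i] * gw[i] * gz[i];
      const double gna  = gbar(i, 3) * gm[i] * gm[i] * gm[i] * gh_[i];
      const double gihc = gbar(i, 4) * gr[i];
      double gtot = gl + gkht + gklt + gna + gihc;
      double gesum = gl * e_leak[i] + (gkht + gklt) * e_k + gna * e_na + gihc * e_h;
      d[i] = cm[i] / dt + gtot;
      b[i] = cm[i] / dt * V[i] + gesum + i_bias[i];
    }
    for (int s = 0; s < ns; ++s) {
      const int seg = (int)syn(s, 0);
      const double g = synB[s] - synA[s];
      d[seg] += g;
      b[seg] += g * syn(s, 5);
    }
    for (int i = 1; i < n; ++i) {
      d[i] += ga[i];
      d[parent[i]] += ga[i];
    }
    for (int i = n - 1; i >= 1; --i) {        // eliminate towards root
      const double f = ga[i] / d[i];
      d[parent[i]] -= f * ga[i];
      b[parent[i]] += f * b[i];
    }
    V[0] = b[0] / d[0];
    for (int i = 1; i < n; ++i) V[i] = (b[i] + ga[i] * V[parent[i]]) / d[i];

    if (!R_finite(V[0]))
      stop("simulation diverged (non-finite somatic voltage) at t = %f ms",
           step * dt);
    vtrace[step] = V[0];
    if (record_all) for (int i = 0; i < n; ++i) vall(step, i) = V[i];
  }

  List state = List::create(_["v"] = V, _["n"] = gn, _["p"] = gp,
                            _["w"] = gw, _["z"] = gz, _["m"] = gm,
                            _["h"] = gh_, _["r"] = gr);
  List out = List::create(_["v_soma"] = vtrace, _["state"] = state);
  if (record_all) out["v_all"] = vall;
  return out;
}
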