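#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Single-compartment conductance model of a small/medium DRG sensory neuron:
//   C dV/dt = I_inj - gNa m^3 h (V-ENa) - gKdr n^4 (V-EK) - gA a^3 b (V-EK)
//             - gL (V-EL)
// Gates follow first-order kinetics dx/dt = (xinf(V) - x)/taux(V) with
// Boltzmann steady states and bell-shaped time constants.
// Units repo-wide: mV, pA, ms, pF, nS (pA = nS * mV).

struct Gate {
  double vh, k, tb, ta, tv, tw;
};

struct Pars {
  double C, gNa, gK, gA, gL, ENa, EK, EL;
  Gate g[5]; // m, h, n, a, b
};

static inline double xinf(const Gate &g, double V) {
  return 1.0 / (1.0 + std::exp(-(V - g.vh) / g.k));
}

static inline double xtau(const Gate &g, double V) {
  double z = (V - g.tv) / g.tw;
  return g.tb + g.ta * std::exp(-z * z);
}

static Pars unpack(const NumericVector &p) {
  if (p.size() != 38) stop("parameter vector must have length 38");
  Pars P;
  P.C = p[0]; P.gNa = p[1]; P.gK = p[2]; P.gA = p[3]; P.gL = p[4];
  P.ENa = p[5]; P.EK = p[6]; P.EL = p[7];
  for (int i = 0; i < 5; ++i) {
    P.g[i].vh = p[8 + 6 * i];
    P.g[i].k  = p[9 + 6 * i];
    P.g[i].tb = p[10 + 6 * i];
    P.g[i].ta = p[11 + 6 * i];
    P.g[i].tv = p[12 + 6 * i];
    P.g[i].tw = p[13 + 6 * i];
  }
  return P;
}

static inline double ionic(const Pars &P, const double *y) {
  double V = y[0], m = y[1], h = y[2], n = y[3], a = y[4], b = y[5];
  double INa = P.gNa * m * m * m * h * (V - P.ENa);
  double IK  = P.gK * n * n * n * n * (V - P.EK);
  double IA  = P.gA * a * a * a * b * (V - P.EK);
  double IL  = P.gL * (V - P.EL);
  return INa + IK + IA + IL;
}

static inline void deriv_cc(const Pars &P, const double *y, double Iinj,
                            double *dy) {
  dy[0] = (Iinj - ionic(P, y)) / P.C;
  for (int i = 0; i < 5; ++i) {
    double V = y[0];
    dy[1 + i] = (xinf(P.g[i], V) - y[1 + i]) / xtau(P.g[i], V);
  }
}

static inline void deriv_gates(const Pars &P, double V, const double *y,
                               double *dy) {
  for (int i = 0; i < 5; ++i)
    dy[i] = (xinf(P.g[i], V) - y[i]) / xtau(P.g[i], V);
}

// Total steady-state membrane current at voltage V with gates at xinf(V);
// used from R to locate the resting potential by root finding.
// [[Rcpp::export]]
double ss_current_cpp(NumericVector pars, double V) {
  Pars P = unpack(pars);
  double y[6];
  y[0] = V;
  for (int i = 0; i < 5; ++i) y[1 + i] = xinf(P.g[i], V);
  return ionic(P, y);
}

// [[Rcpp::export]]
NumericVector gate_inf_cpp(NumericVector pars, double V) {
  Pars P = unpack(pars);
  NumericVector out(5);
  for (int i = 0; i < 5; ++i) out[i] = xinf(P.g[i], V);
  out.attr("names") = CharacterVector::create("m", "h", "n", "a", "b");
  return out;
}

// Current clamp: RK4 at fixed dt over an injected-current waveform sampled
// at the same dt. The command is linearly interpolated at half steps.
// Returns the membrane-voltage trace aligned with i_cmd.
// [[Rcpp::export]]
NumericVector sim_cc_cpp(NumericVector pars, NumericVector i_cmd, double dt,
                         double v0) {
  Pars P = unpack(pars);
  int nT = i_cmd.size();
  NumericVector V(nT);
  double y[6], k1[6], k2[6], k3[6], k4[6], yt[6];
  y[0] = v0;
  for (int i = 0; i < 5; ++i) y[1 + i] = xinf(P.g[i], v0);
  V[0] = v0;
  for (int t = 0; t < nT - 1; ++t) {
    double I0 = i_cmd[t], I1 = i_cmd[t + 1], Ih = 0.5 * (I0 + I1);
    deriv_cc(P, y, I0, k1);
    for (int i = 0; i < 6; ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
    deriv_cc(P, yt, Ih, k2);
    for (int i = 0; i < 6; ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
    deriv_cc(P, yt, Ih, k3);
    for (int i = 0; i < 6; ++i) yt[i] = y[i] + dt * k3[i];
    deriv_cc(P, yt, I1, k4);
    for (int i = 0; i < 6; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if (!std::isfinite(y[0]))
      stop("membrane potential became non-finite at t = %f ms; "
           "unstable parameters or dt too large", (t + 1) * dt);
    V[t + 1] = y[0];
  }
  return V;
}

// Ideal voltage clamp: membrane voltage equals the command exactly; gate
// states are integrated under the commanded voltage and the recorded signal
// is the total membrane (ionic + leak) current.
// [[Rcpp::export]]
NumericVector sim_vc_cpp(NumericVector pars, NumericVector v_cmd, double dt) {
  Pars P = unpack(pars);
  int nT = v_cmd.size();
  NumericVector I(nT);
  double g[5], k1[5], k2[5], k3[5], k4[5], gt[5], y[6];
  for (int i = 0; i < 5; ++i) g[i] = xinf(P.g[i], v_cmd[0]);
  y[0] = v_cmd[0];
  for (int i = 0; i < 5; ++i) y[1 + i] = g[i];
  I[0] = ionic(P, y);
  for (int t = 0; t < nT - 1; ++t) {
    double V0 = v_cmd[t], V1 = v_cmd[t + 1], Vh = 0.5 * (V0 + V1);
    deriv_gates(P, V0, g, k1);
    for (int i = 0; i < 5; ++i) gt[i] = g[i] + 0.5 * dt * k1[i];
    deriv_gates(P, Vh, gt, k2);
    for (int i = 0; i < 5; ++i) gt[i] = g[i] + 0.5 * dt * k2[i];
    deriv_gates(P, Vh, gt, k3);
    for (int i = 0; i < 5; ++i) gt[i] = g[i] + dt * k3[i];
    deriv_gates(P, V1, gt, k4);
    for (int i = 0; i < 5; ++i) {
      g[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (!std::isfinite(g[i]))
        stop("gate state became non-finite during voltage clamp integration");
    }
    y[0] = V1;
    for (int i = 0; i < 5; ++i) y[1 + i] = g[i];
    I[t + 1] = ionic(P, y);
  }
  return I;
}
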