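#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Right-hand side of the five-state mass balance (C, G2, G, Xn, X).
// All model quantities are pre-resolved on the R side into plain doubles:
// lam is the surface-decay rate for this assay, K4 the concentrated
// xylan-hydrolysis constant, E2f the (non-adsorbing) beta-glucosidase pool.
struct Model {
  double k1r, k3r, K1iG2, K1iG, K1iX, K3iG2, K3iG, K3iX;
  double k2r, K2m, K2iG, K2iX;
  double K4, K4iX, kS;
  double lam;
  double E1T, E2f, L0, C0;
  double ea, eb, ec, ka, kb, kc; // exp(a + b*conv + c*conv^2) for Emax / Kp
  double emaxL, kpL;             // lignin (non-productive) adsorption
  bool dynamicS;                 // S(t) = C + Xn + L0, else fixed S0
  double S0;
};

// Free cellulase from the closed Langmuir mass balance
// E1T = E1f + Emax*Kp*E1f*S / ((1 + Kp*E1f) * 1000); positive quadratic
// root written in the cancellation-free form.
static inline double partition_E1f(double E1T, double S, double Emax, double Kp) {
  if (E1T <= 0.0) return 0.0;
  double A = Emax * S / 1000.0; // adsorption capacity, mg protein/mL
  if (Kp <= 0.0 || A <= 0.0) return E1T;
  double b = 1.0 + Kp * (A - E1T);
  return 2.0 * E1T / (b + std::sqrt(b * b + 4.0 * Kp * E1T));
}

static inline void rhs(const Model& m, double t, const double y[5], double dy[5]) {
  double C  = y[0] > 0.0 ? y[0] : 0.0;
  double G2 = y[1] > 0.0 ? y[1] : 0.0;
  double G  = y[2] > 0.0 ? y[2] : 0.0;
  double Xn = y[3] > 0.0 ? y[3] : 0.0;
  double X  = y[4] > 0.0 ? y[4] : 0.0;

  double conv = m.C0 > 0.0 ? 100.0 * (m.C0 - C) / m.C0 : 0.0;
  if (conv < 0.0) conv = 0.0;
  if (conv > 100.0) conv = 100.0;
  double Emax = std::exp(m.ea + m.eb * conv + m.ec * conv * conv);
  double Kp   = std::exp(m.ka + m.kb * conv + m.kc * conv * conv);

  double S = m.dynamicS ? (C + Xn + m.L0) : m.S0;
  double E1f = partition_E1f(m.E1T, S, Emax, Kp);
  double E1b = m.E1T - E1f;
  double E1bL = 0.0;
  if (m.emaxL > 0.0 && m.kpL > 0.0)
    E1bL = m.emaxL * m.kpL * E1f * m.L0 / ((1.0 + m.kpL * E1f) * 1000.0);
  double E1bC = E1b - E1bL;
  if (E1bC < 0.0) E1bC = 0.0;

  double decay = std::exp(-m.lam * t);
  double r1 = m.k1r * E1bC * C * decay /
              (1.0 + G2 / m.K1iG2 + G / m.K1iG + X / m.K1iX);
  double r2 = m.k2r * m.E2f * G2 /
              (m.K2m * (1.0 + G / m.K2iG + X / m.K2iX) + G2);
  double r3 = m.k3r * E1bC * C * decay /
              (1.0 + G2 / m.K3iG2 + G / m.K3iG + X / m.K3iX);
  double r4 = m.K4 * Xn * Xn / ((1.0 + X / m.K4iX) * (m.kS + Xn));

  dy[0] = -r1 - r3;
  dy[1] = 1.056 * r1 - r2;
  dy[2] = 1.053 * r2 + 1.111 * r3;
  dy[3] = -r4;
  dy[4] = 1.136 * r4;
}

static Model model_from_list(const List& ml) {
  Model m;
  m.k1r = ml["k1r"];   m.k3r = ml["k3r"];
  m.K1iG2 = ml["K1iG2"]; m.K1iG = ml["K1iG"]; m.K1iX = ml["K1iX"];
  m.K3iG2 = ml["K3iG2"]; m.K3iG = ml["K3iG"]; m.K3iX = ml["K3iX"];
  m.k2r = ml["k2r"];   m.K2m = ml["K2m"];
  m.K2iG = ml["K2iG"]; m.K2iX = ml["K2iX"];
  m.K4 = ml["K4"];     m.K4iX = ml["K4iX"]; m.kS = ml["kS"];
  m.lam = ml["lam"];
  m.E1T = ml["E1T"];   m.E2f = ml["E2f"];
  m.L0 = ml["L0"];     m.C0 = ml["C0"];
  m.ea = ml["ea"]; m.eb = ml["eb"]; m.ec = ml["ec"];
  m.ka = ml["ka"]; m.kb = ml["kb"]; m.kc = ml["kc"];
  m.emaxL = ml["emaxL"]; m.kpL = ml["kpL"];
  m.dynamicS = as<bool>(ml["dynamicS"]);
  m.S0 = ml["S0"];
  return m;
}

// Single RHS evaluation, used by the R-level derivative API and the
// R-vs-C++ consistency tests.
// [[Rcpp::export(name = ".rhs_cpp")]]
NumericVector rhs_cpp(double t, NumericVector y, List model) {
  Model m = model_from_list(model);
  double yy[5], dy[5];
  for (int i = 0; i < 5; ++i) yy[i] = y[i];
  rhs(m, t, yy, dy);
  NumericVector out(5);
  for (int i = 0; i < 5; ++i) out[i] = dy[i];
  return out;
}

// Classical RK4 over a prescribed time grid; states recorded at the
// report indices (1-based positions into grid). States are clipped at
// zero after each step; the largest clip magnitude is returned so the
// caller can log drift.
// [[Rcpp::export(name = ".rk4_cpp")]]
List rk4_cpp(NumericVector y0, NumericVector grid, IntegerVector report_idx,
             List model) {
  Model m = model_from_list(model);
  int n = grid.size(), nrep = report_idx.size();
  NumericMatrix out(nrep, 5);
  double y[5], k1[5], k2[5], k3[5], k4[5], tmp[5];
  for (int i = 0; i < 5; ++i) y[i] = y0[i];
  double max_clip = 0.0;
  int ri = 0;
  if (ri < nrep && report_idx[ri] == 1) {
    for (int j = 0; j < 5; ++j) out(ri, j) = y[j];
    ++ri;
  }
  for (int i = 0; i + 1 < n; ++i) {
    double t = grid[i], h = grid[i + 1] - t;
    rhs(m, t, y, k1);
    for (int j = 0; j < 5; ++j) tmp[j] = y[j] + 0.5 * h * k1[j];
    rhs(m, t + 0.5 * h, tmp, k2);
    for (int j = 0; j < 5; ++j) tmp[j] = y[j] + 0.5 * h * k2[j];
    rhs(m, t + 0.5 * h, tmp, k3);
    for (int j = 0; j < 5; ++j) tmp[j] = y[j] + h * k3[j];
    rhs(m, t + h, tmp, k4);
    for (int j = 0; j < 5; ++j) {
      y[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      if (y[j] < 0.0) {
        if (-y[j] > max_clip) max_clip = -y[j];
        y[j] = 0.0;
      }
      if (!std::isfinite(y[j]))
        stop("non-finite state at t = %f (component %d)", grid[i + 1], j + 1);
    }
    if (ri < nrep && report_idx[ri] == i + 2) {
      for (int j = 0; j < 5; ++j) out(ri, j) = y[j];
      ++ri;
    }
  }
  return List::create(_["states"] = out, _["max_clip"] = max_clip);
}
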