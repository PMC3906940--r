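// Binary-state speciation-extinction (BiSSE) likelihood core.
//
// State along a branch: y = (E0, E1, D0, D1) with
//   dEi/dt = mui - (lai + mui + qij) Ei + lai Ei^2 + qij Ej
//   dDi/dt = -(lai + mui + qij) Di + qij Dj + 2 lai Ei Di
// integrated backwards in time from the tips (t = time before present).
// Branch propagation uses an adaptive Cash-Karp Runge-Kutta 4(5) scheme;
// D is renormalised whenever it becomes small, with the log-scaler
// accumulated, so deep trees do not underflow.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct BisseP {
  double la0, la1, mu0, mu1, q01, q10;
};

static inline void deriv(const double* y, double* dy, const BisseP& p) {
  const double E0 = y[0], E1 = y[1], D0 = y[2], D1 = y[3];
  dy[0] = p.mu0 - (p.la0 + p.mu0 + p.q01) * E0 + p.la0 * E0 * E0 + p.q01 * E1;
  dy[1] = p.mu1 - (p.la1 + p.mu1 + p.q10) * E1 + p.la1 * E1 * E1 + p.q10 * E0;
  dy[2] = -(p.la0 + p.mu0 + p.q01) * D0 + p.q01 * D1 + 2.0 * p.la0 * E0 * D0;
  dy[3] = -(p.la1 + p.mu1 + p.q10) * D1 + p.q10 * D0 + 2.0 * p.la1 * E1 * D1;
}

// One Cash-Karp step of size h from y; fills y5 (5th order) and err.
static inline void ck_step(const double* y, double h, const BisseP& p,
                           double* y5, double* err) {
  static const double a21 = 1.0 / 5,
    a31 = 3.0 / 40, a32 = 9.0 / 40,
    a41 = 3.0 / 10, a42 = -9.0 / 10, a43 = 6.0 / 5,
    a51 = -11.0 / 54, a52 = 5.0 / 2, a53 = -70.0 / 27, a54 = 35.0 / 27,
    a61 = 1631.0 / 55296, a62 = 175.0 / 512, a63 = 575.0 / 13824,
    a64 = 44275.0 / 110592, a65 = 253.0 / 4096;
  static const double b1 = 37.0 / 378, b3 = 250.0 / 621, b4 = 125.0 / 594,
    b6 = 512.0 / 1771;
  static const double d1 = b1 - 2825.0 / 27648, d3 = b3 - 18575.0 / 48384,
    d4 = b4 - 13525.0 / 55296, d5 = -277.0 / 14336, d6 = b6 - 1.0 / 4;
  double k1[4], k2[4], k3[4], k4[4], k5[4], k6[4], yt[4];
  deriv(y, k1, p);
  for (int i = 0; i < 4; ++i) yt[i] = y[i] + h * a21 * k1[i];
  deriv(yt, k2, p);
  for (int i = 0; i < 4; ++i) yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
  deriv(yt, k3, p);
  for (int i = 0; i < 4; ++i)
    yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
  deriv(yt, k4, p);
  for (int i = 0; i < 4; ++i)
    yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
  deriv(yt, k5, p);
  for (int i = 0; i < 4; ++i)
    yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                        a64 * k4[i] + a65 * k5[i]);
  deriv(yt, k6, p);
  for (int i = 0; i < 4; ++i) {
    y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b6 * k6[i]);
    err[i] = h * (d1 * k1[i] + d3 * k3[i] + d4 * k4[i] + d5 * k5[i] + d6 * k6[i]);
  }
}

// Integrate y over a branch of length len; returns accumulated log-scaler
// applied to (D0, D1). Throws on step-size collapse.
static double propagate(double* y, double len, const BisseP& p,
                        double rtol, double atol) {
  if (len <= 0.0) return 0.0;
  double t = 0.0, logsc = 0.0;
  double rate = p.la0 + p.la1 + p.mu0 + p.mu1 + p.q01 + p.q10;
  double h = std::min(len, 0.5 / std::max(rate, 1e-8));
  int iter = 0;
  while (t < len) {
    if (++iter > 1000000) stop("BiSSE ODE failure: step limit reached");
    if (h > len - t) h = len - t;
    double y5[4], err[4];
    ck_step(y, h, p, y5, err);
    double emax = 0.0;
    for (int i = 0; i < 4; ++i) {
      double sc = atol + rtol * std::fabs(y5[i]);
      double e = std::fabs(err[i]) / sc;
      if (e > emax) emax = e;
    }
    bool bad = !std::isfinite(emax);
    for (int i = 0; i < 4 && !bad; ++i) bad = !std::isfinite(y5[i]);
    if (!bad && emax <= 1.0) {
      t += h;
      for (int i = 0; i < 4; ++i) y[i] = y5[i];
      // keep E in [0,1], D non-negative (tolerate integrator jitter)
      for (int i = 0; i < 2; ++i) {
        if (y[i] < 0.0) { if (y[i] < -1e-6) stop("BiSSE ODE failure: E < 0"); y[i] = 0.0; }
        if (y[i] > 1.0) { if (y[i] > 1.0 + 1e-6) stop("BiSSE ODE failure: E > 1"); y[i] = 1.0; }
      }
      for (int i = 2; i < 4; ++i) {
        if (y[i] < 0.0) { if (y[i] < -1e-8) stop("BiSSE ODE failure: D < 0"); y[i] = 0.0; }
      }
      double s = y[2] + y[3];
      if (s > 0.0 && s < 1e-20) { y[2] /= s; y[3] /= s; logsc += std::log(s); }
      double fac = (emax > 0.0) ? 0.9 * std::pow(emax, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = bad ? 0.1 : std::max(0.2, 0.9 * std::pow(emax, -0.25));
      h *= fac;
      if (h < 1e-14 * len) stop("BiSSE ODE failure: step size underflow");
    }
  }
  return logsc;
}

// [[Rcpp::export(name = ".bisse_branch_cpp")]]
NumericVector bisse_branch_cpp(NumericVector y0, double len,
                               NumericVector pars, double rtol = 1e-8) {
  BisseP p = {pars[0], pars[1], pars[2], pars[3], pars[4], pars[5]};
  double y[4] = {y0[0], y0[1], y0[2], y0[3]};
  double logsc = propagate(y, len, p, rtol, 1e-10);
  NumericVector out = NumericVector::create(y[0], y[1], y[2], y[3]);
  out.attr("log_scale") = logsc;
  return out;
}

// edge: 2-column matrix in postorder (children rows before parent rows),
// 1-based node ids as in ape; tips are 1..n_tip, root is n_tip + 1.
// tip_states: 0/1 per tip. root_mode: 0 = weights proportional to root D,
// 1 = equal weights, 2 = fixed state 0, 3 = fixed state 1.
// [[Rcpp::export(name = ".bisse_loglik_cpp")]]
double bisse_loglik_cpp(IntegerMatrix edge, NumericVector edge_length,
                        int n_tip, IntegerVector tip_states,
                        NumericVector pars, int root_mode = 0,
                        bool condition_surv = false, double rtol = 1e-8) {
  BisseP p = {pars[0], pars[1], pars[2], pars[3], pars[4], pars[5]};
  const double la[2] = {p.la0, p.la1};
  int n_node = n_tip + (int)edge.nrow() / 2 + 1;   // upper bound on ids
  std::vector<double> E0(n_node + 1, 0.0), E1(n_node + 1, 0.0);
  std::vector<double> D0(n_node + 1, 1.0), D1(n_node + 1, 1.0);
  std::vector<int> nseen(n_node + 1, 0);
  double loglik = 0.0;

  for (int r = 0; r < edge.nrow(); ++r) {
    int par = edge(r, 0), ch = edge(r, 1);
    if (par > n_node || ch > n_node) stop("invalid edge matrix");
    double y[4];
    if (ch <= n_tip) {
      int st = tip_states[ch - 1];
      if (st != 0 && st != 1) stop("tip states must be 0 or 1");
      y[0] = 0.0; y[1] = 0.0;             // complete extant sampling
      y[2] = (st == 0) ? 1.0 : 0.0;
      y[3] = (st == 1) ? 1.0 : 0.0;
    } else {
      // internal child: its children have been merged; apply speciation
      y[0] = E0[ch]; y[1] = E1[ch];
      y[2] = D0[ch] * la[0];
      y[3] = D1[ch] * la[1];
    }
    // per-branch renormalisation of D
    double s = y[2] + y[3];
    if (s <= 0.0) stop("BiSSE failure: zero likelihood density at a node");
    y[2] /= s; y[3] /= s;
    loglik += std::log(s);
    loglik += propagate(y, edge_length[r], p, rtol, 1e-10);
    if (nseen[par] == 0) {
      E0[par] = y[0]; E1[par] = y[1];
      D0[par] = y[2]; D1[par] = y[3];
    } else {
      E0[par] = 0.5 * (E0[par] + y[0]);
      E1[par] = 0.5 * (E1[par] + y[1]);
      D0[par] *= y[2]; D1[par] *= y[3];
    }
    nseen[par] += 1;
  }

  int root = n_tip + 1;
  if (nseen[root] != 2) stop("root must be binary");
  double dr[2] = {D0[root] * la[0], D1[root] * la[1]};
  double er[2] = {E0[root], E1[root]};
  if (condition_surv) {
    for (int i = 0; i < 2; ++i) {
      double c = la[i] * (1.0 - er[i]) * (1.0 - er[i]);
      if (c <= 0.0) stop("survival conditioning undefined (E = 1 or lambda = 0)");
      dr[i] /= c;
    }
  }
  double w0, w1;
  switch (root_mode) {
  case 0: {
    double s = dr[0] + dr[1];
    if (s <= 0.0) stop("BiSSE failure: zero root likelihood");
    w0 = dr[0] / s; w1 = dr[1] / s;
    break;
  }
  case 1: w0 = w1 = 0.5; break;
  case 2: w0 = 1.0; w1 = 0.0; break;
  case 3: w0 = 0.0; w1 = 1.0; break;
  default: stop("unknown root mode");
  }
  double L = w0 * dr[0] + w1 * dr[1];
  if (L <= 0.0) return R_NegInf;
  return loglik + std::log(L);
}
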