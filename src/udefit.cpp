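// Compiled numerics: feed-forward ANN (forward pass + analytic Jacobians)
// and a Dormand-Prince 5(4) integrator with forward sensitivities for the
// glycolysis ODE/UDE family. Everything here is deliberately dependency-free
// so the package compiles with plain Rcpp.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double NORM_C = 1e-20; // additive constant inside the input log

// ---------------------------------------------------------------------------
// MLP
// ---------------------------------------------------------------------------

// activation ids: 0 = tanh, 1 = relu, 2 = gaussian rbf, 3 = swish
static inline double act_f(double z, int act) {
  switch (act) {
  case 0: return std::tanh(z);
  case 1: return z > 0.0 ? z : 0.0;
  case 2: return std::exp(-z * z);
  default: return z / (1.0 + std::exp(-z)); // swish
  }
}

static inline double act_df(double z, int act) {
  switch (act) {
  case 0: { double t = std::tanh(z); return 1.0 - t * t; }
  case 1: return z > 0.0 ? 1.0 : 0.0;
  case 2: return -2.0 * z * std::exp(-z * z);
  default: {
    double s = 1.0 / (1.0 + std::exp(-z));
    return s + z * s * (1.0 - s);
  }
  }
}

struct MLP {
  std::vector<int> dims;       // n_layers+1 entries: n_in, widths..., n_out
  std::vector<double> w;       // per layer: W (col-major, out x in), then b
  int act;
  bool normalise;
  int n_par;
  mutable std::vector<double> bp_delta, bp_delta_prev; // backprop scratch
  mutable std::vector<size_t> bp_offs;

  MLP(const IntegerVector &dims_, const NumericVector &w_, int act_,
      bool normalise_)
      : dims(dims_.begin(), dims_.end()), w(w_.begin(), w_.end()), act(act_),
        normalise(normalise_) {
    n_par = 0;
    for (size_t l = 1; l < dims.size(); ++l)
      n_par += dims[l] * (dims[l - 1] + 1);
  }

  int n_in() const { return dims.front(); }
  int n_out() const { return dims.back(); }

  // forward pass; optionally keep per-layer pre-activations/activations
  void forward(const double *x, std::vector<std::vector<double> > &a,
               std::vector<std::vector<double> > &z) const {
    size_t L = dims.size() - 1;
    if (a.size() != L + 1) a.resize(L + 1);
    if (z.size() != L + 1) z.resize(L + 1);
    a[0].assign(x, x + dims[0]);
    if (normalise) {
      for (int i = 0; i < dims[0]; ++i)
        a[0][i] = a[0][i] > 0.0 ? std::log(a[0][i] + NORM_C) : std::log(NORM_C);
    }
    size_t off = 0;
    for (size_t l = 1; l <= L; ++l) {
      int ni = dims[l - 1], no = dims[l];
      z[l].assign(no, 0.0);
      a[l].assign(no, 0.0);
      const double *W = &w[off];            // col-major no x ni
      const double *b = &w[off + (size_t)no * ni];
      for (int j = 0; j < ni; ++j) {
        double aj = a[l - 1][j];
        const double *Wj = W + (size_t)j * no;
        for (int i = 0; i < no; ++i) z[l][i] += Wj[i] * aj;
      }
      for (int i = 0; i < no; ++i) {
        z[l][i] += b[i];
        a[l][i] = (l == L) ? z[l][i] : act_f(z[l][i], act); // linear output
      }
      off += (size_t)no * (ni + 1);
    }
  }

  // y, dy/dx (n_out x n_in), dy/dw (n_out x n_par); row-major flat storage
  void jacobians(const double *x, std::vector<double> &y,
                 std::vector<double> &jx, std::vector<double> &jw) const {
    size_t L = dims.size() - 1;
    std::vector<std::vector<double> > a, z;
    forward(x, a, z);
    int no = dims[L], ni0 = dims[0];
    y = a[L];
    jx.assign((size_t)no * ni0, 0.0);
    jw.assign((size_t)no * n_par, 0.0);

    // layer weight offsets: offs[l] = start of layer l's block
    std::vector<size_t> &offs = bp_offs;
    offs.assign(L + 1, 0);
    for (size_t l = 2; l <= L; ++l)
      offs[l] = offs[l - 1] + (size_t)dims[l - 1] * (dims[l - 2] + 1);

    std::vector<double> &delta = bp_delta, &delta_prev = bp_delta_prev;
    for (int k = 0; k < no; ++k) {
      delta.assign(no, 0.0);
      delta[k] = 1.0; // linear output layer
      for (size_t l = L; l >= 1; --l) {
        int ni = dims[l - 1], nl = dims[l];
        const double *W = &w[offs[l]];
        double *jwk = &jw[(size_t)k * n_par + offs[l]];
        // dW_l[i,j] = delta[i] * a_{l-1}[j]; db_l[i] = delta[i]
        for (int j = 0; j < ni; ++j)
          for (int i = 0; i < nl; ++i)
            jwk[(size_t)j * nl + i] = delta[i] * a[l - 1][j];
        for (int i = 0; i < nl; ++i) jwk[(size_t)ni * nl + i] = delta[i];
        // propagate: delta_prev[j] = act'(z_{l-1}[j]) * sum_i W[i,j] delta[i]
        delta_prev.assign(ni, 0.0);
        for (int j = 0; j < ni; ++j) {
          double s = 0.0;
          const double *Wj = W + (size_t)j * nl;
          for (int i = 0; i < nl; ++i) s += Wj[i] * delta[i];
          delta_prev[j] = s;
        }
        if (l >= 2)
          for (int j = 0; j < ni; ++j)
            delta_prev[j] *= act_df(z[l - 1][j], act);
        delta.swap(delta_prev);
        if (l == 1) break;
      }
      // delta now holds d y_k / d a_0
      for (int j = 0; j < ni0; ++j) {
        double d = delta[j];
        if (normalise) d *= (x[j] > 0.0 ? 1.0 / (x[j] + NORM_C) : 0.0);
        jx[(size_t)k * ni0 + j] = d;
      }
    }
  }
};

// [[Rcpp::export]]
NumericVector mlp_forward_cpp(NumericVector w, IntegerVector dims, int act,
                              bool normalise, NumericVector x) {
  MLP net(dims, w, act, normalise);
  if ((int)x.size() != net.n_in()) stop("input length does not match n_inputs");
  std::vector<std::vector<double> > a, z;
  net.forward(REAL(x), a, z);
  return NumericVector(a.back().begin(), a.back().end());
}

// [[Rcpp::export]]
List mlp_jacobians_cpp(NumericVector w, IntegerVector dims, int act,
                       bool normalise, NumericVector x) {
  MLP net(dims, w, act, normalise);
  if ((int)x.size() != net.n_in()) stop("input length does not match n_inputs");
  std::vector<double> y, jx, jw;
  net.jacobians(REAL(x), y, jx, jw);
  int no = net.n_out(), ni = net.n_in();
  NumericMatrix JX(no, ni), JW(no, net.n_par);
  for (int k = 0; k < no; ++k) {
    for (int j = 0; j < ni; ++j) JX(k, j) = jx[(size_t)k * ni + j];
    for (int j = 0; j < net.n_par; ++j) JW(k, j) = jw[(size_t)k * net.n_par + j];
  }
  return List::create(_["y"] = NumericVector(y.begin(), y.end()),
                      _["jac_x"] = JX, _["jac_w"] = JW);
}

// ---------------------------------------------------------------------------
// Glycolysis RHS + Jacobians
// cons order: J0 k1 k2 k3 k4 k5 k6 K1 kappa phi kex N A  (13)
// states:     S1 S2 S3 S4 N2 A3 S4ex                      (7)
// ---------------------------------------------------------------------------

struct Glyc {
  double J0, k1, k2, k3, k4, k5, k6, K1, kappa, phi, kex, N, A;
  bool include_k5;

  Glyc(const double *c, bool inc5)
      : J0(c[0]), k1(c[1]), k2(c[2]), k3(c[3]), k4(c[4]), k5(c[5]), k6(c[6]),
        K1(c[7]), kappa(c[8]), phi(c[9]), kex(c[10]), N(c[11]), A(c[12]),
        include_k5(inc5) {}

  void rhs(const double *x, double *f) const {
    double S1 = x[0], S2 = x[1], S3 = x[2], S4 = x[3], N2 = x[4], A3 = x[5],
           S4ex = x[6];
    double u = std::pow(A3 / K1, 4.0);
    double H = A3 / (1.0 + u);
    double v1 = k1 * S1 * H;
    double vN = k2 * S2 * (N - N2);
    double vA = k3 * S3 * (A - A3);
    f[0] = J0 - v1;
    f[1] = 2.0 * v1 - vN - k6 * S2 * N2;
    f[2] = vN - vA;
    f[3] = vA - k4 * S4 * N2 - kappa * (S4 - S4ex);
    f[4] = vN - k4 * S4 * N2 - k6 * S2 * N2;
    f[5] = -2.0 * v1 + 2.0 * vA - (include_k5 ? k5 * A3 : 0.0);
    f[6] = phi * kappa * (S4 - S4ex) - kex * S4ex;
  }

  // J[i][j] = d f_i / d x_j, row-major 7x7
  void jac_x(const double *x, double *J) const {
    double S1 = x[0], S2 = x[1], S3 = x[2], S4 = x[3], N2 = x[4], A3 = x[5];
    double u = std::pow(A3 / K1, 4.0);
    double den = 1.0 + u;
    double H = A3 / den;
    double dH = (1.0 - 3.0 * u) / (den * den);
    double v1_S1 = k1 * H, v1_A3 = k1 * S1 * dH;
    for (int i = 0; i < 49; ++i) J[i] = 0.0;
    // f0
    J[0 * 7 + 0] = -v1_S1;               J[0 * 7 + 5] = -v1_A3;
    // f1
    J[1 * 7 + 0] = 2.0 * v1_S1;
    J[1 * 7 + 1] = -k2 * (N - N2) - k6 * N2;
    J[1 * 7 + 4] = k2 * S2 - k6 * S2;
    J[1 * 7 + 5] = 2.0 * v1_A3;
    // f2
    J[2 * 7 + 1] = k2 * (N - N2);
    J[2 * 7 + 2] = -k3 * (A - A3);
    J[2 * 7 + 4] = -k2 * S2;
    J[2 * 7 + 5] = k3 * S3;
    // f3
    J[3 * 7 + 2] = k3 * (A - A3);
    J[3 * 7 + 3] = -k4 * N2 - kappa;
    J[3 * 7 + 4] = -k4 * S4;
    J[3 * 7 + 5] = -k3 * S3;
    J[3 * 7 + 6] = kappa;
    // f4
    J[4 * 7 + 1] = k2 * (N - N2) - k6 * N2;
    J[4 * 7 + 3] = -k4 * N2;
    J[4 * 7 + 4] = -k2 * S2 - k4 * S4 - k6 * S2;
    // f5
    J[5 * 7 + 0] = -2.0 * v1_S1;
    J[5 * 7 + 2] = 2.0 * k3 * (A - A3);
    J[5 * 7 + 5] = -2.0 * v1_A3 - 2.0 * k3 * S3 - (include_k5 ? k5 : 0.0);
    // f6
    J[6 * 7 + 3] = phi * kappa;
    J[6 * 7 + 6] = -phi * kappa - kex;
  }

  // g = d f / d cons[idx], one column of the parameter Jacobian
  void jac_p(const double *x, int idx, double *g) const {
    double S1 = x[0], S2 = x[1], S3 = x[2], S4 = x[3], N2 = x[4], A3 = x[5],
           S4ex = x[6];
    double u = std::pow(A3 / K1, 4.0);
    double den = 1.0 + u;
    double H = A3 / den;
    for (int i = 0; i < 7; ++i) g[i] = 0.0;
    switch (idx) {
    case 0: g[0] = 1.0; break;                       // J0
    case 1: { double s = S1 * H;                     // k1
      g[0] = -s; g[1] = 2.0 * s; g[5] = -2.0 * s; break; }
    case 2: { double s = S2 * (N - N2);              // k2
      g[1] = -s; g[2] = s; g[4] = s; break; }
    case 3: { double s = S3 * (A - A3);              // k3
      g[2] = -s; g[3] = s; g[5] = 2.0 * s; break; }
    case 4: { double s = S4 * N2;                    // k4
      g[3] = -s; g[4] = -s; break; }
    case 5: if (include_k5) g[5] = -A3; break;       // k5
    case 6: { double s = S2 * N2;                    // k6
      g[1] = -s; g[4] = -s; break; }
    case 7: { // K1: dH/dK1 = 4 A3 u / (K1 den^2)
      double dHK = 4.0 * A3 * u / (K1 * den * den);
      double s = k1 * S1 * dHK;
      g[0] = -s; g[1] = 2.0 * s; g[5] = -2.0 * s; break; }
    case 8: { double s = S4 - S4ex;                  // kappa
      g[3] = -s; g[6] = phi * s; break; }
    case 9: g[6] = kappa * (S4 - S4ex); break;       // phi
    case 10: g[6] = -S4ex; break;                    // kex
    case 11: { double s = k2 * S2;                   // N
      g[1] = -s; g[2] = s; g[4] = s; break; }
    case 12: { double s = k3 * S3;                   // A
      g[2] = -s; g[3] = s; g[5] = 2.0 * s; break; }
    }
  }
};

// ---------------------------------------------------------------------------
// Dormand-Prince 5(4) with forward sensitivities
// ---------------------------------------------------------------------------

struct GlycSens {
  Glyc model;
  const MLP *net;          // null when no ANN term
  std::vector<int> sidx;   // constant indices with sensitivities
  bool sens_ann;
  int n_par;               // total sensitivity parameters
  int dim;                 // 7 * (1 + n_par)
  // reusable workspace (hot loop: avoid per-eval allocation)
  mutable std::vector<double> yo, jx, jw;
  mutable std::vector<std::vector<double> > wa, wz;

  GlycSens(const Glyc &m, const MLP *net_, const std::vector<int> &sidx_,
           bool sens_ann_)
      : model(m), net(net_), sidx(sidx_), sens_ann(sens_ann_) {
    n_par = (int)sidx.size() + ((net && sens_ann) ? net->n_par : 0);
    dim = 7 * (1 + n_par);
  }

  // y = [x, S columns], S stored column-per-parameter after the state
  bool operator()(const double *y, double *dy) const {
    double f[7], J[49];
    model.rhs(y, f);
    if (net) {
      if (n_par > 0) {
        net->jacobians(y, yo, jx, jw);
      } else {
        net->forward(y, wa, wz);
        yo = wa.back();
      }
      f[5] += yo[0];
      if (n_par > 0) {
        model.jac_x(y, J);
        for (int j = 0; j < 7; ++j) J[5 * 7 + j] += jx[j];
        // sensitivities
        int p = 0;
        double g[7];
        for (size_t c = 0; c < sidx.size(); ++c, ++p) {
          const double *S = y + 7 * (1 + p);
          double *dS = dy + 7 * (1 + p);
          model.jac_p(y, sidx[c], g);
          for (int i = 0; i < 7; ++i) {
            double s = g[i];
            const double *Ji = J + i * 7;
            for (int j = 0; j < 7; ++j) s += Ji[j] * S[j];
            dS[i] = s;
          }
        }
        if (sens_ann) {
          int nw = net->n_par;
          for (int c = 0; c < nw; ++c, ++p) {
            const double *S = y + 7 * (1 + p);
            double *dS = dy + 7 * (1 + p);
            for (int i = 0; i < 7; ++i) {
              double s = (i == 5) ? jw[c] : 0.0;
              const double *Ji = J + i * 7;
              for (int j = 0; j < 7; ++j) s += Ji[j] * S[j];
              dS[i] = s;
            }
          }
        }
      }
    } else if (n_par > 0) {
      model.jac_x(y, J);
      double g[7];
      for (size_t c = 0; c < sidx.size(); ++c) {
        const double *S = y + 7 * (1 + c);
        double *dS = dy + 7 * (1 + c);
        model.jac_p(y, sidx[c], g);
        for (int i = 0; i < 7; ++i) {
          double s = g[i];
          const double *Ji = J + i * 7;
          for (int j = 0; j < 7; ++j) s += Ji[j] * S[j];
          dS[i] = s;
        }
      }
    }
    for (int i = 0; i < 7; ++i) dy[i] = f[i];
    for (int i = 0; i < dim; ++i)
      if (!std::isfinite(dy[i])) return false;
    return true;
  }
};

// [[Rcpp::export]]
List glyc_solve_cpp(NumericVector times, NumericVector x0, NumericVector cons,
                    bool include_k5, bool use_ann, NumericVector w,
                    IntegerVector dims, int act, bool normalise,
                    IntegerVector sens_cons, bool sens_ann, double rtol,
                    double atol, int max_steps) {
  if (cons.size() != 13) stop("expected 13 glycolysis constants");
  if (x0.size() != 7) stop("expected 7 initial states");
  int nt = times.size();
  for (int i = 1; i < nt; ++i)
    if (times[i] <= times[i - 1]) stop("times must be strictly increasing");
  if (nt > 0 && times[0] < 0.0) stop("times must be non-negative");

  Glyc model(REAL(cons), include_k5);
  MLP *net = nullptr;
  MLP netobj(dims, w, act, normalise);
  if (use_ann) {
    if (netobj.n_in() != 7 || netobj.n_out() != 1)
      stop("glycolysis ANN must map 7 inputs to 1 output");
    net = &netobj;
  }
  std::vector<int> sidx(sens_cons.begin(), sens_cons.end());
  GlycSens sys(model, net, sidx, sens_ann && use_ann);

  int dim = sys.dim, n_par = sys.n_par;
  NumericMatrix states(nt, 7);
  NumericVector sens(Dimension(nt, 7, std::max(n_par, 1)));
  bool success = true;
  std::string reason = "";

  std::vector<double> y(dim, 0.0), ynew(dim), err(dim);
  std::vector<double> k1(dim), k2(dim), k3(dim), k4(dim), k5(dim), k6(dim),
      k7(dim);
  for (int i = 0; i < 7; ++i) y[i] = x0[i];

  // DP5 Butcher tableau
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                      e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

  double t = 0.0;
  double t_end = times[nt - 1];
  int out_idx = 0;
  // record any requested time at t = 0
  if (times[0] == 0.0) {
    for (int i = 0; i < 7; ++i) states(0, i) = y[i];
    for (int p = 0; p < n_par; ++p)
      for (int i = 0; i < 7; ++i) sens[0 + nt * (i + 7 * p)] = 0.0;
    out_idx = 1;
  }

  double h = std::min(1e-3, t_end > 0 ? t_end / 100.0 : 1e-3);
  int steps = 0;
  bool have_k1 = false;
  if (!sys(y.data(), k1.data())) { success = false; reason = "non-finite RHS at t=0"; }
  have_k1 = true;

  while (success && t < t_end && out_idx < nt) {
    if (++steps > max_steps) { success = false; reason = "max step count exceeded"; break; }
    bool hit_output = false;
    double h_try = h;
    if (t + h_try >= times[out_idx]) { h_try = times[out_idx] - t; hit_output = true; }
    if (h_try < 1e-14 * std::max(1.0, t_end)) {
      // degenerate clamp; advance output directly
      h_try = std::max(h_try, 1e-14);
    }

    // FSAL: k1 already holds f(t, y)
    for (int i = 0; i < dim; ++i) ynew[i] = y[i] + h_try * a21 * k1[i];
    if (!sys(ynew.data(), k2.data())) { success = false; reason = "non-finite state"; break; }
    for (int i = 0; i < dim; ++i)
      ynew[i] = y[i] + h_try * (a31 * k1[i] + a32 * k2[i]);
    if (!sys(ynew.data(), k3.data())) { success = false; reason = "non-finite state"; break; }
    for (int i = 0; i < dim; ++i)
      ynew[i] = y[i] + h_try * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    if (!sys(ynew.data(), k4.data())) { success = false; reason = "non-finite state"; break; }
    for (int i = 0; i < dim; ++i)
      ynew[i] = y[i] + h_try * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    if (!sys(ynew.data(), k5.data())) { success = false; reason = "non-finite state"; break; }
    for (int i = 0; i < dim; ++i)
      ynew[i] = y[i] + h_try * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                                a64 * k4[i] + a65 * k5[i]);
    if (!sys(ynew.data(), k6.data())) { success = false; reason = "non-finite state"; break; }
    for (int i = 0; i < dim; ++i)
      ynew[i] = y[i] + h_try * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                                b5 * k5[i] + b6 * k6[i]);
    if (!sys(ynew.data(), k7.data())) { success = false; reason = "non-finite state"; break; }

    // error estimate (5th - 4th order), scaled max-norm over state entries
    double errnorm = 0.0;
    for (int i = 0; i < dim; ++i) {
      double e = h_try * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                          e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = e / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / dim);

    if (!std::isfinite(errnorm)) { success = false; reason = "non-finite error estimate"; break; }

    if (errnorm <= 1.0) {
      t += h_try;
      y.swap(ynew);
      k1.swap(k7); // FSAL
      for (int i = 0; i < 7; ++i)
        if (std::fabs(y[i]) > 1e10) { success = false; reason = "state blow-up"; break; }
      if (!success) break;
      if (hit_output) {
        for (int i = 0; i < 7; ++i) states(out_idx, i) = y[i];
        for (int p = 0; p < n_par; ++p)
          for (int i = 0; i < 7; ++i)
            sens[out_idx + nt * (i + 7 * p)] = y[7 * (1 + p) + i];
        ++out_idx;
      }
    }
    double fac = errnorm > 0.0 ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
    fac = std::min(5.0, std::max(0.2, fac));
    h = (hit_output && errnorm <= 1.0) ? std::max(h, h_try * fac) : h_try * fac;
    if (h < 1e-13 * std::max(1.0, t_end)) { success = false; reason = "step size collapse"; break; }
  }

  if (out_idx < nt && success) { success = false; reason = "integration incomplete"; }

  return List::create(_["success"] = success, _["reason"] = reason,
                      _["states"] = states, _["sens"] = sens,
                      _["n_par"] = n_par);
}

// ---------------------------------------------------------------------------
// Adjoint gradient for the glycolysis family: forward DP5 solve with dense
// output, then a backward adjoint solve with parameter quadratures. The
// gradient cost is independent of the network size, which is what makes
// multi-start training with hundreds of weights affordable.
// ---------------------------------------------------------------------------

struct GlycRhs { // plain 7-state RHS (mechanistic + optional ANN on A3)
  Glyc model;
  const MLP *net;
  mutable std::vector<std::vector<double> > wa, wz; // reusable workspace
  GlycRhs(const Glyc &m, const MLP *n) : model(m), net(n) {}
  bool operator()(const double *y, double *dy) const {
    model.rhs(y, dy);
    if (net) {
      net->forward(y, wa, wz);
      dy[5] += wa.back()[0];
    }
    for (int i = 0; i < 7; ++i)
      if (!std::isfinite(dy[i])) return false;
    return true;
  }
};

// one accepted forward step, stored for dense interpolation
struct DenseStep {
  double t, h;
  double rc[5][7]; // DOPRI5 interpolation coefficients per component
};

// DOPRI5 dense-output weights (Hairer, Norsett & Wanner)
static const double dd1 = -12715105075.0 / 11282082432.0;
static const double dd3 = 87487479700.0 / 32700410799.0;
static const double dd4 = -10690763975.0 / 1880347072.0;
static const double dd5 = 701980252875.0 / 199316789632.0;
static const double dd6 = -1453857185.0 / 822651844.0;
static const double dd7 = 69997945.0 / 29380423.0;

static void dense_eval(const DenseStep &s, double t, double *out) {
  double th = (t - s.t) / s.h, th1 = 1.0 - th;
  for (int i = 0; i < 7; ++i) {
    out[i] = s.rc[0][i] +
             th * (s.rc[1][i] +
                   th1 * (s.rc[2][i] + th * (s.rc[3][i] + th1 * s.rc[4][i])));
  }
}

// forward solve storing dense steps; records states at requested times
static bool forward_dense(const GlycRhs &sys, const NumericVector &times,
                          const double *x0, double rtol, double atol,
                          int max_steps, std::vector<DenseStep> &steps,
                          NumericMatrix &states) {
  static const double c_[6] = {0.2, 0.3, 0.8, 8.0 / 9.0, 1.0, 1.0};
  (void)c_;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                      e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

  int nt = times.size();
  double t = 0.0, t_end = times[nt - 1];
  double y[7], ynew[7], k1[7], k2[7], k3[7], k4[7], k5[7], k6[7], k7[7];
  for (int i = 0; i < 7; ++i) y[i] = x0[i];
  int out_idx = 0;
  if (times[0] == 0.0) {
    for (int i = 0; i < 7; ++i) states(0, i) = y[i];
    out_idx = 1;
  }
  double h = std::min(1e-3, t_end > 0 ? t_end / 100.0 : 1e-3);
  if (!sys(y, k1)) return false;
  int nstep = 0;
  while (t < t_end) {
    if (++nstep > max_steps) return false;
    double h_try = h;
    bool hit = false;
    // never step past the final time; output times are read off the
    // interpolant, so only t_end needs clamping
    if (t + h_try >= t_end) { h_try = t_end - t; hit = true; }
    double tmp[7];
    for (int i = 0; i < 7; ++i) tmp[i] = y[i] + h_try * a21 * k1[i];
    if (!sys(tmp, k2)) return false;
    for (int i = 0; i < 7; ++i)
      tmp[i] = y[i] + h_try * (a31 * k1[i] + a32 * k2[i]);
    if (!sys(tmp, k3)) return false;
    for (int i = 0; i < 7; ++i)
      tmp[i] = y[i] + h_try * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    if (!sys(tmp, k4)) return false;
    for (int i = 0; i < 7; ++i)
      tmp[i] = y[i] + h_try * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                               a54 * k4[i]);
    if (!sys(tmp, k5)) return false;
    for (int i = 0; i < 7; ++i)
      tmp[i] = y[i] + h_try * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                               a64 * k4[i] + a65 * k5[i]);
    if (!sys(tmp, k6)) return false;
    for (int i = 0; i < 7; ++i)
      ynew[i] = y[i] + h_try * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                                b5 * k5[i] + b6 * k6[i]);
    if (!sys(ynew, k7)) return false;

    double errnorm = 0.0;
    for (int i = 0; i < 7; ++i) {
      double e = h_try * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                          e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = e / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / 7.0);
    if (!std::isfinite(errnorm)) return false;

    if (errnorm <= 1.0) {
      DenseStep st;
      st.t = t; st.h = h_try;
      for (int i = 0; i < 7; ++i) {
        double ydiff = ynew[i] - y[i];
        double bspl = h_try * k1[i] - ydiff;
        st.rc[0][i] = y[i];
        st.rc[1][i] = ydiff;
        st.rc[2][i] = bspl;
        st.rc[3][i] = ydiff - h_try * k7[i] - bspl;
        st.rc[4][i] = h_try * (dd1 * k1[i] + dd3 * k3[i] + dd4 * k4[i] +
                               dd5 * k5[i] + dd6 * k6[i] + dd7 * k7[i]);
      }
      steps.push_back(st);
      t += h_try;
      for (int i = 0; i < 7; ++i) {
        y[i] = ynew[i];
        k1[i] = k7[i]; // FSAL
        if (std::fabs(y[i]) > 1e10) return false;
      }
      while (out_idx < nt && times[out_idx] <= t + 1e-14 * std::max(1.0, t_end)) {
        double xi[7];
        dense_eval(steps.back(), std::min((double)times[out_idx], t), xi);
        for (int i = 0; i < 7; ++i) states(out_idx, i) = xi[i];
        ++out_idx;
      }
    }
    double fac = errnorm > 0.0 ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
    fac = std::min(5.0, std::max(0.2, fac));
    h = (hit && errnorm <= 1.0) ? std::max(h, h_try * fac) : h_try * fac;
    if (h < 1e-13 * std::max(1.0, t_end)) return false;
  }
  return out_idx >= nt;
}

// RHS of the reverse-time adjoint system z = (lambda(7), g(n_par)):
// dz/ds at s with u = T - s; x from the dense forward solution.
struct AdjointSys {
  const Glyc &model;
  const MLP *net;
  const std::vector<DenseStep> &steps;
  const std::vector<int> &sidx;
  bool grad_ann;
  double T;
  mutable size_t hint; // last used step index (monotone during the sweep)
  mutable std::vector<double> yo, jx, jw; // reusable workspace

  AdjointSys(const Glyc &m, const MLP *n, const std::vector<DenseStep> &st,
             const std::vector<int> &si, bool ga, double T_)
      : model(m), net(n), steps(st), sidx(si), grad_ann(ga), T(T_), hint(0) {}

  void x_at(double u, double *x) const {
    size_t lo = 0, hi = steps.size() - 1;
    // binary search for the step containing u
    while (lo < hi) {
      size_t mid = (lo + hi + 1) / 2;
      if (steps[mid].t <= u + 1e-14) lo = mid; else hi = mid - 1;
    }
    dense_eval(steps[lo], u, x);
  }

  bool operator()(double s, const double *z, double *dz) const {
    double u = T - s;
    if (u < 0) u = 0;
    double x[7], J[49];
    x_at(u, x);
    model.jac_x(x, J);
    if (net) {
      net->jacobians(x, yo, jx, jw);
      for (int j = 0; j < 7; ++j) J[5 * 7 + j] += jx[j];
    }
    const double *lam = z;
    double *dlam = dz;
    // d lambda / ds = + J_x^T lambda
    for (int j = 0; j < 7; ++j) {
      double ssum = 0.0;
      for (int i = 0; i < 7; ++i) ssum += J[i * 7 + j] * lam[i];
      dlam[j] = ssum;
    }
    // quadratures: dg/ds = + (df/dp)^T lambda
    int p = 0;
    double gcol[7];
    for (size_t c = 0; c < sidx.size(); ++c, ++p) {
      model.jac_p(x, sidx[c], gcol);
      double ssum = 0.0;
      for (int i = 0; i < 7; ++i) ssum += gcol[i] * lam[i];
      dz[7 + p] = ssum;
    }
    if (grad_ann && net) {
      int nw = net->n_par;
      double lA3 = lam[5];
      for (int c = 0; c < nw; ++c) dz[7 + p + c] = lA3 * jw[c];
    }
    int dim = 7 + p + ((grad_ann && net) ? net->n_par : 0);
    for (int i = 0; i < dim; ++i)
      if (!std::isfinite(dz[i])) return false;
    return true;
  }
};

// adaptive DP5 sweep of the adjoint system over [s_from, s_to]
static bool adjoint_sweep(const AdjointSys &sys, int dim, double s_from,
                          double s_to, std::vector<double> &z, double rtol,
                          double atol, int max_steps) {
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                      e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;
  static const double c2 = 0.2, c3 = 0.3, c4 = 0.8, c5 = 8.0 / 9.0;

  double span = s_to - s_from;
  if (span <= 0) return true;
  double s = s_from;
  double h = std::min(1e-2, span);
  std::vector<double> k1(dim), k2(dim), k3(dim), k4(dim), k5(dim), k6(dim),
      k7(dim), tmp(dim), znew(dim);
  if (!sys(s, z.data(), k1.data())) return false;
  int nstep = 0;
  while (s < s_to) {
    if (++nstep > max_steps) return false;
    double h_try = h;
    bool hit = false;
    if (s + h_try >= s_to) { h_try = s_to - s; hit = true; }
    for (int i = 0; i < dim; ++i) tmp[i] = z[i] + h_try * a21 * k1[i];
    if (!sys(s + c2 * h_try, tmp.data(), k2.data())) return false;
    for (int i = 0; i < dim; ++i)
      tmp[i] = z[i] + h_try * (a31 * k1[i] + a32 * k2[i]);
    if (!sys(s + c3 * h_try, tmp.data(), k3.data())) return false;
    for (int i = 0; i < dim; ++i)
      tmp[i] = z[i] + h_try * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    if (!sys(s + c4 * h_try, tmp.data(), k4.data())) return false;
    for (int i = 0; i < dim; ++i)
      tmp[i] = z[i] + h_try * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                               a54 * k4[i]);
    if (!sys(s + c5 * h_try, tmp.data(), k5.data())) return false;
    for (int i = 0; i < dim; ++i)
      tmp[i] = z[i] + h_try * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                               a64 * k4[i] + a65 * k5[i]);
    if (!sys(s + h_try, tmp.data(), k6.data())) return false;
    for (int i = 0; i < dim; ++i)
      znew[i] = z[i] + h_try * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                                b5 * k5[i] + b6 * k6[i]);
    if (!sys(s + h_try, znew.data(), k7.data())) return false;

    double errnorm = 0.0;
    for (int i = 0; i < dim; ++i) {
      double e = h_try * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                          e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(z[i]), std::fabs(znew[i]));
      double r = e / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / dim);
    if (!std::isfinite(errnorm)) return false;
    if (errnorm <= 1.0) {
      s += h_try;
      z.swap(znew);
      k1.swap(k7);
    }
    double fac = errnorm > 0.0 ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
    fac = std::min(5.0, std::max(0.2, fac));
    h = (hit && errnorm <= 1.0) ? std::max(h, h_try * fac) : h_try * fac;
    if (h < 1e-14 * std::max(1.0, span)) return false;
  }
  return true;
}

// [[Rcpp::export]]
List glyc_adjoint_cpp(NumericVector times, NumericVector x0,
                      NumericVector cons, bool include_k5, bool use_ann,
                      NumericVector w, IntegerVector dims, int act,
                      bool normalise, IntegerVector sens_cons,
                      bool grad_ann, IntegerVector rec_time, // 0-based
                      IntegerVector rec_state,               // 0-based
                      NumericVector rec_y, NumericVector rec_wt,
                      double rtol, double atol, int max_steps) {
  if (cons.size() != 13) stop("expected 13 glycolysis constants");
  if (x0.size() != 7) stop("expected 7 initial states");
  int nt = times.size();
  Glyc model(REAL(cons), include_k5);
  MLP netobj(dims, w, act, normalise);
  MLP *net = use_ann ? &netobj : nullptr;
  if (use_ann && (netobj.n_in() != 7 || netobj.n_out() != 1))
    stop("glycolysis ANN must map 7 inputs to 1 output");

  NumericMatrix states(nt, 7);
  std::vector<DenseStep> steps;
  steps.reserve(512);
  GlycRhs rhs(model, net);
  bool ok = forward_dense(rhs, times, REAL(x0), rtol, atol, max_steps, steps,
                          states);
  std::vector<int> sidx(sens_cons.begin(), sens_cons.end());
  int n_par = (int)sidx.size() + ((use_ann && grad_ann) ? netobj.n_par : 0);
  NumericVector grad(std::max(n_par, 1));
  if (!ok || steps.empty()) {
    return List::create(_["success"] = false, _["states"] = states,
                        _["grad"] = grad, _["n_par"] = n_par);
  }
  if (n_par == 0 || rec_time.size() == 0) {
    return List::create(_["success"] = true, _["states"] = states,
                        _["grad"] = grad, _["n_par"] = n_par);
  }

  double T = times[nt - 1];
  AdjointSys adj(model, net, steps, sidx, grad_ann, T);
  int dim = 7 + n_par;
  std::vector<double> z(dim, 0.0);

  // per-time-point weighted residual injections, processed backwards
  int nrec = rec_time.size();
  std::vector<std::vector<std::pair<int, double> > > jumps(nt);
  for (int r = 0; r < nrec; ++r) {
    double pred = states(rec_time[r], rec_state[r]);
    double wgt = (pred - rec_y[r]) * rec_wt[r];
    if (wgt != 0.0) jumps[rec_time[r]].push_back({rec_state[r], wgt});
  }
  // sweep from s = 0 (u = T) down to s = T (u = 0), pausing at data times
  double s_cur = 0.0;
  bool okb = true;
  for (int k = nt - 1; k >= 0; --k) {
    double s_k = T - times[k];
    if (s_k > s_cur) {
      okb = adjoint_sweep(adj, dim, s_cur, s_k, z, rtol, atol, max_steps);
      if (!okb) break;
      s_cur = s_k;
    }
    for (size_t j = 0; j < jumps[k].size(); ++j)
      z[jumps[k][j].first] += jumps[k][j].second;
  }
  if (okb && s_cur < T)
    okb = adjoint_sweep(adj, dim, s_cur, T, z, rtol, atol, max_steps);

  if (okb) {
    for (int p = 0; p < n_par; ++p) grad[p] = z[7 + p];
  }
  return List::create(_["success"] = okb, _["states"] = states,
                      _["grad"] = grad, _["n_par"] = n_par);
}
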