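#include <Rcpp.h>
using namespace Rcpp;

// Four-layer recurrent fuzzy network, normalized units throughout.
// m, sig: I x R (one Gaussian per input per rule); lam: R; w: R x O.
// Rule j fires s_j = prod_i exp(-(x_i - m_ij)^2 / sig_ij^2); the rule
// state is the convex combination u_j(t) = lam_j s_j + (1 - lam_j)
// u_j(t-1); the output is the u-weighted mean of the rule weights.

static const double DENOM_EPS = 1e-12;

// Forward one sample; returns denom. s, u, y are outputs.
static double forward_one(const double* m, const double* sig,
                          const double* lam, const double* w,
                          int I, int R, int O,
                          const double* x, const double* uprev,
                          double* s, double* u, double* y,
                          const double* yhold) {
  for (int j = 0; j < R; ++j) {
    double logs = 0.0;
    for (int i = 0; i < I; ++i) {
      double d = (x[i] - m[i + j * I]) / sig[i + j * I];
      logs -= d * d;
    }
    s[j] = std::exp(logs);
    u[j] = lam[j] * s[j] + (1.0 - lam[j]) * uprev[j];
  }
  double denom = 0.0;
  for (int j = 0; j < R; ++j) denom += u[j];
  if (denom < DENOM_EPS) {
    for (int o = 0; o < O; ++o) y[o] = yhold[o];
    return denom;
  }
  for (int o = 0; o < O; ++o) {
    double acc = 0.0;
    for (int j = 0; j < R; ++j) acc += u[j] * w[j + o * R];
    y[o] = acc / denom;
  }
  return denom;
}

// [[Rcpp::export]]
List rfnn_forward_cpp(NumericMatrix m, NumericMatrix sig, NumericVector lam,
                      NumericMatrix w, NumericMatrix X, NumericVector u0) {
  const int I = m.nrow(), R = m.ncol(), O = w.ncol(), T = X.nrow();
  if (X.ncol() != I) stop("input dimension mismatch");
  NumericMatrix Y(T, O), U(T, R), S(T, R);
  LogicalVector held(T);
  std::vector<double> uprev(u0.begin(), u0.end());
  std::vector<double> s(R), u(R), y(O), yhold(O);
  // hold value before any valid step: equal-weight defuzzification
  for (int o = 0; o < O; ++o) {
    double acc = 0.0;
    for (int j = 0; j < R; ++j) acc += w(j, o);
    yhold[o] = acc / R;
  }
  std::vector<double> xrow(I);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < I; ++i) xrow[i] = X(t, i);
    double denom = forward_one(REAL(m), REAL(sig), REAL(lam), REAL(w),
                               I, R, O, xrow.data(), uprev.data(),
                               s.data(), u.data(), y.data(), yhold.data());
    held[t] = denom < DENOM_EPS;
    for (int j = 0; j < R; ++j) { S(t, j) = s[j]; U(t, j) = u[j]; }
    for (int o = 0; o < O; ++o) Y(t, o) = y[o];
    uprev.assign(u.begin(), u.end());
    if (!held[t]) yhold.assign(y.begin(), y.end());
  }
  return List::create(_["Y"] = Y, _["U"] = U, _["S"] = S, _["held"] = held);
}

// Per-sample gradients of E = 1/2 sum_o (y_o - t_o)^2 with u(t-1)
// treated as constant (depth-1 truncation).
static double grads_one(const double* m, const double* sig,
                        const double* lam, const double* w,
                        int I, int R, int O,
                        const double* x, const double* uprev,
                        const double* yt,
                        double* gm, double* gsig, double* glam, double* gw,
                        double* s, double* u, double* y,
                        bool* valid) {
  std::vector<double> yhold(O, 0.0);
  for (int o = 0; o < O; ++o) {
    double acc = 0.0;
    for (int j = 0; j < R; ++j) acc += w[j + o * R];
    yhold[o] = acc / R;
  }
  double denom = forward_one(m, sig, lam, w, I, R, O, x, uprev,
                             s, u, y, yhold.data());
  std::fill(gm, gm + I * R, 0.0);
  std::fill(gsig, gsig + I * R, 0.0);
  std::fill(glam, glam + R, 0.0);
  std::fill(gw, gw + R * O, 0.0);
  if (denom < DENOM_EPS) { *valid = false; return 0.0; }
  *valid = true;
  double E = 0.0;
  std::vector<double> e(O);
  for (int o = 0; o < O; ++o) {
    e[o] = y[o] - yt[o];
    E += 0.5 * e[o] * e[o];
  }
  for (int j = 0; j < R; ++j) {
    double dEdu = 0.0;
    for (int o = 0; o < O; ++o) {
      gw[j + o * R] = e[o] * u[j] / denom;
      dEdu += e[o] * (w[j + o * R] - y[o]) / denom;
    }
    glam[j] = dEdu * (s[j] - uprev[j]);
    double dEds = dEdu * lam[j];
    for (int i = 0; i < I; ++i) {
      double diff = x[i] - m[i + j * I];
      double sg = sig[i + j * I];
      gm[i + j * I] = dEds * s[j] * 2.0 * diff / (sg * sg);
      gsig[i + j * I] = dEds * s[j] * 2.0 * diff * diff / (sg * sg * sg);
    }
  }
  return E;
}

// [[Rcpp::export]]
List rfnn_grads_cpp(NumericMatrix m, NumericMatrix sig, NumericVector lam,
                    NumericMatrix w, NumericVector x, NumericVector uprev,
                    NumericVector yt) {
  const int I = m.nrow(), R = m.ncol(), O = w.ncol();
  NumericMatrix gm(I, R), gsig(I, R), gw(R, O);
  NumericVector glam(R), s(R), u(R), y(O);
  bool valid = true;
  double E = grads_one(REAL(m), REAL(sig), REAL(lam), REAL(w), I, R, O,
                       REAL(x), REAL(uprev), REAL(yt),
                       REAL(gm), REAL(gsig), REAL(glam), REAL(gw),
                       REAL(s), REAL(u), REAL(y), &valid);
  return List::create(_["gm"] = gm, _["gsig"] = gsig, _["glam"] = glam,
                      _["gw"] = gw, _["s"] = s, _["u"] = u, _["y"] = y,
                      _["E"] = E, _["valid"] = valid);
}

// One epoch of sequential per-sample gradient descent over a list of
// sequences; state resets at each sequence start. Parameters are updated
// in place on clones and returned together with the epoch's mean loss,
// per-rule mean firing strength, and the worst-covered sample.
// [[Rcpp::export]]
List rfnn_train_epoch_cpp(NumericMatrix m0, NumericMatrix sig0,
                          NumericVector lam0, NumericMatrix w0,
                          List Xs, List Ys,
                          double eta_m, double eta_sig,
                          double eta_lam, double eta_w,
                          double sig_min) {
  NumericMatrix m = clone(m0), sig = clone(sig0), w = clone(w0);
  NumericVector lam = clone(lam0);
  const int I = m.nrow(), R = m.ncol(), O = w.ncol();
  std::vector<double> s(R), u(R), y(O), xrow(I), yrow(O);
  std::vector<double> gm(I * R), gsig(I * R), glam(R), gw(R * O);
  NumericVector firing_sum(R);
  double loss = 0.0;
  long nsamp = 0, nheld = 0;
  double worst_fire = R_PosInf;
  NumericVector worst_x(I);
  for (int q = 0; q < Xs.size(); ++q) {
    NumericMatrix X = Xs[q], Y = Ys[q];
    if (X.ncol() != I || Y.ncol() != O || X.nrow() != Y.nrow())
      stop("sequence dimension mismatch");
    std::vector<double> uprev(R, 0.0);
    for (int t = 0; t < X.nrow(); ++t) {
      for (int i = 0; i < I; ++i) xrow[i] = X(t, i);
      for (int o = 0; o < O; ++o) yrow[o] = Y(t, o);
      bool valid = true;
      double E = grads_one(REAL(m), REAL(sig), REAL(lam), REAL(w),
                           I, R, O, xrow.data(), uprev.data(), yrow.data(),
                           gm.data(), gsig.data(), glam.data(), gw.data(),
                           s.data(), u.data(), y.data(), &valid);
      double maxfire = 0.0;
      for (int j = 0; j < R; ++j) {
        firing_sum[j] += s[j];
        if (s[j] > maxfire) maxfire = s[j];
      }
      if (maxfire < worst_fire) {
        worst_fire = maxfire;
        for (int i = 0; i < I; ++i) worst_x[i] = xrow[i];
      }
      if (valid) {
        loss += E;
        for (int k = 0; k < I * R; ++k) {
          double nm = REAL(m)[k] - eta_m * gm[k];
          double ns = REAL(sig)[k] - eta_sig * gsig[k];
          REAL(m)[k] = nm;
          REAL(sig)[k] = ns < sig_min ? sig_min : ns;
        }
        for (int j = 0; j < R; ++j) {
          double nl = lam[j] - eta_lam * glam[j];
          lam[j] = nl < 0.0 ? 0.0 : (nl > 1.0 ? 1.0 : nl);
        }
        for (int k = 0; k < R * O; ++k) REAL(w)[k] -= eta_w * gw[k];
        if (!std::isfinite(loss)) stop("non-finite training loss");
      } else {
        ++nheld;
      }
      uprev.assign(u.begin(), u.end());
      ++nsamp;
    }
  }
  NumericVector firing_mean(R);
  for (int j = 0; j < R; ++j)
    firing_mean[j] = nsamp > 0 ? firing_sum[j] / nsamp : 0.0;
  return List::create(
    _["m"] = m, _["sig"] = sig, _["lam"] = lam, _["w"] = w,
    _["loss"] = nsamp > 0 ? loss / nsamp : 0.0,
    _["firing_mean"] = firing_mean,
    _["worst_fire"] = worst_fire, _["worst_x"] = worst_x,
    _["n_held"] = (double)nheld);
}
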