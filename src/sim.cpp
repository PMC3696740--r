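#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gain: Heaviside H(u - kappa) with H(0) = 1 when gamma <= 0,
// otherwise the logistic sigmoid 1/(1 + exp(-gamma*(u - kappa))).
static inline double gain(double u, double kappa, double gamma) {
  if (gamma <= 0.0) return (u >= kappa) ? 1.0 : 0.0;
  return 1.0 / (1.0 + std::exp(-gamma * (u - kappa)));
}

// Euler-Maruyama integration of the ring neural field with synaptic
// depression.  The cosine kernel cos(2(x-y)) is separable, so the
// convolution reduces to two inner products per step.  Spatially
// correlated noise xi(x) = sqrt(eps*scale)*(eta1*cos x + eta2*sin x)
// realizes covariance eps*scale*cos(x - y) per unit time.
//
// Returns peak activity in the right (x > 0) and left (x < 0) halves
// at a fixed recording stride, plus (optionally) decimated snapshots
// of the full u and q fields.
// [[Rcpp::export]]
List ring_sim_cpp(int n_grid, double dt, double n_steps_d, double tau_m,
                  double tau, double beta, double kappa, double gamma,
                  double I0, double Ia, double eps, double noise_scale,
                  NumericVector u0, NumericVector q0,
                  int record_stride, int snap_stride) {
  const int n = n_grid;
  const R_xlen_t n_steps = (R_xlen_t) n_steps_d;
  if (u0.size() != n || q0.size() != n)
    stop("state arrays do not match n_grid: corrupted state");

  std::vector<double> x(n), c2(n), s2(n), cx(n), sx(n), Iext(n);
  const double dx = M_PI / n;
  for (int i = 0; i < n; ++i) {
    x[i] = -M_PI_2 + i * dx;
    c2[i] = std::cos(2.0 * x[i]);
    s2[i] = std::sin(2.0 * x[i]);
    cx[i] = std::cos(x[i]);
    sx[i] = std::sin(x[i]);
    Iext[i] = -I0 * std::cos(4.0 * x[i]) + Ia * std::sin(2.0 * x[i]);
  }

  std::vector<double> u(u0.begin(), u0.end()), q(q0.begin(), q0.end());
  const double sig = std::sqrt(eps * noise_scale * dt) / tau_m;
  const bool noisy = eps > 0.0;

  const R_xlen_t n_rec = n_steps / record_stride + 1;
  NumericVector rec_t(n_rec), rec_pR(n_rec), rec_pL(n_rec);
  R_xlen_t n_snap = 0;
  NumericMatrix snap_u, snap_q;
  NumericVector snap_t;
  if (snap_stride > 0) {
    n_snap = n_steps / snap_stride + 1;
    snap_u = NumericMatrix(n_snap, n);
    snap_q = NumericMatrix(n_snap, n);
    snap_t = NumericVector(n_snap);
  }

  GetRNGstate();
  R_xlen_t i_rec = 0, i_snap = 0;
  for (R_xlen_t step = 0; step <= n_steps; ++step) {
    // record before stepping so t = 0 is included
    if (step % record_stride == 0 && i_rec < n_rec) {
      double pR = R_NegInf, pL = R_NegInf;
      for (int i = 0; i < n; ++i) {
        if (x[i] > 0.0) { if (u[i] > pR) pR = u[i]; }
        else if (x[i] < 0.0) { if (u[i] > pL) pL = u[i]; }
      }
      rec_t[i_rec] = step * dt; rec_pR[i_rec] = pR; rec_pL[i_rec] = pL;
      ++i_rec;
    }
    if (snap_stride > 0 && step % snap_stride == 0 && i_snap < n_snap) {
      for (int i = 0; i < n; ++i) { snap_u(i_snap, i) = u[i]; snap_q(i_snap, i) = q[i]; }
      snap_t[i_snap] = step * dt;
      ++i_snap;
    }
    if (step == n_steps) break;

    double A = 0.0, B = 0.0;
    double fbuf_stack[4096];
    double *f = fbuf_stack; // n <= 4096 enforced in R wrapper
    for (int i = 0; i < n; ++i) {
      const double fi = gain(u[i], kappa, gamma);
      f[i] = fi;
      if (fi != 0.0) {
        const double qf = q[i] * fi;
        A += c2[i] * qf;
        B += s2[i] * qf;
      }
    }
    A *= dx; B *= dx;

    double e1 = 0.0, e2 = 0.0;
    if (noisy) { e1 = norm_rand(); e2 = norm_rand(); }
    for (int i = 0; i < n; ++i) {
      const double drive = A * c2[i] + B * s2[i];
      double du = dt * (-u[i] + drive + Iext[i]) / tau_m;
      if (noisy) du += sig * (e1 * cx[i] + e2 * sx[i]);
      u[i] += du;
      if (beta > 0.0)
        q[i] += dt * (1.0 - q[i] - beta * q[i] * f[i]) / tau;
    }

    if ((step & 0x3FF) == 0 && !std::isfinite(u[0])) {
      PutRNGstate();
      stop("non-finite field state at step %d (t = %g)", (int) step, step * dt);
    }
  }
  PutRNGstate();
  if (!std::isfinite(u[0]))
    stop("non-finite field state at end of integration");

  List out = List::create(
    _["t"] = rec_t, _["peak_R"] = rec_pR, _["peak_L"] = rec_pL,
    _["u_final"] = NumericVector(u.begin(), u.end()),
    _["q_final"] = NumericVector(q.begin(), q.end()));
  if (snap_stride > 0) {
    out["snap_t"] = snap_t; out["snap_u"] = snap_u; out["snap_q"] = snap_q;
  }
  return out;
}

// Euler-Maruyama integration of the space-free two-population
// mutual-inhibition network with depression.  White noise of variance
// eps enters the activity equations only.
// [[Rcpp::export]]
List reduced_sim_cpp(double dt, double n_steps_d, double tau, double beta,
                     double IR, double IL, double eps,
                     NumericVector u0, NumericVector q0, int record_stride) {
  const R_xlen_t n_steps = (R_xlen_t) n_steps_d;
  double uR = u0[0], uL = u0[1], qR = q0[0], qL = q0[1];
  const double sig = std::sqrt(eps * dt);
  const bool noisy = eps > 0.0;

  const R_xlen_t n_rec = n_steps / record_stride + 1;
  NumericVector rec_t(n_rec), ruR(n_rec), ruL(n_rec), rqR(n_rec), rqL(n_rec);

  GetRNGstate();
  R_xlen_t i_rec = 0;
  for (R_xlen_t step = 0; step <= n_steps; ++step) {
    if (step % record_stride == 0 && i_rec < n_rec) {
      rec_t[i_rec] = step * dt;
      ruR[i_rec] = uR; ruL[i_rec] = uL; rqR[i_rec] = qR; rqL[i_rec] = qL;
      ++i_rec;
    }
    if (step == n_steps) break;
    const double fR = (IR - qL * uL >= 0.0) ? 1.0 : 0.0;
    const double fL = (IL - qR * uR >= 0.0) ? 1.0 : 0.0;
    double duR = dt * (-uR + fR), duL = dt * (-uL + fL);
    if (noisy) { duR += sig * norm_rand(); duL += sig * norm_rand(); }
    const double dqR = dt * (1.0 - qR - beta * uR * qR) / tau;
    const double dqL = dt * (1.0 - qL - beta * uL * qL) / tau;
    uR += duR; uL += duL; qR += dqR; qL += dqL;
    if ((step & 0xFFF) == 0 && !(std::isfinite(uR) && std::isfinite(uL))) {
      PutRNGstate();
      stop("non-finite state at step %d (t = %g)", (int) step, step * dt);
    }
  }
  PutRNGstate();
  return List::create(_["t"] = rec_t, _["uR"] = ruR, _["uL"] = ruL,
                      _["qR"] = rqR, _["qL"] = rqL);
}

// Three-population competitive network with depression; each
// population is inhibited by the other two through depressing synapses.
// [[Rcpp::export]]
List tristable_sim_cpp(double dt, double n_steps_d, double tau, double beta,
                       double I, double eps,
                       NumericVector u0, NumericVector q0, int record_stride) {
  const R_xlen_t n_steps = (R_xlen_t) n_steps_d;
  double u[3] = {u0[0], u0[1], u0[2]}, q[3] = {q0[0], q0[1], q0[2]};
  const double sig = std::sqrt(eps * dt);
  const bool noisy = eps > 0.0;

  const R_xlen_t n_rec = n_steps / record_stride + 1;
  NumericVector rec_t(n_rec);
  NumericMatrix ru(n_rec, 3), rq(n_rec, 3);

  GetRNGstate();
  R_xlen_t i_rec = 0;
  for (R_xlen_t step = 0; step <= n_steps; ++step) {
    if (step % record_stride == 0 && i_rec < n_rec) {
      rec_t[i_rec] = step * dt;
      for (int j = 0; j < 3; ++j) { ru(i_rec, j) = u[j]; rq(i_rec, j) = q[j]; }
      ++i_rec;
    }
    if (step == n_steps) break;
    double du[3];
    for (int j = 0; j < 3; ++j) {
      const int a = (j + 1) % 3, b = (j + 2) % 3;
      const double arg = I - q[a] * u[a] - q[b] * u[b];
      const double fj = (arg >= 0.0) ? 1.0 : 0.0;
      du[j] = dt * (-u[j] + fj);
      if (noisy) du[j] += sig * norm_rand();
    }
    for (int j = 0; j < 3; ++j) {
      q[j] += dt * (1.0 - q[j] - beta * u[j] * q[j]) / tau;
      u[j] += du[j];
    }
    if ((step & 0xFFF) == 0 && !std::isfinite(u[0])) {
      PutRNGstate();
      stop("non-finite state at step %d (t = %g)", (int) step, step * dt);
    }
  }
  PutRNGstate();
  return List::create(_["t"] = rec_t, _["u"] = ru, _["q"] = rq);
}
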