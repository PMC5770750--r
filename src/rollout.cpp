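#include <Rcpp.h>
using namespace Rcpp;

// One closed-loop reaching movement: delayed-feedback state estimation,
// neural-net controller, semi-implicit Euler plant integration with
// signal-dependent motor noise. Mirrors the R-level primitives
// (arm_step / open_loop_update / closed_loop_update / policy_forward)
// step for step; a test asserts the equivalence.

struct Arm {
  double k1, k2, k3;            // rigid-body constants
  double B[4];                  // damping, column-major 2x2
  double A[12];                 // moment arms, column-major 6x2
  double fmax[6];
  double kappa, dt;
  double qlo[2], qhi[2];
  double l1, l2;
};

// noise-free or noisy plant step; u_eff is the activation actually applied
static inline void plant_step(const Arm &a, double q[2], double qd[2],
                              const double u_eff[6]) {
  // torque tau = t(A) %*% (fmax * u)
  double tau0 = 0.0, tau1 = 0.0;
  for (int i = 0; i < 6; ++i) {
    double f = a.fmax[i] * u_eff[i];
    tau0 += a.A[i] * f;        // column 1 of A
    tau1 += a.A[6 + i] * f;    // column 2 of A
  }
  double c2 = cos(q[1]);
  double m11 = a.k1 + 2.0 * a.k2 * c2;
  double m12 = a.k3 + a.k2 * c2;
  double m22 = a.k3;
  double s2 = sin(q[1]);
  double cor0 = -a.k2 * s2 * qd[1] * (2.0 * qd[0] + qd[1]);
  double cor1 = a.k2 * s2 * qd[0] * qd[0];
  double r0 = tau0 - cor0 - (a.B[0] * qd[0] + a.B[2] * qd[1]);
  double r1 = tau1 - cor1 - (a.B[1] * qd[0] + a.B[3] * qd[1]);
  double det = m11 * m22 - m12 * m12;
  double qdd0 = (m22 * r0 - m12 * r1) / det;
  double qdd1 = (-m12 * r0 + m11 * r1) / det;
  qd[0] += qdd0 * a.dt; qd[1] += qdd1 * a.dt;
  q[0] += qd[0] * a.dt; q[1] += qd[1] * a.dt;
  for (int j = 0; j < 2; ++j) {
    if (q[j] < a.qlo[j]) { q[j] = a.qlo[j]; qd[j] = 0.0; }
    if (q[j] > a.qhi[j]) { q[j] = a.qhi[j]; qd[j] = 0.0; }
  }
}

struct Net {
  int nh;
  const double *W1, *b1, *W2, *b2;   // views into theta
  double vel_scale;
  double qlo[2], qhi[2];
};

static inline void net_forward(const Net &n, const double q[2],
                               const double qd[2], double u[6]) {
  double x[4];
  x[0] = 2.0 * (q[0] - n.qlo[0]) / (n.qhi[0] - n.qlo[0]) - 1.0;
  x[1] = 2.0 * (q[1] - n.qlo[1]) / (n.qhi[1] - n.qlo[1]) - 1.0;
  x[2] = qd[0] / n.vel_scale;
  x[3] = qd[1] / n.vel_scale;
  std::vector<double> h(n.nh);
  for (int i = 0; i < n.nh; ++i) {
    double z = n.b1[i];
    for (int j = 0; j < 4; ++j) z += n.W1[j * n.nh + i] * x[j];
    h[i] = tanh(z);
  }
  for (int m = 0; m < 6; ++m) {
    double z = n.b2[m];
    for (int k = 0; k < n.nh; ++k) z += n.W2[k * 6 + m] * h[k];
    u[m] = 1.0 / (1.0 + exp(-z));
  }
}

// [[Rcpp::export]]
List rollout_cpp(NumericVector theta, int n_hidden, double vel_scale,
                 NumericVector q0, NumericVector qd0,
                 double k1, double k2, double k3,
                 NumericMatrix Bmat, NumericMatrix Amat,
                 NumericVector fmax,
                 double kappa, double dt,
                 NumericVector q_lower, NumericVector q_upper,
                 double l1, double l2,
                 double wall_y, int n_max,
                 int delay, double ke1, double ke2,
                 bool record) {
  Arm a;
  a.k1 = k1; a.k2 = k2; a.k3 = k3;
  for (int i = 0; i < 4; ++i) a.B[i] = Bmat[i];
  for (int i = 0; i < 12; ++i) a.A[i] = Amat[i];
  for (int i = 0; i < 6; ++i) a.fmax[i] = fmax[i];
  a.kappa = kappa; a.dt = dt;
  a.qlo[0] = q_lower[0]; a.qlo[1] = q_lower[1];
  a.qhi[0] = q_upper[0]; a.qhi[1] = q_upper[1];
  a.l1 = l1; a.l2 = l2;

  Net net;
  net.nh = n_hidden;
  net.W1 = &theta[0];
  net.b1 = &theta[4 * n_hidden];
  net.W2 = &theta[5 * n_hidden];
  net.b2 = &theta[5 * n_hidden + 6 * n_hidden];
  net.vel_scale = vel_scale;
  net.qlo[0] = a.qlo[0]; net.qlo[1] = a.qlo[1];
  net.qhi[0] = a.qhi[0]; net.qhi[1] = a.qhi[1];

  double q[2] = { q0[0], q0[1] };
  double qd[2] = { qd0[0], qd0[1] };
  double e1q[2] = { q[0], q[1] };       // open-loop estimate
  double e1qd[2] = { qd[0], qd[1] };

  int buf = delay > 0 ? delay : 1;
  std::vector<double> ubuf(6 * buf, 0.0);      // efference copies, ring
  std::vector<double> xbuf(4 * (buf + 1));     // true states, ring
  xbuf[0] = q[0]; xbuf[1] = q[1]; xbuf[2] = qd[0]; xbuf[3] = qd[1];

  NumericMatrix tab;
  if (record) tab = NumericMatrix(n_max, 13);

  double effort = 0.0;
  int status = 0;                // 0 timeout, >0 wall crossed
  double hit_x = NA_REAL, mt = NA_REAL, vx = NA_REAL, vy = NA_REAL;
  double px = l1 * cos(q[0]) + l2 * cos(q[0] + q[1]);
  double py = l1 * sin(q[0]) + l2 * sin(q[0] + q[1]);
  int steps = 0;

  for (int t = 0; t < n_max; ++t) {
    // --- state estimate
    double eq[2], eqd[2];
    if (t == 0) {
      eq[0] = q[0]; eq[1] = q[1]; eqd[0] = qd[0]; eqd[1] = qd[1];
    } else {
      // open-loop term advanced with u_{t-1} (done below after command);
      // closed-loop term: delayed truth rolled through buffered commands
      int avail = t < delay ? t : delay;
      int base = ((t - avail) % (buf + 1)) * 4;
      double cq[2] = { xbuf[base], xbuf[base + 1] };
      double cqd[2] = { xbuf[base + 2], xbuf[base + 3] };
      for (int s = t - avail; s < t; ++s) {
        const double *us = &ubuf[(s % buf) * 6];
        plant_step(a, cq, cqd, us);
      }
      double den = ke1 + ke2;
      eq[0] = (ke1 * e1q[0] + ke2 * cq[0]) / den;
      eq[1] = (ke1 * e1q[1] + ke2 * cq[1]) / den;
      eqd[0] = (ke1 * e1qd[0] + ke2 * cqd[0]) / den;
      eqd[1] = (ke1 * e1qd[1] + ke2 * cqd[1]) / den;
    }

    // --- controller
    double u[6];
    net_forward(net, eq, eqd, u);

    if (record) {
      tab(t, 0) = t * dt;
      tab(t, 1) = q[0]; tab(t, 2) = q[1];
      tab(t, 3) = qd[0]; tab(t, 4) = qd[1];
      for (int i = 0; i < 6; ++i) tab(t, 5 + i) = u[i];
      tab(t, 11) = px; tab(t, 12) = py;
    }

    // --- efference copy into buffer, advance open-loop estimate
    for (int i = 0; i < 6; ++i) ubuf[(t % buf) * 6 + i] = u[i];
    plant_step(a, e1q, e1qd, u);

    // --- true plant step under signal-dependent noise
    double u_eff[6];
    if (kappa > 0.0) {
      NumericVector z = Rcpp::rnorm(6);
      for (int i = 0; i < 6; ++i) {
        double v = u[i] * (1.0 + kappa * z[i]);
        u_eff[i] = v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
      }
    } else {
      for (int i = 0; i < 6; ++i) u_eff[i] = u[i];
    }
    plant_step(a, q, qd, u_eff);
    if (!(std::isfinite(q[0]) && std::isfinite(q[1]) &&
          std::isfinite(qd[0]) && std::isfinite(qd[1])))
      stop("non-finite dynamics at step %d", t);

    double eff = 0.0;
    for (int i = 0; i < 6; ++i) eff += u[i] * u[i];
    effort += eff * dt;

    int slot = ((t + 1) % (buf + 1)) * 4;
    xbuf[slot] = q[0]; xbuf[slot + 1] = q[1];
    xbuf[slot + 2] = qd[0]; xbuf[slot + 3] = qd[1];

    double nx = l1 * cos(q[0]) + l2 * cos(q[0] + q[1]);
    double ny = l1 * sin(q[0]) + l2 * sin(q[0] + q[1]);
    steps = t + 1;
    if (ny >= wall_y && py < wall_y) {
      double alpha = (wall_y - py) / (ny - py);
      hit_x = px + alpha * (nx - px);
      mt = (t + alpha) * dt;
      // Cartesian velocity at crossing from the Jacobian at the new state
      double s1 = sin(q[0]), c1 = cos(q[0]);
      double s12 = sin(q[0] + q[1]), c12 = cos(q[0] + q[1]);
      vx = (-l1 * s1 - l2 * s12) * qd[0] + (-l2 * s12) * qd[1];
      vy = (l1 * c1 + l2 * c12) * qd[0] + (l2 * c12) * qd[1];
      status = 1;
      px = nx; py = ny;
      break;
    }
    px = nx; py = ny;
  }

  List out = List::create(
    _["status"] = status, _["hit_x"] = hit_x, _["mt"] = mt,
    _["vx"] = vx, _["vy"] = vy, _["effort"] = effort,
    _["steps"] = steps);
  if (record) {
    out["table"] = tab(Range(0, steps - 1), Range(0, 12));
  }
  return out;
}
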