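#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Ramp-and-hold floor profile. The rate is defined on [onset, onset + duration)
// so that phi is continuous and phidot is piecewise constant.
static inline double floor_angle_c(double t, double onset, double dur, double amp) {
  if (t <= onset) return 0.0;
  if (t >= onset + dur) return amp;
  return amp * (t - onset) / dur;
}

static inline double floor_rate_c(double t, double onset, double dur, double amp) {
  // tolerance keeps corner samples consistent under floating jitter
  return (t >= onset - 1e-12 && t < onset + dur - 1e-12) ? amp / dur : 0.0;
}

struct Plant {
  double mgh, J, kP, kD;
  double onset, dur, amp;
};

// Deterministic drift of the pendulum with the control torque tau and the
// sampled noise torque w held constant over the step.
static inline void drift(const Plant &p, double th, double thd, double t,
                         double tau, double w, double &d1, double &d2) {
  const double phi  = floor_angle_c(t, p.onset, p.dur, p.amp);
  const double phid = floor_rate_c(t, p.onset, p.dur, p.amp);
  const double tauf = -p.kP * (th - phi) - p.kD * (thd - phid);
  d1 = thd;
  d2 = (p.mgh * std::sin(th) + tau + tauf + w) / p.J;
}

// Impulse-response sequences of the predicted angle used to assemble the
// preview gains: h[k] = C A^(k-1) B, f*[k] = C A^(k-1) Bd[, *], and the
// free-response rows Fm[k, ] = C A^k.
// [[Rcpp::export]]
List mpc_gain_aux_cpp(NumericMatrix A, NumericVector B, NumericMatrix Bd,
                      int Np) {
  NumericVector h(Np), fphi(Np), fphid(Np);
  NumericMatrix Fm(Np, 2);
  double r1 = 1.0, r2 = 0.0;
  for (int k = 0; k < Np; ++k) {
    h[k] = r1 * B[0] + r2 * B[1];
    fphi[k] = r1 * Bd(0, 0) + r2 * Bd(1, 0);
    fphid[k] = r1 * Bd(0, 1) + r2 * Bd(1, 1);
    const double n1 = r1 * A(0, 0) + r2 * A(1, 0);
    const double n2 = r1 * A(0, 1) + r2 * A(1, 1);
    r1 = n1; r2 = n2;
    Fm(k, 0) = r1; Fm(k, 1) = r2;
  }
  return List::create(_["h"] = h, _["fphi"] = fphi, _["fphid"] = fphid,
                      _["Fm"] = Fm);
}

// r[i] = sum_{j >= i} v[j] * f[j - i + 1] (1-based), the reversed
// cross-correlation that turns the dual vector into preview gains.
// [[Rcpp::export]]
NumericVector rev_xcorr_cpp(NumericVector v, NumericVector f) {
  const int n = v.size();
  NumericVector r(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = i; j < n; ++j) acc += v[j] * f[j - i];
    r[i] = acc;
  }
  return r;
}

// Closed-loop fixed-step integration of the stance pendulum.
//
// ctrl_type: 0 none, 1 linear PD, 2 nonlinear PD, 3 MPC preview gain.
// For PD controllers (g1, g2, g3) are gains in SI units acting on the delayed
// measurement. For MPC, (kx, ktau, kdphi, kdphid) are the precomputed preview
// gains and (A, B, Bd) the discrete internal model used for delay
// compensation; `preview` toggles knowledge of the future floor angle.
// integrator: 0 explicit Euler, 1 classical RK4 on the drift.
// [[Rcpp::export]]
List simulate_loop_cpp(int n, double dt, double t0,
                       double mgh, double J, double kP, double kD,
                       double onset, double dur, double amp,
                       NumericVector w, int ctrl_type,
                       double g1, double g2, double g3,
                       int delay_steps,
                       NumericVector kx, double ktau,
                       NumericVector kdphi, NumericVector kdphid,
                       NumericMatrix A, NumericVector B, NumericMatrix Bd,
                       bool preview, bool compensate, int integrator,
                       double blow, double theta0, double theta_dot0) {
  const Plant p = {mgh, J, kP, kD, onset, dur, amp};
  const int Np = kdphi.size();

  NumericVector theta(n), theta_dot(n), tau(n), tau_floor(n), phi(n);
  // floor samples, padded past the end of the window for the preview
  std::vector<double> phis(n + Np + 1), phids(n + Np + 1);
  for (int k = 0; k < n + Np + 1; ++k) {
    const double t = t0 + k * dt;
    phis[k]  = floor_angle_c(t, onset, dur, amp);
    phids[k] = floor_rate_c(t, onset, dur, amp);
  }

  double skdphi = 0.0;
  if (ctrl_type == 3 && !preview)
    for (int j = 0; j < Np; ++j) skdphi += kdphi[j];

  // The floor profile is piecewise linear (flat, ramp, hold), so the
  // preview inner products reduce to prefix sums of the gains: O(1) per
  // step instead of O(Np).
  std::vector<double> P1(Np + 1, 0.0), P2(Np + 1, 0.0), Q1(Np + 1, 0.0);
  int i1 = -1, i2 = -1;
  if (ctrl_type == 3 && preview) {
    for (int j = 0; j < Np; ++j) {
      P1[j + 1] = P1[j] + kdphi[j];
      P2[j + 1] = P2[j] + kdphi[j] * static_cast<double>(j);
      Q1[j + 1] = Q1[j] + kdphid[j];
    }
    for (int i = 0; i < n + Np + 1; ++i)
      if (phids[i] != 0.0) { if (i1 < 0) i1 = i; i2 = i; }
  }
  const double rate = (dur > 0) ? amp / dur : 0.0;
  const double c1 = rate * dt;                 // slope of phi per sample
  const double c0 = rate * (t0 - onset);       // phi at sample index 0 on ramp

  const double a11 = A(0, 0), a12 = A(0, 1), a21 = A(1, 0), a22 = A(1, 1);
  const double b1 = B[0], b2 = B[1];
  const double bd11 = Bd(0, 0), bd12 = Bd(0, 1), bd21 = Bd(1, 0), bd22 = Bd(1, 1);

  double th = theta0, thd = theta_dot0;
  int status = 0, stopstep = -1;

  for (int k = 0; k < n; ++k) {
    const double t = t0 + k * dt;
    theta[k] = th;
    theta_dot[k] = thd;
    phi[k] = phis[k];
    tau_floor[k] = -kP * (th - phis[k]) - kD * (thd - phids[k]);

    // delayed measurement (state was at rest before the window)
    const int km = k - delay_steps;
    double mth = theta0, mthd = theta_dot0;
    if (km >= 0) { mth = theta[km]; mthd = theta_dot[km]; }

    double u = 0.0;
    if (ctrl_type == 1) {
      u = -g1 * mth - g2 * mthd;
    } else if (ctrl_type == 2) {
      u = -g1 * mth * std::fabs(mth) - g2 * mth - g3 * mthd;
    } else if (ctrl_type == 3) {
      // optionally forward-predict the delayed measurement through the
      // internal model; otherwise the stale measurement is used as-is
      double x1 = mth, x2 = mthd;
      if (compensate) for (int i = km; i < k; ++i) {
        const double ui = (i >= 0) ? tau[i] : 0.0;
        const double pf = (i >= 0) ? phis[i] : floor_angle_c(t0 + i * dt, onset, dur, amp);
        const double pd = (i >= 0) ? phids[i] : floor_rate_c(t0 + i * dt, onset, dur, amp);
        const double nx1 = a11 * x1 + a12 * x2 + b1 * ui + bd11 * pf + bd12 * pd;
        const double nx2 = a21 * x1 + a22 * x2 + b2 * ui + bd21 * pf + bd22 * pd;
        x1 = nx1; x2 = nx2;
      }
      const double tau_prev = (k > 0) ? tau[k - 1] : 0.0;
      u = kx[0] * x1 + kx[1] * x2 + ktau * tau_prev;
      if (preview) {
        if (i1 < 0) {
          u += phis[k] * P1[Np];               // floor constant over preview
        } else {
          int jA = i1 - k, jB = i2 + 1 - k;
          jA = std::max(0, std::min(jA, Np));
          jB = std::max(0, std::min(jB, Np));
          u += (c0 + c1 * k) * (P1[jB] - P1[jA]) + c1 * (P2[jB] - P2[jA]) +
               amp * (P1[Np] - P1[jB]) + rate * (Q1[jB] - Q1[jA]);
        }
      } else {
        u += skdphi * phis[k];
      }
    }

    if (!std::isfinite(u)) { status = 2; stopstep = k; break; }
    tau[k] = u;

    if (k == n - 1) break;

    double d1, d2;
    if (integrator == 0) {
      drift(p, th, thd, t, u, w[k], d1, d2);
      th += dt * d1;
      thd += dt * d2;
    } else {
      double k1a, k1b, k2a, k2b, k3a, k3b, k4a, k4b;
      // the end-point stage stays inside [t, t+dt) so that a floor-rate
      // regime switch at the next sample boundary does not leak into this
      // step's quadrature
      const double te = t + dt * (1.0 - 1e-6);
      drift(p, th, thd, t, u, w[k], k1a, k1b);
      drift(p, th + 0.5 * dt * k1a, thd + 0.5 * dt * k1b, t + 0.5 * dt, u, w[k], k2a, k2b);
      drift(p, th + 0.5 * dt * k2a, thd + 0.5 * dt * k2b, t + 0.5 * dt, u, w[k], k3a, k3b);
      drift(p, th + dt * k3a, thd + dt * k3b, te, u, w[k], k4a, k4b);
      th += dt / 6.0 * (k1a + 2.0 * k2a + 2.0 * k3a + k4a);
      thd += dt / 6.0 * (k1b + 2.0 * k2b + 2.0 * k3b + k4b);
    }

    if (!std::isfinite(th) || !std::isfinite(thd) || std::fabs(th) > blow) {
      // the pendulum has fallen; freeze the trace instead of overflowing
      if (!std::isfinite(th)) th = (theta[k] >= 0) ? blow : -blow;
      th = std::max(std::min(th, blow), -blow);
      for (int j = k + 1; j < n; ++j) {
        theta[j] = th; theta_dot[j] = 0.0; tau[j] = 0.0;
        phi[j] = phis[j];
        tau_floor[j] = -kP * (th - phis[j]);
      }
      status = 1;
      stopstep = k + 1;
      break;
    }
  }

  return List::create(_["theta"] = theta, _["theta_dot"] = theta_dot,
                      _["tau"] = tau, _["tau_floor"] = tau_floor,
                      _["phi"] = phi, _["status"] = status,
                      _["step"] = stopstep);
}
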