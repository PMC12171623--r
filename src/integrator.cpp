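// Coupled Keller-Miksis bubble-cluster dynamics with Kelvin-Voigt wall
// stress, integrated by an adaptive Dormand-Prince 5(4) scheme.
//
// State layout: y = (R_1..R_q, U_1..U_q), U = dR/dt.  The wall
// accelerations solve a q x q linear system M a = b with
// M = diag(d) + cpf * 1 s^T (rank-one radiation coupling), handled by the
// Sherman-Morrison identity.  Window maxima (R/R0, |U|, and min R, from
// which the adiabatic core temperature follows) are accumulated over every
// accepted internal step plus interpolated sub-samples, so collapse spikes
// narrower than any fixed output grid still register.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct ClusterParams {
  int q;
  std::vector<double> R0;    // rest radii (m)
  std::vector<double> S;     // coupling strengths 2*pi*n^(1/3) (1/m)
  double rho, cl, sigma, mu, G, p0, pv, kappa;
  double pa, f;              // drive amplitude (Pa) and frequency (Hz)
  double cpf;                // coupling prefactor (parse switch, default 1)
};

// Liquid-side boundary pressure p_i at the bubble wall.  Terms are grouped
// so the rest state (R = R0, U = 0, no drive) gives exactly zero.
static inline double wall_pressure(const ClusterParams& P, int i,
                                   double R, double U, double ps) {
  const double R0 = P.R0[i];
  const double pg0 = P.p0 - P.pv + 2.0 * P.sigma / R0;
  const double x = std::pow(R0 / R, 3.0 * P.kappa);
  return pg0 * (x - 1.0) + 2.0 * P.sigma * (1.0 / R0 - 1.0 / R) -
         4.0 * P.mu * U / R -
         (4.0 * P.G / 3.0) * (1.0 - (R0 * R0 * R0) / (R * R * R)) - ps;
}

// dp_i/dt with the acceleration part (-4 mu Rdd / R) removed; that part is
// folded into the system diagonal as +4 mu / (rho cl).
static inline double wall_pressure_rate_explicit(const ClusterParams& P, int i,
                                                 double R, double U,
                                                 double dps) {
  const double R0 = P.R0[i];
  const double pg0 = P.p0 - P.pv + 2.0 * P.sigma / R0;
  const double pgas = pg0 * std::pow(R0 / R, 3.0 * P.kappa);
  return -3.0 * P.kappa * pgas * U / R + 2.0 * P.sigma * U / (R * R) +
         4.0 * P.mu * U * U / (R * R) -
         4.0 * P.G * (R0 * R0 * R0) * U / (R * R * R * R) - dps;
}

// RHS of the first-order system.  Returns false on a singular acceleration
// system or a non-positive radius.
static bool cluster_rhs(const ClusterParams& P, double t,
                        const std::vector<double>& y,
                        std::vector<double>& dy) {
  const int q = P.q;
  const double w = 2.0 * M_PI * P.f;
  const double ps = -P.pa * std::sin(w * t);
  const double dps = -P.pa * w * std::cos(w * t);

  std::vector<double> d(q), b(q), v(q);
  double couple_b = 0.0;
  for (int j = 0; j < q; ++j) {
    const double R = y[j], U = y[q + j];
    if (!(R > 0.0) || !std::isfinite(R) || !std::isfinite(U)) return false;
    couple_b += P.S[j] * 2.0 * R * U * U;
    v[j] = P.cpf * P.S[j] * R * R;
  }
  couple_b *= P.cpf;

  for (int i = 0; i < q; ++i) {
    const double R = y[i], U = y[q + i];
    const double p = wall_pressure(P, i, R, U, ps);
    const double expl = wall_pressure_rate_explicit(P, i, R, U, dps);
    d[i] = (1.0 - U / P.cl) * R + 4.0 * P.mu / (P.rho * P.cl);
    b[i] = (1.0 + U / P.cl) * p / P.rho + R / (P.rho * P.cl) * expl -
           1.5 * U * U * (1.0 - U / (3.0 * P.cl)) - couple_b;
    if (std::fabs(d[i]) < 1e-300) return false;
  }

  // Sherman-Morrison: (D + 1 v^T)^{-1} b
  double sb = 0.0, su = 0.0;
  for (int j = 0; j < q; ++j) {
    sb += v[j] * b[j] / d[j];
    su += v[j] / d[j];
  }
  const double denom = 1.0 + su;
  if (std::fabs(denom) < 1e-14) return false;
  for (int i = 0; i < q; ++i) {
    const double acc = b[i] / d[i] - (sb / denom) / d[i];
    dy[i] = y[q + i];
    dy[q + i] = acc;
    if (!std::isfinite(acc)) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".km_rhs_cpp")]]
NumericVector km_rhs_cpp(double t, NumericVector y, NumericVector R0,
                         NumericVector S, double rho, double cl, double sigma,
                         double mu, double G, double p0, double pv,
                         double kappa, double pa, double f, double cpf) {
  ClusterParams P;
  P.q = R0.size();
  P.R0 = as<std::vector<double>>(R0);
  P.S = as<std::vector<double>>(S);
  P.rho = rho; P.cl = cl; P.sigma = sigma; P.mu = mu; P.G = G;
  P.p0 = p0; P.pv = pv; P.kappa = kappa; P.pa = pa; P.f = f; P.cpf = cpf;
  std::vector<double> yv = as<std::vector<double>>(y);
  std::vector<double> dy(yv.size());
  if (!cluster_rhs(P, t, yv, dy))
    stop("singular or non-finite right-hand side at t = %g", t);
  return wrap(dy);
}

// Dormand-Prince 5(4) coefficients
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

struct WindowAcc {
  std::vector<double> Rmax, Rmin, Umax;
  void init(const std::vector<double>& R0) {
    Rmax = R0; Rmin = R0;
    Umax.assign(R0.size(), 0.0);
  }
  void update(const std::vector<double>& y, int q) {
    for (int i = 0; i < q; ++i) {
      if (y[i] > Rmax[i]) Rmax[i] = y[i];
      if (y[i] < Rmin[i]) Rmin[i] = y[i];
      const double u = std::fabs(y[q + i]);
      if (u > Umax[i]) Umax[i] = u;
    }
  }
};

// cubic Hermite interpolation between accepted steps
static inline void hermite(const std::vector<double>& y0,
                           const std::vector<double>& f0,
                           const std::vector<double>& y1,
                           const std::vector<double>& f1, double h,
                           double theta, std::vector<double>& out) {
  const double t2 = theta * theta, t3 = t2 * theta;
  const double h00 = 2 * t3 - 3 * t2 + 1, h10 = t3 - 2 * t2 + theta;
  const double h01 = -2 * t3 + 3 * t2, h11 = t3 - t2;
  for (size_t k = 0; k < y0.size(); ++k)
    out[k] = h00 * y0[k] + h10 * h * f0[k] + h01 * y1[k] + h11 * h * f1[k];
}

// [[Rcpp::export(name = ".km_integrate_cpp")]]
List km_integrate_cpp(NumericVector R0, NumericVector S, double rho, double cl,
                      double sigma, double mu, double G, double p0, double pv,
                      double kappa, double pa, double f, double n_cycles,
                      double win_lo, double win_hi, double rtol, double atol_R,
                      double atol_U, int samples_per_cycle, double max_steps,
                      double cpf, bool save_trajectory) {
  ClusterParams P;
  const int q = R0.size();
  P.q = q;
  P.R0 = as<std::vector<double>>(R0);
  P.S = as<std::vector<double>>(S);
  P.rho = rho; P.cl = cl; P.sigma = sigma; P.mu = mu; P.G = G;
  P.p0 = p0; P.pv = pv; P.kappa = kappa; P.pa = pa; P.f = f; P.cpf = cpf;

  const int n = 2 * q;
  const double period = 1.0 / f;
  const double t_end = n_cycles * period;
  const double t_win0 = win_lo * period, t_win1 = win_hi * period;

  std::vector<double> y = P.R0;
  y.resize(n, 0.0);
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n);
  std::vector<double> ytmp(n), y5(n), yint(n);

  // output grid
  const long n_out =
      save_trajectory ? (long)std::ceil(n_cycles * samples_per_cycle) + 1 : 0;
  NumericVector t_out(save_trajectory ? n_out : 0);
  NumericMatrix R_out(save_trajectory ? n_out : 0, save_trajectory ? q : 0);
  NumericMatrix U_out(save_trajectory ? n_out : 0, save_trajectory ? q : 0);
  long i_out = 0;
  const double dt_out = t_end / std::max<long>(n_out - 1, 1);
  if (save_trajectory) {
    t_out[0] = 0.0;
    for (int i = 0; i < q; ++i) { R_out(0, i) = y[i]; U_out(0, i) = y[q + i]; }
    i_out = 1;
  }

  WindowAcc win;
  win.init(P.R0);
  bool window_touched = false;

  double t = 0.0;
  double h = 1e-3 * period;  // initial guess; controller adapts quickly
  const double hmin = t_end * 1e-15;
  double steps = 0, rejected = 0;
  int status = 0;  // 0 completed, 1 failed
  double fail_time = NA_REAL;

  if (!cluster_rhs(P, t, y, k1)) {
    status = 1; fail_time = t;
  }

  while (status == 0 && t < t_end) {
    if (steps >= max_steps) { status = 1; fail_time = t; break; }
    if (h < hmin) { status = 1; fail_time = t; break; }
    if (t + h > t_end) h = t_end - t;

    bool ok = true;
    for (int k = 0; k < n; ++k) ytmp[k] = y[k] + h * a21 * k1[k];
    ok = ok && cluster_rhs(P, t + c2 * h, ytmp, k2);
    if (ok) {
      for (int k = 0; k < n; ++k)
        ytmp[k] = y[k] + h * (a31 * k1[k] + a32 * k2[k]);
      ok = cluster_rhs(P, t + c3 * h, ytmp, k3);
    }
    if (ok) {
      for (int k = 0; k < n; ++k)
        ytmp[k] = y[k] + h * (a41 * k1[k] + a42 * k2[k] + a43 * k3[k]);
      ok = cluster_rhs(P, t + c4 * h, ytmp, k4);
    }
    if (ok) {
      for (int k = 0; k < n; ++k)
        ytmp[k] = y[k] + h * (a51 * k1[k] + a52 * k2[k] + a53 * k3[k] +
                              a54 * k4[k]);
      ok = cluster_rhs(P, t + c5 * h, ytmp, k5);
    }
    if (ok) {
      for (int k = 0; k < n; ++k)
        ytmp[k] = y[k] + h * (a61 * k1[k] + a62 * k2[k] + a63 * k3[k] +
                              a64 * k4[k] + a65 * k5[k]);
      ok = cluster_rhs(P, t + h, ytmp, k6);
    }
    if (ok) {
      for (int k = 0; k < n; ++k)
        y5[k] = y[k] + h * (b1 * k1[k] + b3 * k3[k] + b4 * k4[k] +
                            b5 * k5[k] + b6 * k6[k]);
      // positivity of radii within the attempted step
      for (int i = 0; i < q; ++i)
        if (!(y5[i] > 0.0)) { ok = false; break; }
    }
    if (ok) ok = cluster_rhs(P, t + h, y5, k7);  // FSAL

    double err = 0.0;
    if (ok) {
      for (int k = 0; k < n; ++k) {
        const double ek = h * (e1 * k1[k] + e3 * k3[k] + e4 * k4[k] +
                               e5 * k5[k] + e6 * k6[k] + e7 * k7[k]);
        const double atol = (k < q) ? atol_R : atol_U;
        const double sc =
            atol + rtol * std::max(std::fabs(y[k]), std::fabs(y5[k]));
        const double r = ek / sc;
        err += r * r;
      }
      err = std::sqrt(err / n);
      if (!std::isfinite(err)) ok = false;
    }

    ++steps;
    if (ok && err <= 1.0) {
      // accepted: dense output + window accumulation
      const double t_new = t + h;
      if (save_trajectory) {
        while (i_out < n_out && i_out * dt_out <= t_new + 1e-12 * t_end) {
          const double ts = std::min(i_out * dt_out, t_new);
          hermite(y, k1, y5, k7, h, (ts - t) / h, yint);
          t_out[i_out] = ts;
          for (int i = 0; i < q; ++i) {
            R_out(i_out, i) = yint[i];
            U_out(i_out, i) = yint[q + i];
          }
          ++i_out;
        }
      }
      if (t_new >= t_win0 && t <= t_win1) {
        window_touched = true;
        // endpoints plus interior sub-samples of the interpolant
        if (t >= t_win0) win.update(y, q);
        if (t_new <= t_win1) win.update(y5, q);
        for (int ssub = 1; ssub <= 4; ++ssub) {
          const double th = ssub / 5.0;
          const double ts = t + th * h;
          if (ts >= t_win0 && ts <= t_win1) {
            hermite(y, k1, y5, k7, h, th, yint);
            win.update(yint, q);
          }
        }
      }
      t = t_new;
      y.swap(y5);
      k1.swap(k7);
      const double fac =
          std::min(5.0, std::max(0.2, 0.9 * std::pow(err + 1e-30, -0.2)));
      h *= fac;
    } else {
      ++rejected;
      h *= ok ? std::max(0.2, 0.9 * std::pow(err, -0.2)) : 0.25;
    }
  }

  if (save_trajectory && status == 0 && i_out < n_out) {
    // final point
    t_out[i_out] = t_end;
    for (int i = 0; i < q; ++i) {
      R_out(i_out, i) = y[i];
      U_out(i_out, i) = y[q + i];
    }
    ++i_out;
  }

  List traj = R_NilValue;
  if (save_trajectory) {
    t_out = head(t_out, i_out);
    R_out = R_out(Range(0, std::max<long>(i_out - 1, 0)), _);
    U_out = U_out(Range(0, std::max<long>(i_out - 1, 0)), _);
    traj = List::create(_["t"] = t_out, _["R"] = R_out, _["U"] = U_out);
  }

  return List::create(
      _["status"] = status, _["fail_time"] = fail_time,
      _["t_final"] = t,
      _["window_touched"] = window_touched,
      _["Rmax"] = wrap(win.Rmax), _["Rmin"] = wrap(win.Rmin),
      _["Umax"] = wrap(win.Umax),
      _["n_steps"] = steps, _["n_rejected"] = rejected,
      _["trajectory"] = traj);
}
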