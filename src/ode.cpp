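#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Model ids: 1 = forward five-compartment DOX transport (6 states:
// w1 systemic plasma, w3 peripheral, w2 tumor plasma, w4 tumor EES,
// w5 tumor intracellular, w_el cumulative eliminated),
// 2 = reverse-path signalling (4 states: v1, v2, mRNA, luciferase).
//
// Forward parameter layout (all rates per minute):
//   0 k12, 1 k21, 2 k10, 3 ps, 4 Fpv_t, 5 vp_t, 6 ve_t, 7 U_Dox,
//   8 U_Dox_e, 9 k1wi, 10 k2wi, 11 k3wi, 12 k5wi, 13 kiwi,
//   14 eq15_literal flag (0/1)
// Reverse parameter layout (per minute):
//   0 k12_r, 1 k21_r, 2 k1, 3 k10, 4 mu, 5 kr, 6 gamma_r, 7 kp, 8 gamma_p

static inline double uptake_term(double x, double w5, const double* p) {
  // k3wi * (k1wi*x + k2wi*x/(kiwi + x) - k5wi*w5); x is the EES-side
  // substrate (already carrying any protein-binding factor).
  if (p[14] > 0.5) {
    // literal rendering: both linear coefficients over one saturable
    // denominator
    return p[11] * ((p[9] * x + p[10] * x) / (p[13] + x) - p[12] * w5);
  }
  return p[11] * (p[9] * x + p[10] * x / (p[13] + x) - p[12] * w5);
}

static inline void rhs(int model, double t, const double* y, double* dy,
                       const double* p) {
  (void)t;  // both systems are autonomous
  if (model == 1) {
    const double w1 = y[0], w3 = y[1], w2 = y[2], w4 = y[3], w5 = y[4];
    const double x4e = w4 * p[8];
    dy[0] = -w1 * (p[0] + p[2]) + p[1] * w3;
    dy[1] = p[0] * w1 - p[1] * w3;
    dy[2] = -(p[3] / p[5]) * w2 * p[7] + (p[3] / p[5]) * w4 * p[8] -
            p[4] * w2 + p[4] * w1;
    dy[3] = (p[3] / p[6]) * w2 * p[7] - (p[3] / p[6]) * w4 * p[8] -
            uptake_term(x4e, w5, p);
    dy[4] = uptake_term(w4, w5, p);
    dy[5] = p[2] * w1;
  } else {
    const double v1 = y[0], v2 = y[1], m = y[2], lu = y[3];
    const double gr = p[2] * v1;  // receiver output k1 * v1
    dy[0] = p[1] * v2 - (p[0] + p[3] + p[2]) * v1;
    dy[1] = p[0] * v1 - p[1] * v2;
    dy[2] = p[5] * p[4] * gr - p[6] * m;
    dy[3] = p[7] * m - p[8] * lu;
  }
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
static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                    e3 = 500.0 / 1113 - 7571.0 / 16695,
                    e4 = 125.0 / 192 - 393.0 / 640,
                    e5 = -2187.0 / 6784 + 92097.0 / 339200,
                    e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

// Integrate one model from times[0] to times[n-1], reporting the state at
// every grid time. Steps never cross a grid point, so no dense-output
// interpolation error enters the reported states. States falling in
// [-neg_tol, 0) are clipped to zero; more negative values abort.
// If wsafe is finite, state component `wsafe_idx` is clipped at wsafe after
// every accepted step (hard safety projection); clip events are counted.
// [[Rcpp::export(name = ".sim_ode_cpp")]]
List sim_ode_cpp(int model, NumericVector y0, NumericVector pars,
                 NumericVector times, double rtol, double atol,
                 double wsafe, int wsafe_idx, double max_steps) {
  const int d = y0.size();
  const int nt = times.size();
  NumericMatrix out(nt, d);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> p(pars.begin(), pars.end());
  std::vector<double> k1(d), k2(d), k3(d), k4(d), k5(d), k6(d), k7(d),
      ytmp(d), ynew(d), yerr(d);
  const double neg_tol = 10.0 * atol;
  long clip_count = 0;
  double first_clip_time = NA_REAL;

  for (int j = 0; j < d; ++j) out(0, j) = y[j];
  double t = times[0];
  double h = 0.0;
  long nstep = 0;

  for (int i = 1; i < nt; ++i) {
    const double tend = times[i];
    if (!(tend > t))
      stop("time grid must be strictly increasing");
    if (h <= 0.0) h = std::min(1.0, tend - t);
    while (t < tend) {
      if (++nstep > (long)max_steps)
        stop("ODE integrator exceeded %d steps at t = %g (h = %g)",
             (long)max_steps, t, h);
      bool hit_end = false;
      if (h >= tend - t) {
        h = tend - t;
        hit_end = true;
      }
      rhs(model, t, y.data(), k1.data(), p.data());
      for (int j = 0; j < d; ++j) ytmp[j] = y[j] + h * a21 * k1[j];
      rhs(model, t + c2 * h, ytmp.data(), k2.data(), p.data());
      for (int j = 0; j < d; ++j)
        ytmp[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
      rhs(model, t + c3 * h, ytmp.data(), k3.data(), p.data());
      for (int j = 0; j < d; ++j)
        ytmp[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
      rhs(model, t + c4 * h, ytmp.data(), k4.data(), p.data());
      for (int j = 0; j < d; ++j)
        ytmp[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] +
                              a54 * k4[j]);
      rhs(model, t + c5 * h, ytmp.data(), k5.data(), p.data());
      for (int j = 0; j < d; ++j)
        ytmp[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                              a64 * k4[j] + a65 * k5[j]);
      rhs(model, t + h, ytmp.data(), k6.data(), p.data());
      for (int j = 0; j < d; ++j)
        ynew[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] +
                              b5 * k5[j] + b6 * k6[j]);
      rhs(model, t + h, ynew.data(), k7.data(), p.data());

      double errnorm = 0.0;
      for (int j = 0; j < d; ++j) {
        yerr[j] = h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] + e5 * k5[j] +
                       e6 * k6[j] + e7 * k7[j]);
        const double sc =
            atol + rtol * std::max(std::fabs(y[j]), std::fabs(ynew[j]));
        const double r = yerr[j] / sc;
        errnorm += r * r;
      }
      errnorm = std::sqrt(errnorm / d);

      if (errnorm <= 1.0) {  // accept
        t += h;
        for (int j = 0; j < d; ++j) {
          if (ynew[j] < 0.0) {
            if (ynew[j] >= -neg_tol) {
              ynew[j] = 0.0;
            } else {
              stop("state %d went negative (%g) at t = %g beyond tolerance",
                   j + 1, ynew[j], t);
            }
          }
          y[j] = ynew[j];
        }
        if (R_finite(wsafe) && y[wsafe_idx] > wsafe) {
          y[wsafe_idx] = wsafe;
          if (clip_count == 0) first_clip_time = t;
          ++clip_count;
        }
        double fac = errnorm > 0.0
                         ? 0.9 * std::pow(errnorm, -0.2)
                         : 5.0;
        h *= std::min(5.0, std::max(0.2, fac));
        if (hit_end) break;
      } else {  // reject
        double fac = 0.9 * std::pow(errnorm, -0.2);
        h *= std::min(1.0, std::max(0.1, fac));
        if (h < 1e-12)
          stop("step size underflow at t = %g (err = %g)", t, errnorm);
      }
    }
    for (int j = 0; j < d; ++j) out(i, j) = y[j];
  }
  return List::create(_["states"] = out, _["n_clip"] = (double)clip_count,
                      _["first_clip_time"] = first_clip_time,
                      _["n_steps"] = (double)nstep);
}

// Fixed-step explicit Euler oracle. Records every `thin`-th step (plus the
// initial and final states) and tracks the running maximum of component
// `track_idx` at full step resolution.
// [[Rcpp::export(name = ".sim_euler_cpp")]]
List sim_euler_cpp(int model, NumericVector y0, NumericVector pars,
                   double t0, double dt, double n_steps_d, int thin,
                   int track_idx) {
  const int d = y0.size();
  const long n_steps = (long)n_steps_d;
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> p(pars.begin(), pars.end());
  std::vector<double> dy(d);
  const long n_rec = n_steps / thin + 1;
  NumericMatrix out(n_rec + 1, d);
  NumericVector tout(n_rec + 1);
  long rec = 0;
  for (int j = 0; j < d; ++j) out(0, j) = y[j];
  tout[0] = t0;
  rec = 1;
  double ymax = y[track_idx], tmax = t0;
  for (long i = 1; i <= n_steps; ++i) {
    rhs(model, t0 + (i - 1) * dt, y.data(), dy.data(), p.data());
    for (int j = 0; j < d; ++j) {
      y[j] += dt * dy[j];
      if (y[j] < 0.0) y[j] = 0.0;
    }
    if (y[track_idx] > ymax) {
      ymax = y[track_idx];
      tmax = t0 + i * dt;
    }
    if (i % thin == 0 || i == n_steps) {
      if (rec <= n_rec) {
        for (int j = 0; j < d; ++j) out(rec, j) = y[j];
        tout[rec] = t0 + i * dt;
        ++rec;
      }
    }
  }
  NumericMatrix states(rec, d);
  NumericVector times(rec);
  for (long r = 0; r < rec; ++r) {
    times[r] = tout[r];
    for (int j = 0; j < d; ++j) states(r, j) = out(r, j);
  }
  return List::create(_["times"] = times, _["states"] = states,
                      _["t_peak"] = tmax, _["peak"] = ymax);
}

// Quadratic (logistic-type) chaotic map keystream:
// x_{n+1} = alpha * x_n * (1 - x_n) + beta, s_n = x_{n+1}.
// [[Rcpp::export(name = ".keystream_cpp")]]
NumericVector keystream_cpp(double alpha, double beta, double x0, int n) {
  NumericVector s(n);
  double x = x0;
  for (int i = 0; i < n; ++i) {
    x = alpha * x * (1.0 - x) + beta;
    if (!R_finite(x)) stop("chaotic iterate diverged at step %d", i + 1);
    s[i] = x;
  }
  return s;
}
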