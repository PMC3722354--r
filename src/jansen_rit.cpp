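#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Firing-rate sigmoid centred so that the resting state (all voltages 0)
// is a fixed point of the coupled system: s(0) = 0.
static inline double sigm0(double v, double e0, double v0, double r) {
  return 2.0 * e0 / (1.0 + std::exp(-r * (v - v0))) -
         2.0 * e0 / (1.0 + std::exp(r * v0));
}

struct JRSys {
  int n;
  const NumericMatrix &AF, &AB, &AL;  // [target, source]
  const NumericVector &selfgain, &Cin, &gamma;
  double He, Hi, ke, ki, e0, v0, r;
  double delay, onset, width, amp, dt;
  const std::vector<double> &hist;  // outputs, row-major [step * n + src]
  int filled;                       // highest filled step index in hist

  // pyramidal output of source j at absolute time t (s), linearly
  // interpolated from the step history; zero (resting) before t = 0
  double delayed_out(int j, double t) const {
    double pos = t / dt;
    if (pos <= 0.0) return 0.0;
    if (pos >= filled) return hist[(size_t)filled * n + j];
    int i0 = (int)std::floor(pos);
    double f = pos - i0;
    return hist[(size_t)i0 * n + j] * (1.0 - f) +
           hist[(size_t)(i0 + 1) * n + j] * f;
  }

  void deriv(const std::vector<double> &x, double t,
             std::vector<double> &dx) const {
    std::vector<double> sd(n);
    for (int j = 0; j < n; ++j)
      sd[j] = sigm0(delayed_out(j, t - delay), e0, v0, r);
    double u0 = amp * std::exp(-(t - onset) * (t - onset) /
                               (2.0 * width * width));
    for (int i = 0; i < n; ++i) {
      double ext_s = 0.0, ext_p = 0.0;
      for (int j = 0; j < n; ++j) {
        ext_s += (AF(i, j) + AL(i, j)) * sd[j];
        ext_p += (AB(i, j) + AL(i, j)) * sd[j];
      }
      const double *xi = &x[8 * i];
      double y = xi[2] - xi[4];  // pyramidal depolarization
      double in1 = gamma[0] * selfgain[i] * sigm0(y, e0, v0, r) + ext_s +
                   Cin[i] * u0;                      // -> spiny stellate
      double in2 = gamma[1] * sigm0(xi[0], e0, v0, r) + ext_p;  // -> pyr (exc)
      double in4 = gamma[2] * sigm0(y, e0, v0, r) + ext_p;      // -> inhib pop
      double in3 = gamma[3] * sigm0(xi[6], e0, v0, r);          // -> pyr (inh)
      double *d = &dx[8 * i];
      d[0] = xi[1]; d[1] = He * ke * in1 - 2.0 * ke * xi[1] - ke * ke * xi[0];
      d[2] = xi[3]; d[3] = He * ke * in2 - 2.0 * ke * xi[3] - ke * ke * xi[2];
      d[4] = xi[5]; d[5] = Hi * ki * in3 - 2.0 * ki * xi[5] - ki * ki * xi[4];
      d[6] = xi[7]; d[7] = He * ke * in4 - 2.0 * ke * xi[7] - ke * ke * xi[6];
    }
  }
};

// Fixed-step RK4 integration of the coupled multi-source three-population
// neural mass model with a uniform inter-source conduction delay.
// Returns the pyramidal depolarization (mV) per source: (nsteps+1) x n.
// [[Rcpp::export]]
NumericMatrix simulate_jr_cpp(int n, NumericMatrix AF, NumericMatrix AB,
                              NumericMatrix AL, NumericVector selfgain,
                              NumericVector Cin, double He, double Hi,
                              double taue, double taui, double e0, double v0,
                              double r, NumericVector gamma, double delay,
                              double onset, double width, double amp,
                              double dt, int nsteps, double guard) {
  std::vector<double> hist((size_t)(nsteps + 1) * n, 0.0);
  JRSys sys{n,  AF, AB, AL, selfgain, Cin, gamma,
            He, Hi, 1.0 / taue, 1.0 / taui, e0, v0, r,
            delay, onset, width, amp, dt, hist, 0};

  int m = 8 * n;
  std::vector<double> x(m, 0.0), k1(m), k2(m), k3(m), k4(m), xt(m);
  NumericMatrix out(nsteps + 1, n);
  for (int j = 0; j < n; ++j) out(0, j) = 0.0;

  for (int s = 0; s < nsteps; ++s) {
    double t = s * dt;
    sys.filled = s;
    sys.deriv(x, t, k1);
    for (int q = 0; q < m; ++q) xt[q] = x[q] + 0.5 * dt * k1[q];
    sys.deriv(xt, t + 0.5 * dt, k2);
    for (int q = 0; q < m; ++q) xt[q] = x[q] + 0.5 * dt * k2[q];
    sys.deriv(xt, t + 0.5 * dt, k3);
    for (int q = 0; q < m; ++q) xt[q] = x[q] + dt * k3[q];
    sys.deriv(xt, t + dt, k4);
    double vmax = 0.0;
    for (int q = 0; q < m; ++q) {
      x[q] += dt / 6.0 * (k1[q] + 2.0 * k2[q] + 2.0 * k3[q] + k4[q]);
      if (std::fabs(x[q]) > vmax) vmax = std::fabs(x[q]);
    }
    if (vmax > guard)
      stop("neural mass simulation diverged at t = %.1f ms (|state| = %.3g "
           "exceeds guard %.3g); parameter regime unstable", (t + dt) * 1e3,
           vmax, guard);
    for (int j = 0; j < n; ++j) {
      double y = x[8 * j + 2] - x[8 * j + 4];
      hist[(size_t)(s + 1) * n + j] = y;
      out(s + 1, j) = y;
    }
  }
  return out;
}
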