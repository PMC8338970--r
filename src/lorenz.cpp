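#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step RK4 integration of the Lorenz flow, returning successive local
// maxima of x(t) after the transient.  A sample strictly greater than both
// neighbours marks a maximum; its value is refined by the vertex of the
// parabola through the three samples.

struct LState { double x, y, z; };

static inline LState deriv(const LState &s, double sigma, double R, double b) {
  LState d;
  d.x = sigma * (s.y - s.x);
  d.y = s.x * (R - s.z) - s.y;
  d.z = s.x * s.y - b * s.z;
  return d;
}

static inline LState rk4_step(const LState &s, double dt, double sigma,
                              double R, double b) {
  LState k1 = deriv(s, sigma, R, b);
  LState t;
  t.x = s.x + 0.5 * dt * k1.x; t.y = s.y + 0.5 * dt * k1.y; t.z = s.z + 0.5 * dt * k1.z;
  LState k2 = deriv(t, sigma, R, b);
  t.x = s.x + 0.5 * dt * k2.x; t.y = s.y + 0.5 * dt * k2.y; t.z = s.z + 0.5 * dt * k2.z;
  LState k3 = deriv(t, sigma, R, b);
  t.x = s.x + dt * k3.x; t.y = s.y + dt * k3.y; t.z = s.z + dt * k3.z;
  LState k4 = deriv(t, sigma, R, b);
  LState out;
  out.x = s.x + dt * (k1.x + 2 * k2.x + 2 * k3.x + k4.x) / 6.0;
  out.y = s.y + dt * (k1.y + 2 * k2.y + 2 * k3.y + k4.y) / 6.0;
  out.z = s.z + dt * (k1.z + 2 * k2.z + 2 * k3.z + k4.z) / 6.0;
  return out;
}

// [[Rcpp::export]]
NumericVector lorenz_maxima_cpp(int n_maxima, double sigma, double R, double b,
                                double dt, double transient_time,
                                double max_time, double x0, double y0,
                                double z0) {
  if (n_maxima < 1) stop("n_maxima must be >= 1");
  if (dt <= 0) stop("dt must be positive");
  LState s;
  s.x = x0; s.y = y0; s.z = z0;
  const long n_transient = (long)std::ceil(transient_time / dt);
  const long n_cap = (long)std::ceil(max_time / dt);
  double xm2 = NA_REAL, xm1 = NA_REAL;
  NumericVector out(n_maxima);
  int found = 0;
  for (long i = 0; i < n_cap; ++i) {
    s = rk4_step(s, dt, sigma, R, b);
    if (!R_finite(s.x)) stop("Lorenz integration diverged (reduce dt)");
    if (i > n_transient && R_finite(xm2)) {
      if (xm1 > xm2 && xm1 > s.x) {
        const double denom = xm2 + s.x - 2.0 * xm1;
        double peak = xm1;
        if (denom < 0.0) {
          const double d = s.x - xm2;
          peak = xm1 - d * d / (8.0 * denom);
        }
        out[found++] = peak;
        if (found == n_maxima) return out;
      }
    }
    xm2 = xm1;
    xm1 = s.x;
  }
  stop("found only %d of %d requested maxima within the integration-time cap "
       "(%g time units); the orbit may have settled on a fixed point",
       found, n_maxima, max_time);
  return out; // unreached
}
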