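#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Forward iteration of the interval maps.  An orbit landing exactly on the
// fixed point 0 is degenerate (it stays there forever) and is reported as an
// error rather than returned: for the beta-x map with integer beta this is
// the generic fate of *every* double-precision forward orbit, see
// betax_backward_cpp below for the measure-faithful construction.

enum MapId { BETAX = 0, LOGISTIC = 1, SCHUSTER = 2, SKEWTENT = 3 };

static inline double step_map(int id, double x, double p) {
  switch (id) {
  case BETAX: {
    double v = p * x;
    return v - std::floor(v);
  }
  case LOGISTIC:
    return p * x * (1.0 - x);
  case SCHUSTER: {
    double v = x + std::pow(x, p);
    return v - std::floor(v);
  }
  case SKEWTENT:
    return (x <= p) ? x / p : (1.0 - x) / (1.0 - p);
  default:
    return NA_REAL;
  }
}

// [[Rcpp::export]]
NumericVector iterate_map_cpp(int map_id, double param, double x0, int n,
                              int transient) {
  if (n < 1) stop("n must be >= 1");
  if (transient < 0) stop("transient must be >= 0");
  if (!(x0 > 0.0 && x0 < 1.0)) stop("x0 must lie in the open unit interval");
  double x = x0;
  for (int t = 0; t < transient; ++t) {
    x = step_map(map_id, x, param);
    if (x == 0.0)
      stop("degenerate orbit: iterate hit the fixed point 0 during the "
           "transient (step %d)", t + 1);
  }
  NumericVector out(n);
  for (int t = 0; t < n; ++t) {
    out[t] = x;
    x = step_map(map_id, x, param);
    if (x == 0.0 && t < n - 1)
      stop("degenerate orbit: iterate hit the fixed point 0 at step %d",
           transient + t + 1);
  }
  return out;
}

// Exact backward construction for the beta-x map with integer beta: draw the
// endpoint from the (uniform) invariant measure, pull back through uniformly
// chosen inverse branches y_{k+1} = (y_k + b_k)/beta, and reverse.  The
// reversed sequence satisfies x_{t+1} = beta x_t mod 1 to within 1 ulp and
// never collapses, unlike forward double-precision iteration.

// [[Rcpp::export]]
NumericVector betax_backward_cpp(double y0, IntegerVector branches,
                                 int beta) {
  const int n = branches.size() + 1;
  NumericVector y(n);
  y[0] = y0;
  for (int k = 1; k < n; ++k)
    y[k] = (y[k - 1] + branches[k - 1]) / beta;
  NumericVector out(n);
  for (int t = 0; t < n; ++t) out[t] = y[n - 1 - t];
  return out;
}
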