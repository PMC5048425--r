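#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 integration of a radially relaxing (Poincare-type)
// limit-cycle oscillator with gated photic forcing on the first state
// variable:
//
//   dx/dt = stiffness * x * (1 - r) - (2*pi/tau) * y + F(t) * s(x)
//   dy/dt = stiffness * y * (1 - r) + (2*pi/tau) * x,   r = sqrt(x^2+y^2)
//
// with photic sensitivity s(x) = max(0, -x) + leak. The max(0, -x)
// term gates light input to the half-cycle where x < 0 (subjective
// night), producing a type-1 phase response curve with delays in early
// subjective night, advances in late subjective night and a dead zone
// throughout subjective day, the canonical nocturnal rodent PRC shape;
// the small constant leak keeps the dead zone weakly responsive (real
// dead zones are shallow, not absolute), which controls how fast an
// out-of-phase oscillator is captured by a new schedule.
//
// The forcing F is piecewise constant over regimen samples of width
// `sample_h` hours; each sample is integrated with `substeps` RK4 steps,
// so step discontinuities in F always coincide with step boundaries.
// Returns the state at every sample boundary: (n_samples + 1) x 2.

static inline void deriv(double x, double y, double omega, double g,
                         double F, double leak, double &dx, double &dy) {
  double r = sqrt(x * x + y * y);
  dx = g * x * (1.0 - r) - omega * y + F * (std::max(0.0, -x) + leak);
  dy = g * y * (1.0 - r) + omega * x;
}

// [[Rcpp::export]]
NumericMatrix rk4_limit_cycle(NumericVector state0, double tau,
                              double stiffness, NumericVector forcing,
                              double sample_h, int substeps, double leak) {
  if (state0.size() != 2) stop("state0 must have length 2");
  if (substeps < 1) stop("substeps must be >= 1");
  const int n = forcing.size();
  const double omega = 2.0 * M_PI / tau;
  const double h = sample_h / substeps;
  NumericMatrix out(n + 1, 2);
  double x = state0[0], y = state0[1];
  out(0, 0) = x;
  out(0, 1) = y;
  for (int i = 0; i < n; ++i) {
    const double F = forcing[i];
    for (int s = 0; s < substeps; ++s) {
      double k1x, k1y, k2x, k2y, k3x, k3y, k4x, k4y;
      deriv(x, y, omega, stiffness, F, leak, k1x, k1y);
      deriv(x + 0.5 * h * k1x, y + 0.5 * h * k1y, omega, stiffness, F, leak, k2x, k2y);
      deriv(x + 0.5 * h * k2x, y + 0.5 * h * k2y, omega, stiffness, F, leak, k3x, k3y);
      deriv(x + h * k3x, y + h * k3y, omega, stiffness, F, leak, k4x, k4y);
      x += h / 6.0 * (k1x + 2.0 * k2x + 2.0 * k3x + k4x);
      y += h / 6.0 * (k1y + 2.0 * k2y + 2.0 * k3y + k4y);
    }
    if (!R_finite(x) || !R_finite(y))
      stop("oscillator state became non-finite at sample %d", i + 1);
    out(i + 1, 0) = x;
    out(i + 1, 1) = y;
  }
  return out;
}
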