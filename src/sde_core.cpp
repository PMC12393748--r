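#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of dX = b(X) dt + c dW with b = -grad U and
// U a sum of inverted Gaussian wells. c may vary per step (piecewise
// schedules, e.g. month-dependent diffusion). Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix sde_sim_cpp(NumericVector x0, int n_steps, double dt,
                          NumericVector c_step,
                          NumericMatrix centres,
                          NumericVector depths,
                          NumericVector widths) {
  if (n_steps < 1) stop("n_steps must be >= 1");
  if (dt <= 0) stop("dt must be positive");
  const int K = depths.size();
  NumericMatrix out(n_steps + 1, 2);
  double x = x0[0], y = x0[1];
  out(0, 0) = x;
  out(0, 1) = y;
  const double sqdt = std::sqrt(dt);
  for (int k = 0; k < n_steps; ++k) {
    double bx = 0.0, by = 0.0;
    for (int j = 0; j < K; ++j) {
      const double dx = x - centres(j, 0);
      const double dy = y - centres(j, 1);
      const double w2 = widths[j] * widths[j];
      const double e = depths[j] * std::exp(-(dx * dx + dy * dy) / (2.0 * w2)) / w2;
      bx -= dx * e;
      by -= dy * e;
    }
    const double c = c_step[k % c_step.size()];
    x += bx * dt + c * sqdt * norm_rand();
    y += by * dt + c * sqdt * norm_rand();
    if (!std::isfinite(x) || !std::isfinite(y))
      stop("non-finite position at step %d: drift blow-up (reduce dt or well depth)", k + 1);
    out(k + 1, 0) = x;
    out(k + 1, 1) = y;
  }
  return out;
}
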