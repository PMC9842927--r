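#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Euler-Maruyama integration of the coupled Stuart-Landau (Hopf normal form)
// system:
//   dx_i = [(a_i - x_i^2 - y_i^2) x_i - w_i y_i + G sum_j C_ij (x_j - x_i)] dt
//          + beta sqrt(dt) eta
//   dy_i = [(a_i - x_i^2 - y_i^2) y_i + w_i x_i + G sum_j C_ij (y_j - y_i)] dt
//          + beta sqrt(dt) eta
// C_ij is read column-to-row: entry (i, j) couples source j into target i.
// Noise comes from R's RNG (norm_rand) so a set.seed() upstream makes the
// trajectory fully reproducible; draw order is x then y within each node.
//
// Returns an N x n_volumes matrix of x, sampled every steps_per_tr steps
// after burn_steps steps are discarded.
// [[Rcpp::export(name = ".hopf_integrate")]]
NumericMatrix hopf_integrate(const NumericMatrix& ec,
                             const NumericVector& a,
                             const NumericVector& omega,
                             double G, double beta, double dt,
                             int steps_per_tr, int n_volumes, int burn_steps,
                             const NumericVector& x0,
                             const NumericVector& y0) {
  const int N = a.size();
  if (ec.nrow() != N || ec.ncol() != N)
    stop("ec must be %d x %d", N, N);
  if (x0.size() != N || y0.size() != N)
    stop("initial state dimension mismatch");

  NumericMatrix out(N, n_volumes);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> xn(N), yn(N);
  const double sq = beta * std::sqrt(dt);
  const bool noisy = beta > 0.0;
  const long total = (long)burn_steps + (long)steps_per_tr * n_volumes;

  // Pre-scan sparsity: most ground-truth matrices are sparse.
  std::vector<std::vector<int> > nbr(N);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j)
      if (ec(i, j) != 0.0 && i != j) nbr[i].push_back(j);

  RNGScope scope;
  int vol = 0;
  for (long s = 0; s < total; ++s) {
    for (int i = 0; i < N; ++i) {
      const double r2 = x[i] * x[i] + y[i] * y[i];
      double cx = 0.0, cy = 0.0;
      const std::vector<int>& nb = nbr[i];
      for (size_t k = 0; k < nb.size(); ++k) {
        const int j = nb[k];
        const double c = ec(i, j);
        cx += c * (x[j] - x[i]);
        cy += c * (y[j] - y[i]);
      }
      xn[i] = x[i] + dt * ((a[i] - r2) * x[i] - omega[i] * y[i] + G * cx);
      yn[i] = y[i] + dt * ((a[i] - r2) * y[i] + omega[i] * x[i] + G * cy);
      if (noisy) {
        xn[i] += sq * norm_rand();
        yn[i] += sq * norm_rand();
      }
      if (!std::isfinite(xn[i]) || !std::isfinite(yn[i]))
        stop("numerical blow-up (non-finite state) at step %ld, node %d: reduce dt",
             s + 1, i + 1);
    }
    x.swap(xn);
    y.swap(yn);
    if (s >= burn_steps && ((s - burn_steps + 1) % steps_per_tr) == 0) {
      for (int i = 0; i < N; ++i) out(i, vol) = x[i];
      if (++vol == n_volumes) break;
    }
    if ((s & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  if (vol != n_volumes) stop("internal error: recorded %d of %d volumes", vol, n_volumes);
  return out;
}
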