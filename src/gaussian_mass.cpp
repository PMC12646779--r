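#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Accumulate weighted isotropic bivariate Gaussian probability mass onto a
// regular grid by the cell-centre approximation (density at centre times cell
// area). Shared kernel of the BBMM and KUD estimators: each component is one
// bridge integration step or one kernel centre. Components are truncated at
// `trunc` standard deviations; callers renormalize afterwards.
//
// Grid convention: cell (r, c) (1-based in R) has centre
//   x = x0 + (c - 0.5) * cell,  y = y0 + (r - 0.5) * cell.
// [[Rcpp::export]]
NumericMatrix gaussian_mass_grid(int n_rows, int n_cols,
                                 double x0, double y0, double cell,
                                 NumericVector mu_x, NumericVector mu_y,
                                 NumericVector sd, NumericVector w,
                                 double trunc = 6.0) {
  NumericMatrix mass(n_rows, n_cols);
  const int n = mu_x.size();
  const double area = cell * cell;
  for (int i = 0; i < n; ++i) {
    const double s = sd[i];
    if (!(trunc * s > 0.5 * cell)) {
      // component (much) narrower than a cell: all mass in the containing cell
      int c = (int)std::floor((mu_x[i] - x0) / cell);
      int r = (int)std::floor((mu_y[i] - y0) / cell);
      if (r >= 0 && r < n_rows && c >= 0 && c < n_cols) mass(r, c) += w[i];
      continue;
    }
    const double reach = trunc * s;
    int c0 = (int)std::floor((mu_x[i] - reach - x0) / cell);
    int c1 = (int)std::floor((mu_x[i] + reach - x0) / cell);
    int r0 = (int)std::floor((mu_y[i] - reach - y0) / cell);
    int r1 = (int)std::floor((mu_y[i] + reach - y0) / cell);
    if (c0 < 0) c0 = 0;
    if (r0 < 0) r0 = 0;
    if (c1 >= n_cols) c1 = n_cols - 1;
    if (r1 >= n_rows) r1 = n_rows - 1;
    if (c1 < c0 || r1 < r0) continue;
    const double inv2s2 = 1.0 / (2.0 * s * s);
    const double norm = w[i] * area / (2.0 * M_PI * s * s);
    for (int c = c0; c <= c1; ++c) {
      const double dx = x0 + (c + 0.5) * cell - mu_x[i];
      const double ex = std::exp(-dx * dx * inv2s2);
      for (int r = r0; r <= r1; ++r) {
        const double dy = y0 + (r + 0.5) * cell - mu_y[i];
        mass(r, c) += norm * ex * std::exp(-dy * dy * inv2s2);
      }
    }
  }
  return mass;
}
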