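#include <Rcpp.h>
#include <algorithm>
#include <cfloat>
#include <vector>

using namespace Rcpp;

// Median of a scratch buffer; even lengths take the midpoint of the two
// central order statistics (same arithmetic as stats::median for doubles).
static double med_inplace(std::vector<double> &v) {
  const std::size_t n = v.size();
  std::sort(v.begin(), v.end());
  if (n % 2 == 1) return v[n / 2];
  return 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

// Two-way median polish of a P x T matrix.
//
// Alternates full row (probe) then column (array) median sweeps.  After each
// full sweep the sum of absolute residuals is compared against the previous
// one; the fit stops when the reduction falls below tol * (initial sum +
// epsilon) or when the residuals vanish, up to max_iter sweeps.  Effects are
// median-centered at the end with the centering constants folded into an
// explicit overall term, so that
//   x[p, t] == overall + row_eff[p] + col_eff[t] + residual[p, t]
// holds exactly.
// [[Rcpp::export]]
List median_polish_cpp(NumericMatrix x, int max_iter, double tol) {
  const int P = x.nrow(), T = x.ncol();
  NumericMatrix z = clone(x);
  std::vector<double> re(P, 0.0), ce(T, 0.0), buf;

  double init_sum = 0.0;
  for (int j = 0; j < T; ++j)
    for (int i = 0; i < P; ++i) init_sum += std::abs(z(i, j));

  double oldsum = R_PosInf;
  bool converged = false;
  int iters = 0;

  for (int it = 1; it <= max_iter; ++it) {
    iters = it;
    // row sweep
    for (int i = 0; i < P; ++i) {
      buf.assign(T, 0.0);
      for (int j = 0; j < T; ++j) buf[j] = z(i, j);
      const double m = med_inplace(buf);
      for (int j = 0; j < T; ++j) z(i, j) -= m;
      re[i] += m;
    }
    // column sweep
    for (int j = 0; j < T; ++j) {
      buf.assign(P, 0.0);
      for (int i = 0; i < P; ++i) buf[i] = z(i, j);
      const double m = med_inplace(buf);
      for (int i = 0; i < P; ++i) z(i, j) -= m;
      ce[j] += m;
    }
    double newsum = 0.0;
    for (int j = 0; j < T; ++j)
      for (int i = 0; i < P; ++i) newsum += std::abs(z(i, j));
    if (newsum == 0.0 || (oldsum - newsum) < tol * (init_sum + DBL_EPSILON)) {
      converged = true;
      break;
    }
    oldsum = newsum;
  }

  buf = re;
  const double mr = med_inplace(buf);
  buf = ce;
  const double mc = med_inplace(buf);
  NumericVector row_eff(P), col_eff(T);
  for (int i = 0; i < P; ++i) row_eff[i] = re[i] - mr;
  for (int j = 0; j < T; ++j) col_eff[j] = ce[j] - mc;

  return List::create(_["overall"] = mr + mc, _["row_effects"] = row_eff,
                      _["col_effects"] = col_eff, _["residuals"] = z,
                      _["converged"] = converged, _["n_iterations"] = iters);
}
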