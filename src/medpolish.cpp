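#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static double med_inplace(std::vector<double>& v) {
  const size_t n = v.size();
  const size_t k = n / 2;
  std::nth_element(v.begin(), v.begin() + k, v.end());
  double hi = v[k];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(v.begin(), v.begin() + k);
  return 0.5 * (lo + hi);
}

// Iterated row/column median sweeps of the additive two-way model
// (rows swept before columns each iteration). Exact decomposition:
// overall + row + col + residual == input at every step.
// [[Rcpp::export(name = ".medpolish_cpp")]]
List medpolish_cpp(NumericMatrix mat, int max_iter, double tol) {
  const int nr = mat.nrow(), nc = mat.ncol();
  NumericMatrix r(clone(mat));
  NumericVector row_eff(nr), col_eff(nc);
  double overall = 0.0;
  bool converged = false;
  int iter = 0;
  std::vector<double> buf;
  NumericMatrix old(nr, nc);
  for (iter = 1; iter <= max_iter; ++iter) {
    std::copy(r.begin(), r.end(), old.begin());
    // row sweep
    for (int i = 0; i < nr; ++i) {
      buf.assign(nc, 0.0);
      for (int j = 0; j < nc; ++j) buf[j] = r(i, j);
      double m = med_inplace(buf);
      for (int j = 0; j < nc; ++j) r(i, j) -= m;
      row_eff[i] += m;
    }
    buf.assign(row_eff.begin(), row_eff.end());
    double d = med_inplace(buf);
    for (int i = 0; i < nr; ++i) row_eff[i] -= d;
    overall += d;
    // column sweep
    for (int j = 0; j < nc; ++j) {
      buf.assign(nr, 0.0);
      for (int i = 0; i < nr; ++i) buf[i] = r(i, j);
      double m = med_inplace(buf);
      for (int i = 0; i < nr; ++i) r(i, j) -= m;
      col_eff[j] += m;
    }
    buf.assign(col_eff.begin(), col_eff.end());
    d = med_inplace(buf);
    for (int j = 0; j < nc; ++j) col_eff[j] -= d;
    overall += d;
    double delta = 0.0;
    for (int k = 0; k < nr * nc; ++k)
      delta = std::max(delta, std::abs(r[k] - old[k]));
    if (delta <= tol) { converged = true; break; }
  }
  return List::create(_["overall"] = overall, _["row_effects"] = row_eff,
                      _["col_effects"] = col_eff, _["residuals"] = r,
                      _["converged"] = converged,
                      _["iterations"] = std::min(iter, max_iter));
}
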