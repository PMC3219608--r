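#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// median of the finite entries of a buffer; NaN when empty
static double med(std::vector<double> &buf) {
  if (buf.empty()) return NA_REAL;
  size_t n = buf.size();
  std::sort(buf.begin(), buf.end());
  if (n % 2 == 1) return buf[n / 2];
  return 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
}

// Median polish of a matrix with NAs: alternately sweeps row and column
// medians out of the residuals until the total absolute residual stops
// improving (relative eps) or maxiter is reached. Returns the additive
// row and column effects (overall effect left in the residuals, as the
// caller rescales by the plate median anyway).
// [[Rcpp::export(name = ".med_polish")]]
List med_polish(NumericMatrix x, double eps = 1e-10, int maxiter = 30) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix r = clone(x);
  NumericVector re(nr), ce(nc);
  std::vector<double> buf;
  double oldsum = 0.0;
  for (int it = 0; it < maxiter; ++it) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int j = 0; j < nc; ++j)
        if (R_finite(r(i, j))) buf.push_back(r(i, j));
      double m = med(buf);
      if (R_finite(m)) {
        re[i] += m;
        for (int j = 0; j < nc; ++j)
          if (R_finite(r(i, j))) r(i, j) -= m;
      }
    }
    for (int j = 0; j < nc; ++j) {
      buf.clear();
      for (int i = 0; i < nr; ++i)
        if (R_finite(r(i, j))) buf.push_back(r(i, j));
      double m = med(buf);
      if (R_finite(m)) {
        ce[j] += m;
        for (int i = 0; i < nr; ++i)
          if (R_finite(r(i, j))) r(i, j) -= m;
      }
    }
    double newsum = 0.0;
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < nc; ++j)
        if (R_finite(r(i, j))) newsum += std::abs(r(i, j));
    if (newsum == 0.0 || (it > 0 && std::abs(newsum - oldsum) < eps * newsum))
      break;
    oldsum = newsum;
  }
  return List::create(_["row"] = re, _["col"] = ce);
}
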