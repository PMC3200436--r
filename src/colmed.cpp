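#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// median of each column; used by the iteratively reweighted averager
// [[Rcpp::export]]
NumericVector col_medians(const NumericMatrix& x) {
  const int n = x.nrow(), m = x.ncol();
  NumericVector out(m);
  std::vector<double> buf(n);
  const int h = n / 2;
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) buf[i] = x(i, j);
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double med = buf[h];
    if (n % 2 == 0) {
      med = 0.5 * (med + *std::max_element(buf.begin(), buf.begin() + h));
    }
    out[j] = med;
  }
  return out;
}
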