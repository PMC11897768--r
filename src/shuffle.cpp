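#include <Rcpp.h>
using namespace Rcpp;

// Null distribution of the mean inter-trial correlation under independent
// circular shifts of each trial's standardized bin vector.
//
// z: bins x trials matrix, each column standardized (mean 0, unit sample
//    variance; all-zero columns allowed for zero-variance trials).
// offsets: n_shuffles x trials matrix of circular shifts in [0, bins).
//
// Returns ||sum_t shift(z_t)||^2 per shuffle; the caller converts to the
// mean pairwise correlation via (out - sum||z_t||^2) / (2 (B-1) P).
// [[Rcpp::export]]
NumericVector cpp_shift_null(const NumericMatrix& z,
                             const IntegerMatrix& offsets) {
  const int b = z.nrow(), t = z.ncol(), ns = offsets.nrow();
  NumericVector out(ns);
  std::vector<double> s(b);
  for (int sh = 0; sh < ns; ++sh) {
    std::fill(s.begin(), s.end(), 0.0);
    for (int j = 0; j < t; ++j) {
      const int off = offsets(sh, j);
      const double* col = &z(0, j);
      // s[i] += z[(i + off) % b]
      int k = off;
      for (int i = 0; i < b; ++i) {
        s[i] += col[k];
        if (++k == b) k = 0;
      }
    }
    double acc = 0.0;
    for (int i = 0; i < b; ++i) acc += s[i] * s[i];
    out[sh] = acc;
  }
  return out;
}
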