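#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR/FIR filter with explicit state carry.
// a is assumed normalized (a[0] == 1). State z has length
// max(length(b), length(a)) - 1. Batch and streaming callers share this
// kernel, so per-sample arithmetic (and therefore rounding) is identical
// whether a signal is processed in one call or sample by sample.
// [[Rcpp::export]]
List df2t_filter(NumericVector b, NumericVector a, NumericVector x,
                 NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nz = std::max(nb, na) - 1;
  if (zi.size() != nz)
    stop("filter state length %d does not match expected %d", (int)zi.size(), nz);
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector z = clone(zi);
  int n = x.size();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int j = 0; j < nz - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    if (nz > 0)
      z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return List::create(_["y"] = y, _["zf"] = z);
}
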