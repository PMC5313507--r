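#include <Rcpp.h>
using namespace Rcpp;

// Direct form II transposed IIR recursion with caller-supplied initial
// state (length max(length(a), length(b)) - 1, a normalized so a[0] = 1).
// The zero-phase wrapper in R supplies steady-state initial conditions and
// odd-extension padding, then runs this forward and backward.

// [[Rcpp::export(name = ".iir_filter_cpp")]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nz = std::max(na, nb) - 1;
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0), z(nz, 0.0);
  for (int k = 0; k < nb; ++k) bb[k] = b[k];
  for (int k = 0; k < na; ++k) aa[k] = a[k];
  for (int k = 0; k < nz && k < zi.size(); ++k) z[k] = zi[k];

  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int k = 0; k < nz - 1; ++k)
      z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
    if (nz > 0) z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return y;
}
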