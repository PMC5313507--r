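#include <Rcpp.h>
using namespace Rcpp;

// Banded (Sakoe-Chiba) accumulated-cost DTW. Cells with |i - j| > w are never
// filled and read as +Inf, so the recurrence min() skips them naturally.
// Cost of matching sample i of x1 with sample j of x2 is the squared
// difference; the distance reported by the R wrappers is the square root of
// the (l1, l2) corner entry.

// Full l1 x l2 matrix (tests, plots, backtracking). Memory O(l1 * l2).
// [[Rcpp::export(name = ".dtw_cost_matrix_cpp")]]
NumericMatrix dtw_cost_matrix_cpp(NumericVector x1, NumericVector x2, int w) {
  const int l1 = x1.size(), l2 = x2.size();
  NumericMatrix m(l1, l2);
  std::fill(m.begin(), m.end(), R_PosInf);
  for (int i = 0; i < l1; ++i) {
    const int jlo = std::max(0, i - w), jhi = std::min(l2 - 1, i + w);
    for (int j = jlo; j <= jhi; ++j) {
      double c = x1[i] - x2[j];
      c *= c;
      double best;
      if (i == 0 && j == 0) {
        best = 0.0;
      } else if (i == 0) {
        best = m(0, j - 1);
      } else if (j == 0) {
        best = m(i - 1, 0);
      } else {
        best = m(i - 1, j - 1);
        if (m(i - 1, j) < best) best = m(i - 1, j);
        if (m(i, j - 1) < best) best = m(i, j - 1);
      }
      m(i, j) = c + best;
    }
  }
  return m;
}

// Corner entry only, band storage: two rolling rows, memory O(l2).
static double dtw_corner_one(const double* x1, int l1,
                             const double* x2, int l2,
                             int w, std::vector<double>& prev,
                             std::vector<double>& cur) {
  std::fill(prev.begin(), prev.end(), R_PosInf);
  std::fill(cur.begin(), cur.end(), R_PosInf);
  for (int i = 0; i < l1; ++i) {
    const int jlo = std::max(0, i - w), jhi = std::min(l2 - 1, i + w);
    if (jlo > 0) cur[jlo - 1] = R_PosInf;
    for (int j = jlo; j <= jhi; ++j) {
      double c = x1[i] - x2[j];
      c *= c;
      double best;
      if (i == 0 && j == 0) {
        best = 0.0;
      } else if (i == 0) {
        best = cur[j - 1];
      } else if (j == 0) {
        best = prev[0];
      } else {
        best = prev[j - 1];
        if (prev[j] < best) best = prev[j];
        if (cur[j - 1] < best) best = cur[j - 1];
      }
      cur[j] = c + best;
    }
    if (jhi + 1 < l2) cur[jhi + 1] = R_PosInf;
    std::swap(prev, cur);
  }
  return prev[l2 - 1];
}

// [[Rcpp::export(name = ".dtw_corner_cpp")]]
double dtw_corner_cpp(NumericVector x1, NumericVector x2, int w) {
  std::vector<double> prev(x2.size(), R_PosInf), cur(x2.size(), R_PosInf);
  return dtw_corner_one(x1.begin(), x1.size(), x2.begin(), x2.size(), w,
                        prev, cur);
}

// One reference series against every row of a matrix (seed maps, matrices).
// series is n_series x n_time; returns corner entries.
// [[Rcpp::export(name = ".dtw_corner_many_cpp")]]
NumericVector dtw_corner_many_cpp(NumericVector x1, NumericMatrix series,
                                  int w) {
  const int ns = series.nrow(), nt = series.ncol();
  NumericVector out(ns);
  std::vector<double> prev(nt, R_PosInf), cur(nt, R_PosInf), row(nt);
  for (int s = 0; s < ns; ++s) {
    for (int t = 0; t < nt; ++t) row[t] = series(s, t);
    out[s] = dtw_corner_one(x1.begin(), x1.size(), row.data(), nt, w,
                            prev, cur);
  }
  return out;
}
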