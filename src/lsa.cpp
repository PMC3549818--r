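#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Result of one lag-bounded scan; window is 0-based half-open on the
// first series' index.
struct PairRes {
  double p_hat, n_hat, statistic;
  int best_lag, win_start, win_end;
};

// Truncated-partial-sum dynamic program, one diagonal (fixed shift d)
// at a time. d = index into x minus index into y, |d| <= D. Along each
// diagonal the running sums of +x[i]*y[i-d] (P) and -x[i]*y[i-d] (N)
// are floored at zero; their maxima over all diagonals are P-hat and
// N-hat. The first maximizing (lag, window) in scan order (d ascending,
// window ends ascending) is retained: updates use strict > so ties keep
// the earliest candidate.
static PairRes lsa_scan(const double* x, const double* y, int n, int D) {
  double best_p = 0.0, best_n = 0.0;
  int p_lag = 0, p_s = 0, p_e = 0;
  int n_lag = 0, n_s = 0, n_e = 0;
  for (int d = -D; d <= D; ++d) {
    const int i0 = d > 0 ? d : 0;
    const int i1 = d < 0 ? n + d : n;
    double P = 0.0, N = 0.0;
    int ps = i0, ns = i0;
    for (int i = i0; i < i1; ++i) {
      const double z = x[i] * y[i - d];
      P += z;
      if (P < 0.0) {
        P = 0.0; ps = i + 1;
      } else if (P > best_p) {
        best_p = P; p_lag = d; p_s = ps; p_e = i + 1;
      }
      N -= z;
      if (N < 0.0) {
        N = 0.0; ns = i + 1;
      } else if (N > best_n) {
        best_n = N; n_lag = d; n_s = ns; n_e = i + 1;
      }
    }
  }
  PairRes r;
  r.p_hat = best_p;
  r.n_hat = best_n;
  if (best_p >= best_n) {  // tie resolved to the positive sign
    r.statistic = best_p / n;
    r.best_lag = p_lag; r.win_start = p_s; r.win_end = p_e;
  } else {
    r.statistic = -best_n / n;
    r.best_lag = n_lag; r.win_start = n_s; r.win_end = n_e;
  }
  return r;
}

// [[Rcpp::export]]
List lsa_pair_cpp(NumericVector x, NumericVector y, int D) {
  PairRes r = lsa_scan(x.begin(), y.begin(), (int)x.size(), D);
  return List::create(
    _["statistic"] = r.statistic,
    _["p_hat"] = r.p_hat,
    _["n_hat"] = r.n_hat,
    _["best_lag"] = r.best_lag,
    _["win_start"] = r.win_start,
    _["win_end"] = r.win_end);
}

// All unordered pairs of rows of `mat` (series in rows), canonical order
// (i, j) with i < j, i outer. Deterministic and serial.
// [[Rcpp::export]]
DataFrame all_pairs_cpp(NumericMatrix mat, int D) {
  const int m = mat.nrow(), n = mat.ncol();
  const R_xlen_t npair = (R_xlen_t)m * (m - 1) / 2;
  IntegerVector ia(npair), jb(npair), lag(npair), ws(npair), we(npair);
  NumericVector stat(npair), ph(npair), nh(npair);

  // contiguous row buffers (R matrices are column-major)
  std::vector<double> rows((size_t)m * n);
  for (int i = 0; i < m; ++i)
    for (int t = 0; t < n; ++t)
      rows[(size_t)i * n + t] = mat(i, t);

  R_xlen_t k = 0;
  for (int i = 0; i < m; ++i) {
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
    const double* xi = &rows[(size_t)i * n];
    for (int j = i + 1; j < m; ++j, ++k) {
      PairRes r = lsa_scan(xi, &rows[(size_t)j * n], n, D);
      ia[k] = i + 1; jb[k] = j + 1;
      stat[k] = r.statistic; ph[k] = r.p_hat; nh[k] = r.n_hat;
      lag[k] = r.best_lag; ws[k] = r.win_start; we[k] = r.win_end;
    }
  }
  return DataFrame::create(
    _["i"] = ia, _["j"] = jb, _["statistic"] = stat,
    _["p_hat"] = ph, _["n_hat"] = nh, _["best_lag"] = lag,
    _["win_start"] = ws, _["win_end"] = we);
}

// Statistic for row-wise pairs (X[i,], Y[i,]); batch helper for
// permutation nulls and tail simulations.
// [[Rcpp::export]]
NumericVector lsa_stat_rows_cpp(NumericMatrix X, NumericMatrix Y, int D) {
  const int m = X.nrow(), n = X.ncol();
  NumericVector out(m);
  std::vector<double> xb(n), yb(n);
  for (int i = 0; i < m; ++i) {
    for (int t = 0; t < n; ++t) { xb[t] = X(i, t); yb[t] = Y(i, t); }
    out[i] = lsa_scan(xb.data(), yb.data(), n, D).statistic;
  }
  return out;
}
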