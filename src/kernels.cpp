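#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Kendall tau-b with tie correction. Returns NA when either margin is
// completely tied (zero variance).
static double tau_b(const double* x, const double* y, int n) {
  long long C = 0, D = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[j] - x[i], dy = y[j] - y[i];
      double s = dx * dy;
      if (s > 0) ++C; else if (s < 0) ++D;
    }
  }
  // tie counts per margin
  long long n0 = (long long)n * (n - 1) / 2;
  long long Tx = 0, Ty = 0;
  {
    std::vector<double> xs(x, x + n), ys(y, y + n);
    std::sort(xs.begin(), xs.end());
    std::sort(ys.begin(), ys.end());
    long long run = 1;
    for (int i = 1; i <= n; ++i) {
      if (i < n && xs[i] == xs[i - 1]) ++run;
      else { Tx += run * (run - 1) / 2; run = 1; }
    }
    run = 1;
    for (int i = 1; i <= n; ++i) {
      if (i < n && ys[i] == ys[i - 1]) ++run;
      else { Ty += run * (run - 1) / 2; run = 1; }
    }
  }
  double den = std::sqrt((double)(n0 - Tx)) * std::sqrt((double)(n0 - Ty));
  if (den == 0.0) return NA_REAL;
  return (double)(C - D) / den;
}

// [[Rcpp::export(name = ".kendall_tau_b_cpp")]]
double kendall_tau_b_cpp(NumericVector x, NumericVector y) {
  if (x.size() != y.size()) stop("x and y must have equal length");
  return tau_b(x.begin(), y.begin(), x.size());
}

// For each column of `series`, the maximum tau-b against the columns of
// `refs` and the 1-based index of the maximising reference.
// [[Rcpp::export(name = ".max_tau_cpp")]]
List max_tau_cpp(NumericMatrix series, NumericMatrix refs) {
  int n = series.nrow(), m = series.ncol(), k = refs.ncol();
  if (refs.nrow() != n) stop("series and refs must have matching rows");
  NumericVector best(m);
  IntegerVector which(m);
  for (int s = 0; s < m; ++s) {
    double bt = R_NegInf; int bw = NA_INTEGER;
    for (int r = 0; r < k; ++r) {
      double t = tau_b(&series(0, s), &refs(0, r), n);
      if (!ISNA(t) && t > bt) { bt = t; bw = r + 1; }
    }
    if (bw == NA_INTEGER) { best[s] = NA_REAL; which[s] = NA_INTEGER; }
    else { best[s] = bt; which[s] = bw; }
  }
  return List::create(_["tau"] = best, _["which"] = which);
}

// Repeated-observations (within-subject centred) correlation between every
// pair of columns of m, pairwise-complete over non-missing (non-NA) cells.
// subject: 0-based integer codes, length nrow(m). Undefined correlations
// (zero within-subject variance or < 3 shared observations) are returned
// as NA; the caller decides how to encode them.
// [[Rcpp::export(name = ".rm_corr_matrix_cpp")]]
NumericMatrix rm_corr_matrix_cpp(NumericMatrix m, IntegerVector subject,
                                 int n_subjects) {
  int n = m.nrow(), p = m.ncol();
  if (subject.size() != n) stop("subject length must equal nrow(m)");
  NumericMatrix r(p, p);
  std::vector<double> sx(n_subjects), sy(n_subjects);
  std::vector<int> cnt(n_subjects);
  for (int a = 0; a < p; ++a) {
    r(a, a) = 1.0;
    for (int b = a + 1; b < p; ++b) {
      std::fill(sx.begin(), sx.end(), 0.0);
      std::fill(sy.begin(), sy.end(), 0.0);
      std::fill(cnt.begin(), cnt.end(), 0);
      int nobs = 0;
      for (int i = 0; i < n; ++i) {
        double xa = m(i, a), xb = m(i, b);
        if (std::isnan(xa) || std::isnan(xb)) continue;
        int s = subject[i];
        sx[s] += xa; sy[s] += xb; ++cnt[s]; ++nobs;
      }
      int nact = 0;
      for (int s = 0; s < n_subjects; ++s) if (cnt[s] > 0) ++nact;
      double out = NA_REAL;
      // >= 2 within-subject residual degrees of freedom
      if (nobs - nact >= 2) {
        double sxy = 0, sxx = 0, syy = 0;
        for (int i = 0; i < n; ++i) {
          double xa = m(i, a), xb = m(i, b);
          if (std::isnan(xa) || std::isnan(xb)) continue;
          int s = subject[i];
          double dx = xa - sx[s] / cnt[s];
          double dy = xb - sy[s] / cnt[s];
          sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
        }
        if (sxx > 0 && syy > 0) out = sxy / std::sqrt(sxx * syy);
      }
      r(a, b) = out;
      r(b, a) = out;
    }
  }
  return r;
}
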