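#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cmath>
#include <vector>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// pairwise-complete repeated-observations correlation between two columns
// (raw pointers, std::isnan: this sits in the innermost permutation loop)
static inline double rm_corr_cols(const double* xa, const double* xb, int n,
                                  const int* subject, int n_subjects,
                                  std::vector<double>& sx,
                                  std::vector<double>& sy,
                                  std::vector<int>& cnt,
                                  std::vector<double>& mx,
                                  std::vector<double>& my,
                                  std::vector<unsigned char>& ok) {
  std::fill(sx.begin(), sx.end(), 0.0);
  std::fill(sy.begin(), sy.end(), 0.0);
  std::fill(cnt.begin(), cnt.end(), 0);
  int nobs = 0;
  for (int i = 0; i < n; ++i) {
    double a = xa[i], b = xb[i];
    bool v = !(std::isnan(a) || std::isnan(b));
    ok[i] = v;
    if (v) { int s = subject[i]; sx[s] += a; sy[s] += b; ++cnt[s]; ++nobs; }
  }
  if (nobs < 3) return NA_REAL;
  for (int s = 0; s < n_subjects; ++s) {
    if (cnt[s] > 0) { mx[s] = sx[s] / cnt[s]; my[s] = sy[s] / cnt[s]; }
  }
  double sxy = 0, sxx = 0, syy = 0;
  for (int i = 0; i < n; ++i) {
    if (!ok[i]) continue;
    int s = subject[i];
    double dx = xa[i] - mx[s], dy = xb[i] - my[s];
    sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
  }
  if (sxx <= 0 || syy <= 0) return NA_REAL;
  return sxy / std::sqrt(sxx * syy);
}

// Ward.D2 agglomeration (nearest-neighbour chain, Lance-Williams update on
// squared distances) down to two clusters; fills `lab` with 1/2.
static void ward_two_cut(std::vector<double>& D2, int p,
                         std::vector<int>& lab) {
  std::vector<int> size(p, 1);
  std::vector<bool> active(p, true);
  std::vector<std::vector<int> > members(p);
  for (int i = 0; i < p; ++i) members[i].push_back(i);
  auto d2 = [&](int i, int j) -> double& { return D2[(size_t)i * p + j]; };
  std::vector<int> chain;
  chain.reserve(p);
  int n_active = p;
  while (n_active > 2) {
    if (chain.empty()) {
      for (int i = 0; i < p; ++i) if (active[i]) { chain.push_back(i); break; }
    }
    int a = chain.back();
    int b = -1; double best = R_PosInf;
    const double* row = &D2[(size_t)a * p];
    for (int j = 0; j < p; ++j) {
      if (!active[j] || j == a) continue;
      if (row[j] < best) { best = row[j]; b = j; }
    }
    if (chain.size() >= 2 && b == chain[chain.size() - 2]) {
      chain.pop_back(); chain.pop_back();
      int keep = std::min(a, b), drop = std::max(a, b);
      int na = size[a], nb = size[b];
      double dab = d2(a, b);
      for (int k = 0; k < p; ++k) {
        if (!active[k] || k == a || k == b) continue;
        int nk = size[k];
        double v = ((na + nk) * d2(a, k) + (nb + nk) * d2(b, k) -
                    (double)nk * dab) / (double)(na + nb + nk);
        d2(keep, k) = v; d2(k, keep) = v;
      }
      size[keep] = na + nb;
      active[drop] = false;
      members[keep].insert(members[keep].end(), members[drop].begin(),
                           members[drop].end());
      members[drop].clear();
      --n_active;
    } else {
      chain.push_back(b);
    }
  }
  int first = -1;
  for (int i = 0; i < p; ++i) if (active[i]) { first = i; break; }
  lab.assign(p, 2);
  for (size_t k = 0; k < members[first].size(); ++k)
    lab[members[first][k]] = 1;
}

// two-group PERMANOVA pseudo-F from a squared-distance matrix
static double pseudo_f(const std::vector<double>& D2, int p,
                       const std::vector<int>& lab) {
  double ss_t = 0, ssw1 = 0, ssw2 = 0;
  int n1 = 0;
  for (int i = 0; i < p; ++i) if (lab[i] == 1) ++n1;
  int n2 = p - n1;
  if (n1 == 0 || n2 == 0 || p - 2 <= 0) return NA_REAL;
  for (int i = 0; i < p; ++i) {
    const double* row = &D2[(size_t)i * p];
    for (int j = i + 1; j < p; ++j) {
      double v = row[j];
      ss_t += v;
      if (lab[i] == lab[j]) { if (lab[i] == 1) ssw1 += v; else ssw2 += v; }
    }
  }
  ss_t /= p;
  double ssw = ssw1 / n1 + ssw2 / n2;
  if (ssw <= 0) return R_PosInf;
  return (ss_t - ssw) / (ssw / (p - 2));
}

// Selection-aware split test: permute each feature column of the node's
// rCLR submatrix independently across samples (R RNG, so set.seed
// applies), recompute the repeated-observations correlation distance,
// re-select the Ward two-way split and score its pseudo-F against the
// observed one.  Stops early once p < alpha is no longer attainable.
//
// When every subject contributes at most two observations (`pair_rows`
// gives the row pairs of the two-observation subjects), the
// within-subject centred sums reduce exactly to products of per-subject
// observation differences — a subject with a missing value in either
// row of either feature contributes nothing — so the whole correlation
// matrix is three BLAS crossproducts over the ns x p difference matrix.
// [[Rcpp::export(name = ".split_test_data_cpp")]]
List split_test_data_cpp(NumericMatrix m, IntegerVector subject,
                         int n_subjects, double obs_f, double alpha,
                         int n_perm,
                         Nullable<IntegerMatrix> pair_rows = R_NilValue) {
  int n = m.nrow(), p = m.ncol();
  std::vector<double> sx(n_subjects), sy(n_subjects), mx(n_subjects),
      my(n_subjects);
  std::vector<int> cnt(n_subjects);
  std::vector<unsigned char> okbuf(n);
  std::vector<double> buf((size_t)n * p);
  std::vector<double> D2((size_t)p * p), D2work((size_t)p * p);
  std::vector<int> lab(p);
  const double* src = REAL(m);
  const int* subj = INTEGER(subject);
  bool use_diff = pair_rows.isNotNull();
  IntegerMatrix pr;
  int ns2 = 0;
  std::vector<double> A, A2, U, Sxy, Sxx, Cnt;
  if (use_diff) {
    pr = pair_rows.get();
    ns2 = pr.ncol();
    A.resize((size_t)ns2 * p); A2.resize((size_t)ns2 * p);
    U.resize((size_t)ns2 * p);
    Sxy.resize((size_t)p * p); Sxx.resize((size_t)p * p);
    Cnt.resize((size_t)p * p);
  }
  double max_exceed = alpha * (1.0 + n_perm) - 1.0;
  int exceed = 0, done = 0;
  const double one = 1.0, zero = 0.0;
  RNGScope scope;
  for (int it = 0; it < n_perm; ++it) {
    std::copy(src, src + (size_t)n * p, buf.begin());
    for (int j = 0; j < p; ++j) {
      double* col = &buf[(size_t)j * n];
      for (int i = n - 1; i > 0; --i) {
        int k = (int)(unif_rand() * (i + 1));
        if (k > i) k = i;
        double t = col[i]; col[i] = col[k]; col[k] = t;
      }
    }
    if (use_diff) {
      for (int j = 0; j < p; ++j) {
        const double* col = &buf[(size_t)j * n];
        double* aj = &A[(size_t)j * ns2];
        double* a2j = &A2[(size_t)j * ns2];
        double* uj = &U[(size_t)j * ns2];
        for (int s = 0; s < ns2; ++s) {
          double v1 = col[pr(0, s)], v2 = col[pr(1, s)];
          if (std::isnan(v1) || std::isnan(v2)) {
            aj[s] = 0.0; a2j[s] = 0.0; uj[s] = 0.0;
          } else {
            double d = v1 - v2;
            aj[s] = d; a2j[s] = d * d; uj[s] = 1.0;
          }
        }
      }
      F77_CALL(dgemm)("T", "N", &p, &p, &ns2, &one, A.data(), &ns2,
                      A.data(), &ns2, &zero, Sxy.data(), &p FCONE FCONE);
      F77_CALL(dgemm)("T", "N", &p, &p, &ns2, &one, A2.data(), &ns2,
                      U.data(), &ns2, &zero, Sxx.data(), &p FCONE FCONE);
      F77_CALL(dgemm)("T", "N", &p, &p, &ns2, &one, U.data(), &ns2,
                      U.data(), &ns2, &zero, Cnt.data(), &p FCONE FCONE);
      for (int a = 0; a < p; ++a) {
        D2[(size_t)a * p + a] = 0.0;
        for (int b = a + 1; b < p; ++b) {
          double r = 0.0;
          // >= 2 joint subjects, i.e. >= 4 joint observations
          if (Cnt[(size_t)a * p + b] >= 2.0) {
            double den = Sxx[(size_t)b * p + a] * Sxx[(size_t)a * p + b];
            if (den > 0)
              r = Sxy[(size_t)a * p + b] / std::sqrt(den);
          }
          double d = 1.0 - r;
          D2[(size_t)a * p + b] = d * d;
          D2[(size_t)b * p + a] = d * d;
        }
      }
    } else {
      for (int a = 0; a < p; ++a) {
        D2[(size_t)a * p + a] = 0.0;
        const double* ca = &buf[(size_t)a * n];
        for (int b = a + 1; b < p; ++b) {
          double r = rm_corr_cols(ca, &buf[(size_t)b * n], n, subj,
                                  n_subjects, sx, sy, cnt, mx, my, okbuf);
          if (std::isnan(r)) r = 0.0;
          double d = 1.0 - r;
          D2[(size_t)a * p + b] = d * d;
          D2[(size_t)b * p + a] = d * d;
        }
      }
    }
    D2work = D2;
    ward_two_cut(D2work, p, lab);
    double f = pseudo_f(D2, p, lab);
    done = it + 1;
    if (!std::isnan(f) && f >= obs_f - 1e-12) {
      ++exceed;
      if (exceed > max_exceed) break;
    }
    if (it % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["p"] = (1.0 + exceed) / (1.0 + done),
                      _["n_perm"] = done, _["exceed"] = exceed);
}
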