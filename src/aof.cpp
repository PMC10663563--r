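#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Alignment objective between a transformed source slice and a target
// slice: mean domain agreement over mutual k-nearest-neighbour pairs
// within max_dist, minus |n_o/n_j - 1|^p on the non-overlap fraction.
// Called thousands of times per differential-evolution search, hence C++.
// Ties in neighbour selection are broken by index order.

static void knn_rows(const std::vector<double>& d2, int nr, int nc, int k,
                     std::vector<int>& out, bool byrow) {
  std::vector<int> idx;
  for (int i = 0; i < nr; ++i) {
    int m = nc;
    idx.resize(m);
    for (int j = 0; j < m; ++j) idx[j] = j;
    std::partial_sort(idx.begin(), idx.begin() + k, idx.end(),
                      [&](int a, int b) {
                        double da = byrow ? d2[(size_t)i * nc + a]
                                          : d2[(size_t)a * nr + i];
                        double db = byrow ? d2[(size_t)i * nc + b]
                                          : d2[(size_t)b * nr + i];
                        if (da != db) return da < db;
                        return a < b;
                      });
    for (int j = 0; j < k; ++j) out[(size_t)i * k + j] = idx[j];
  }
}

// [[Rcpp::export]]
double aof_cpp(NumericMatrix S, IntegerVector sdom,
               NumericMatrix T, IntegerVector tdom,
               int k, double p, double max_dist) {
  const int ns = S.nrow(), nt = T.nrow();
  const int kk = std::min(k, std::min(ns, nt));
  std::vector<double> d2((size_t)ns * nt);
  for (int i = 0; i < ns; ++i) {
    const double sx = S(i, 0), sy = S(i, 1);
    for (int j = 0; j < nt; ++j) {
      const double dx = sx - T(j, 0), dy = sy - T(j, 1);
      d2[(size_t)i * nt + j] = dx * dx + dy * dy;
    }
  }
  std::vector<int> kn_s((size_t)ns * kk), kn_t((size_t)nt * kk);
  knn_rows(d2, ns, nt, kk, kn_s, true);   // source -> target
  knn_rows(d2, nt, ns, kk, kn_t, false);  // target -> source
  const double md2 = max_dist * max_dist;
  int n_o = 0;
  double agree_sum = 0.0;
  for (int i = 0; i < ns; ++i) {
    int m = 0, match = 0;
    for (int a = 0; a < kk; ++a) {
      const int j = kn_s[(size_t)i * kk + a];
      if (d2[(size_t)i * nt + j] > md2) continue;
      bool mutual = false;
      for (int b = 0; b < kk; ++b) {
        if (kn_t[(size_t)j * kk + b] == i) { mutual = true; break; }
      }
      if (!mutual) continue;
      ++m;
      if (tdom[j] == sdom[i]) ++match;
    }
    if (m > 0) {
      ++n_o;
      agree_sum += (double)match / m;
    }
  }
  const double frac = (double)n_o / ns;
  const double agree = n_o > 0 ? agree_sum / n_o : 0.0;
  return agree - std::pow(std::fabs(frac - 1.0), p);
}
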