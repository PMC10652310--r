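#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Two-sample two-dimensional Kolmogorov-Smirnov statistic in the
// Fasano-Franceschini style. Each data point serves as a quadrant origin;
// the statistic conditioned on one sample is the maximum over that
// sample's origins and the quadrant family of |F_A - F_B|, and D is the
// average of the two conditioned maxima. At every origin both the closed
// partition ((x <= x0) x (y <= y0), four blocks) and the open partition
// ((x < x0) x (y < y0)) are evaluated and the larger discrepancy kept --
// the 2D analogue of taking the sup of |F_A - F_B| from both sides of a
// jump in the 1D KS statistic. With one coordinate constant this reduces
// exactly to the 1D two-sample KS statistic. Counting uses a Fenwick tree
// over y-ranks inside one x-sweep: O(n log n) per evaluation.

struct Fenwick {
  std::vector<int> t;
  int n;
  void init(int n_) { n = n_; t.assign(n + 1, 0); }
  void reset() { std::fill(t.begin(), t.end(), 0); }
  void add(int i) { for (; i <= n; i += i & -i) t[i]++; }
  int query(int i) const { int s = 0; for (; i > 0; i -= i & -i) s += t[i]; return s; }
};

struct FFWork {
  int n, m;
  std::vector<int> ord_x;        // indices sorted by x
  std::vector<int> yrank;        // dense 1-based y ranks
  std::vector<int> y_order;      // indices sorted by y
  std::vector<int> y_group_of;   // tie-group index along y for each point
  int n_ygroups;
  Fenwick bit0, bit1;
  // per-permutation marginal counts along y, per label:
  // cum{0,1}_le[g] = #{label, y <= group g}, cum{0,1}_lt strict
  std::vector<int> cum0_le, cum1_le;
};

static void ff_prepare(const NumericVector& x, const NumericVector& y,
                       FFWork& w) {
  int n = x.size();
  w.n = n;
  w.ord_x.resize(n);
  w.y_order.resize(n);
  for (int i = 0; i < n; ++i) w.ord_x[i] = w.y_order[i] = i;
  std::sort(w.ord_x.begin(), w.ord_x.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  std::sort(w.y_order.begin(), w.y_order.end(),
            [&](int a, int b) { return y[a] < y[b]; });
  w.yrank.assign(n, 0);
  w.y_group_of.assign(n, 0);
  int r = 0;
  for (int i = 0; i < n; ++i) {
    if (i == 0 || y[w.y_order[i]] > y[w.y_order[i - 1]]) ++r;
    w.yrank[w.y_order[i]] = r;
    w.y_group_of[w.y_order[i]] = r - 1;
  }
  w.m = r;
  w.n_ygroups = r;
  w.bit0.init(w.m);
  w.bit1.init(w.m);
  w.cum0_le.assign(r + 1, 0);
  w.cum1_le.assign(r + 1, 0);
}

static inline double blockmax(int qll0, int qll1, int cx0, int cx1,
                              int cy0, int cy1, int n0, int n1,
                              double invA, double invB) {
  double d1 = std::fabs(qll0 * invA - qll1 * invB);
  double d2 = std::fabs((cx0 - qll0) * invA - (cx1 - qll1) * invB);
  double d3 = std::fabs((cy0 - qll0) * invA - (cy1 - qll1) * invB);
  double d4 = std::fabs((n0 - cx0 - cy0 + qll0) * invA -
                        (n1 - cx1 - cy1 + qll1) * invB);
  return std::max(std::max(d1, d2), std::max(d3, d4));
}

static double ff_eval(const NumericVector& x, const std::vector<int>& lab,
                      FFWork& w, int nA, int nB) {
  int n = w.n;
  // cumulative label counts along y tie groups (index g = groups 1..G)
  {
    int c0 = 0, c1 = 0, g = 0, i = 0;
    while (i < n) {
      int gi = w.y_group_of[w.y_order[i]];
      while (g < gi) { ++g; w.cum0_le[g] = c0; w.cum1_le[g] = c1; }
      int j = i;
      while (j < n && w.y_group_of[w.y_order[j]] == gi) {
        if (lab[w.y_order[j]]) ++c1; else ++c0;
        ++j;
      }
      ++g;
      w.cum0_le[g] = c0;
      w.cum1_le[g] = c1;
      i = j;
    }
  }
  w.bit0.reset();
  w.bit1.reset();
  double dA = 0.0, dB = 0.0;
  double invA = 1.0 / nA, invB = 1.0 / nB;
  int ins0 = 0, ins1 = 0;
  int i = 0;
  while (i < n) {
    int j = i;
    double xv = x[w.ord_x[i]];
    while (j < n && x[w.ord_x[j]] == xv) ++j;
    // open partition: counts use x <, y < (query before batch insertion)
    for (int t = i; t < j; ++t) {
      int idx = w.ord_x[t];
      int yr = w.yrank[idx];
      int qs0 = w.bit0.query(yr - 1);
      int qs1 = w.bit1.query(yr - 1);
      int cys0 = w.cum0_le[yr - 1], cys1 = w.cum1_le[yr - 1];
      double d = blockmax(qs0, qs1, ins0, ins1, cys0, cys1, nA, nB,
                          invA, invB);
      if (lab[idx]) { if (d > dB) dB = d; }
      else          { if (d > dA) dA = d; }
    }
    for (int t = i; t < j; ++t) {
      int idx = w.ord_x[t];
      if (lab[idx]) { w.bit1.add(w.yrank[idx]); ++ins1; }
      else          { w.bit0.add(w.yrank[idx]); ++ins0; }
    }
    // closed partition: counts use x <=, y <= (query after insertion)
    for (int t = i; t < j; ++t) {
      int idx = w.ord_x[t];
      int yr = w.yrank[idx];
      int ql0 = w.bit0.query(yr);
      int ql1 = w.bit1.query(yr);
      int cy0 = w.cum0_le[yr], cy1 = w.cum1_le[yr];
      double d = blockmax(ql0, ql1, ins0, ins1, cy0, cy1, nA, nB,
                          invA, invB);
      if (lab[idx]) { if (d > dB) dB = d; }
      else          { if (d > dA) dA = d; }
    }
    i = j;
  }
  return 0.5 * (dA + dB);
}

// [[Rcpp::export(name = ".ff_test_cpp")]]
List ff_test_cpp(NumericVector x, NumericVector y, IntegerVector labels,
                 int nPerm) {
  int n = x.size();
  if (y.size() != n || labels.size() != n)
    stop("coordinate and label lengths differ");
  std::vector<int> lab(n);
  int nB = 0;
  for (int i = 0; i < n; ++i) { lab[i] = labels[i] ? 1 : 0; nB += lab[i]; }
  int nA = n - nB;
  if (nA == 0 || nB == 0) stop("both samples must be non-empty");

  FFWork w;
  ff_prepare(x, y, w);
  double D = ff_eval(x, lab, w, nA, nB);

  double p = NA_REAL;
  if (nPerm > 0) {
    GetRNGstate();
    int ge = 0;
    std::vector<int> perm(lab);
    for (int r = 0; r < nPerm; ++r) {
      for (int i = n - 1; i > 0; --i) {  // Fisher-Yates via R's RNG
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(perm[i], perm[j]);
      }
      if (ff_eval(x, perm, w, nA, nB) >= D - 1e-12) ++ge;
    }
    PutRNGstate();
    p = (1.0 + ge) / (1.0 + nPerm);
  }
  return List::create(_["D"] = D, _["p"] = p);
}
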