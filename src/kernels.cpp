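#include <Rcpp.h>
#include <set>
#include <vector>
using namespace Rcpp;

// 3x3 all-ones binary erosion; out-of-bounds neighbours count as background
// (matches the usual zero border convention for binary morphology).
// [[Rcpp::export(name = ".binary_erode3x3")]]
LogicalMatrix binary_erode3x3(LogicalMatrix m, int iterations = 1) {
  int nr = m.nrow(), nc = m.ncol();
  LogicalMatrix cur = clone(m);
  for (int it = 0; it < iterations; ++it) {
    LogicalMatrix out(nr, nc);
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        bool keep = cur(i, j);
        if (keep) {
          for (int dj = -1; dj <= 1 && keep; ++dj) {
            for (int di = -1; di <= 1 && keep; ++di) {
              int ii = i + di, jj = j + dj;
              if (ii < 0 || ii >= nr || jj < 0 || jj >= nc || !cur(ii, jj))
                keep = false;
            }
          }
        }
        out(i, j) = keep;
      }
    }
    cur = out;
  }
  return cur;
}

// 3x3 all-ones binary dilation (Chebyshev radius `iterations`).
// [[Rcpp::export(name = ".binary_dilate3x3")]]
LogicalMatrix binary_dilate3x3(LogicalMatrix m, int iterations = 1) {
  int nr = m.nrow(), nc = m.ncol();
  LogicalMatrix cur = clone(m);
  for (int it = 0; it < iterations; ++it) {
    LogicalMatrix out(nr, nc);
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        bool on = false;
        for (int dj = -1; dj <= 1 && !on; ++dj) {
          for (int di = -1; di <= 1 && !on; ++di) {
            int ii = i + di, jj = j + dj;
            if (ii >= 0 && ii < nr && jj >= 0 && jj < nc && cur(ii, jj))
              on = true;
          }
        }
        out(i, j) = on;
      }
    }
    cur = out;
  }
  return cur;
}

// 8-connected component labelling; labels 1..K in first-encounter
// (column-major) order, 0 = background.
// [[Rcpp::export(name = ".label_components8")]]
IntegerMatrix label_components8(LogicalMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (m(i, j) && lab(i, j) == 0) {
        ++next;
        stack.push_back(i + j * nr);
        lab(i, j) = next;
        while (!stack.empty()) {
          int idx = stack.back(); stack.pop_back();
          int ci = idx % nr, cj = idx / nr;
          for (int dj = -1; dj <= 1; ++dj) {
            for (int di = -1; di <= 1; ++di) {
              int ii = ci + di, jj = cj + dj;
              if (ii >= 0 && ii < nr && jj >= 0 && jj < nc &&
                  m(ii, jj) && lab(ii, jj) == 0) {
                lab(ii, jj) = next;
                stack.push_back(ii + jj * nr);
              }
            }
          }
        }
      }
    }
  }
  return lab;
}

namespace {
// Running nearest-rank order statistic: two multisets partitioned at the
// current rank, rebalanced as the window slides (O(log w) per step).
struct RankTracker {
  std::multiset<double> low, high; // low holds the k smallest
  void insert(double v) {
    if (low.empty() || v <= *low.rbegin()) low.insert(v); else high.insert(v);
  }
  void erase(double v) {
    auto it = low.find(v);
    if (it != low.end()) low.erase(it);
    else high.erase(high.find(v));
  }
  void rebalance(size_t k) {
    while (low.size() < k) {
      auto it = high.begin();
      low.insert(*it); high.erase(it);
    }
    while (low.size() > k) {
      auto it = std::prev(low.end());
      high.insert(*it); low.erase(it);
    }
  }
  double kth() const { return *low.rbegin(); }
};
} // namespace

// Running nearest-rank percentile filter along time for each pixel trace;
// x is pixels x frames. Window is centred, truncated (not padded) at the
// trace edges; the rank index within a window of m samples is
// ceil(rank * m), clamped to [1, m].
// [[Rcpp::export(name = ".run_rank_filter")]]
NumericMatrix run_rank_filter(NumericMatrix x, int window, double rank) {
  int p = x.nrow(), n = x.ncol();
  if (window < 1) stop("window must be >= 1");
  int h = window / 2;
  NumericMatrix out(p, n);
  for (int i = 0; i < p; ++i) {
    RankTracker rt;
    int lo = 0, hi = std::min(h, n - 1); // inclusive current window bounds
    for (int t = lo; t <= hi; ++t) rt.insert(x(i, t));
    for (int t = 0; t < n; ++t) {
      if (t > 0) {
        int add = t + h;
        if (add < n) { rt.insert(x(i, add)); hi = add; }
        int drop = t - h - 1;
        if (drop >= 0) { rt.erase(x(i, drop)); lo = drop + 1; }
      }
      size_t m = (size_t)(hi - lo + 1);
      size_t k = (size_t)std::ceil(rank * (double)m);
      if (k < 1) k = 1;
      if (k > m) k = m;
      rt.rebalance(k);
      out(i, t) = rt.kth();
    }
  }
  return out;
}

// Calcium forward model in one allocation: c_t = y_t + gamma * c_{t-1},
// F_t = baseline_t * (1 + c_t) + noise (R's RNG, column-major order).
// y is pixels x frames; baseline has one value per frame.
// [[Rcpp::export(name = ".forward_model")]]
NumericMatrix forward_model(NumericMatrix y, double gamma,
                            NumericVector baseline, double noise_sd) {
  int p = y.nrow(), n = y.ncol();
  if (baseline.size() != n) stop("baseline length must equal frame count");
  NumericMatrix f(p, n);
  std::vector<double> cal(p, 0.0);
  RNGScope scope;
  for (int t = 0; t < n; ++t) {
    double b = baseline[t];
    for (int i = 0; i < p; ++i) {
      cal[i] = y(i, t) + gamma * cal[i];
      double v = b * (1.0 + cal[i]);
      if (noise_sd > 0) v += R::norm_rand() * noise_sd;
      f(i, t) = v;
    }
  }
  return f;
}

// Prior-frame subtraction in one allocation: out_t = r_t - gamma * r_{t-1},
// out_1 = r_1. r is pixels x frames.
// [[Rcpp::export(name = ".prior_frame_subtract")]]
NumericMatrix prior_frame_subtract(NumericMatrix r, double gamma) {
  int p = r.nrow(), n = r.ncol();
  NumericMatrix out(p, n);
  for (int i = 0; i < p; ++i) out(i, 0) = r(i, 0);
  for (int t = 1; t < n; ++t)
    for (int i = 0; i < p; ++i)
      out(i, t) = r(i, t) - gamma * r(i, t - 1);
  return out;
}

// (F - F0) / F0 in one allocation.
// [[Rcpp::export(name = ".dff_ratio")]]
NumericMatrix dff_ratio(NumericMatrix f, NumericMatrix f0) {
  int p = f.nrow(), n = f.ncol();
  NumericMatrix out(p, n);
  for (int t = 0; t < n; ++t)
    for (int i = 0; i < p; ++i)
      out(i, t) = (f(i, t) - f0(i, t)) / f0(i, t);
  return out;
}
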