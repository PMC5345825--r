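// Low-level binary/label image operations used by the segmentation and
// morphometry layers: connected-component labelling, exact Euclidean
// distance transform, seeded watershed flooding, label-preserving dilation
// and Moore-neighbour boundary tracing. Images are R matrices indexed
// [row, col]; masks use 0 = background, nonzero = foreground.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

// 8-neighbourhood in clockwise screen order (y down): E SE S SW W NW N NE
static const int DR8[8] = {0, 1, 1, 1, 0, -1, -1, -1};
static const int DC8[8] = {1, 1, 0, -1, -1, -1, 0, 1};
static const int DR4[4] = {0, 1, 0, -1};
static const int DC4[4] = {1, 0, -1, 0};

// [[Rcpp::export]]
IntegerMatrix cpp_label(IntegerMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int *dr = (connectivity == 4) ? DR4 : DR8;
  const int *dc = (connectivity == 4) ? DC4 : DC8;
  int ndir = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < ndir; ++k) {
          int rr = cr + dr[k], cch = cc + dc[k];
          if (rr < 0 || rr >= nr || cch < 0 || cch >= nc) continue;
          if (mask(rr, cch) != 0 && lab(rr, cch) == 0) {
            lab(rr, cch) = next;
            stack.push_back(rr + cch * nr);
          }
        }
      }
    }
  }
  return lab;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher 2012)
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance to the nearest background (zero) pixel.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e20;
  NumericMatrix out(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // pass 1: along columns
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = (mask(r, c) != 0) ? INF : 0.0;
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) out(r, c) = d[r];
  }
  // pass 2: along rows
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = out(r, c);
    dt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) out(r, c) = d[c];
  }
  return out;
}

struct QItem {
  double prio;   // flooding order: higher distance first
  long long seq; // FIFO tie-break for determinism
  int idx;
};
struct QCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.prio != b.prio) return a.prio < b.prio; // max-heap on prio
    return a.seq > b.seq;                         // then FIFO
  }
};

// Meyer-style seeded flooding on a priority surface (the distance
// transform). Pixels reachable from exactly one seed label are assigned to
// it; pixels contested at assignment time become watershed lines (0 in the
// output). mask limits flooding to foreground.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix dist, IntegerMatrix seeds,
                            IntegerMatrix mask) {
  int nr = dist.nrow(), nc = dist.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<char> queued(nr * (size_t)nc, 0);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long long seq = 0;
  const int LINE = -1;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0) lab(r, c) = seeds(r, c);
  // enqueue unlabelled mask pixels bordering a seed
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      bool border = false;
      for (int k = 0; k < 8 && !border; ++k) {
        int rr = r + DR8[k], cc = c + DC8[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (lab(rr, cc) > 0) border = true;
      }
      if (border) {
        pq.push({dist(r, c), seq++, r + c * nr});
        queued[r + (size_t)c * nr] = 1;
      }
    }
  }
  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    int r = it.idx % nr, c = it.idx / nr;
    if (lab(r, c) != 0) continue;
    int found = 0;
    bool conflict = false;
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR8[k], cc = c + DC8[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int L = lab(rr, cc);
      if (L > 0) {
        if (found == 0) found = L;
        else if (found != L) { conflict = true; break; }
      }
    }
    if (conflict) { lab(r, c) = LINE; continue; }
    if (found == 0) continue; // isolated: neighbours were all lines
    lab(r, c) = found;
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR8[k], cc = c + DC8[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      size_t li = rr + (size_t)cc * nr;
      if (mask(rr, cc) != 0 && lab(rr, cc) == 0 && !queued[li]) {
        pq.push({dist(rr, cc), seq++, rr + cc * nr});
        queued[li] = 1;
      }
    }
  }
  // watershed lines become background
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) == LINE) lab(r, c) = 0;
  return lab;
}

// One 8-connected dilation shell per iteration; a background pixel
// adjacent to two or more distinct labels in the same iteration stays
// background, so regions never merge.
// [[Rcpp::export]]
IntegerMatrix cpp_dilate_no_merge(IntegerMatrix labels, int iterations) {
  int nr = labels.nrow(), nc = labels.ncol();
  IntegerMatrix cur = clone(labels);
  for (int it = 0; it < iterations; ++it) {
    IntegerMatrix nxt = clone(cur);
    bool changed = false;
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        if (cur(r, c) != 0) continue;
        int found = 0;
        bool conflict = false;
        for (int k = 0; k < 8; ++k) {
          int rr = r + DR8[k], cc = c + DC8[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          int L = cur(rr, cc);
          if (L > 0) {
            if (found == 0) found = L;
            else if (found != L) { conflict = true; break; }
          }
        }
        if (found > 0 && !conflict) { nxt(r, c) = found; changed = true; }
      }
    }
    cur = nxt;
    if (!changed) break;
  }
  return cur;
}

// Moore-neighbour contour trace. The walk stops when it is about to repeat
// the initial move start->second, so thin 8-connected shapes that pass
// through the start pixel more than once are traced completely.
// Returns the closed boundary as 1-based (row, col) pairs in trace order;
// the first vertex is not repeated at the end.
// [[Rcpp::export]]
IntegerMatrix cpp_trace_boundary(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  int sr = -1, sc = -1;
  for (int r = 0; r < nr && sr < 0; ++r)
    for (int c = 0; c < nc; ++c)
      if (mask(r, c) != 0) { sr = r; sc = c; break; }
  if (sr < 0) return IntegerMatrix(0, 2);
  std::vector<int> rows, cols;
  rows.push_back(sr); cols.push_back(sc);
  // backtrack starts at the (background) pixel west of the start
  int br = sr, bc = sc - 1;
  int cr = sr, cc = sc;
  int secr = -1, secc = -1; // the second vertex of the walk
  long long guard = 0, maxit = 8LL * nr * nc + 16;
  while (guard++ < maxit) {
    // direction index of backtrack pixel relative to current
    int bd = -1;
    for (int k = 0; k < 8; ++k)
      if (cr + DR8[k] == br && cc + DC8[k] == bc) { bd = k; break; }
    if (bd < 0) bd = 4; // degenerate; restart scan from west
    int fr = -1, fc = -1;
    for (int s = 1; s <= 8; ++s) {
      int k = (bd + s) % 8;
      int rr = cr + DR8[k], cch = cc + DC8[k];
      bool fg = (rr >= 0 && rr < nr && cch >= 0 && cch < nc &&
                 mask(rr, cch) != 0);
      if (fg) { fr = rr; fc = cch; break; }
      br = rr; bc = cch; // last background examined
    }
    if (fr < 0) break; // isolated single pixel
    if (secr < 0) { secr = fr; secc = fc; }
    else if (cr == sr && cc == sc && fr == secr && fc == secc) break;
    rows.push_back(fr); cols.push_back(fc);
    cr = fr; cc = fc;
  }
  // drop the duplicated closing vertex if the trace re-appended the start
  int n = rows.size();
  if (n > 1 && rows[n - 1] == sr && cols[n - 1] == sc) { --n; }
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = rows[i] + 1; out(i, 1) = cols[i] + 1; }
  return out;
}
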