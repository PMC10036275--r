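#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Marker-controlled watershed by Meyer-style priority flooding on the
// (inverted) canopy height surface: regions grow outward from the marker
// cells, always extending the current highest frontier cell, so basin
// boundaries form along height-model valleys. Only cells with
// chm >= min_height are floodable. 8-connectivity. Ties are broken by
// insertion order, which makes the result deterministic.

struct QCell {
  double h;
  unsigned long order;
  int idx;
};
struct QCmp {
  bool operator()(const QCell& a, const QCell& b) const {
    if (a.h != b.h) return a.h < b.h;   // max-heap on height
    return a.order > b.order;           // FIFO among equal heights
  }
};

// [[Rcpp::export]]
IntegerMatrix ws_flood_cpp(NumericMatrix chm, IntegerMatrix markers,
                           double min_height) {
  const int nr = chm.nrow(), nc = chm.ncol();
  IntegerMatrix labels(nr, nc);
  std::priority_queue<QCell, std::vector<QCell>, QCmp> pq;
  unsigned long counter = 0;

  for (int k = 0; k < markers.nrow(); ++k) {
    int r = markers(k, 0) - 1, c = markers(k, 1) - 1;
    if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
    if (labels(r, c) != 0) continue;
    labels(r, c) = k + 1;
    pq.push({chm(r, c), counter++, r + c * nr});
  }

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  while (!pq.empty()) {
    QCell cur = pq.top();
    pq.pop();
    int r = cur.idx % nr, c = cur.idx / nr;
    int lab = labels(r, c);
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (labels(rr, cc) != 0) continue;
      double h = chm(rr, cc);
      if (ISNAN(h) || h < min_height) continue;
      labels(rr, cc) = lab;
      pq.push({h, counter++, rr + cc * nr});
    }
  }
  return labels;
}

// Variable-window local maxima: cell (r,c) is a treetop candidate when its
// value is >= min_height and strictly greater than every cell of the
// circular window whose radius (in cells) is given per-cell in `radius`.
// Equal-valued cells inside each other's windows: the one with the smaller
// (row, col) wins.

// [[Rcpp::export]]
IntegerMatrix local_maxima_cpp(NumericMatrix chm, NumericMatrix radius,
                               double min_height) {
  const int nr = chm.nrow(), nc = chm.ncol();
  std::vector<int> out_r, out_c;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = chm(r, c);
      if (ISNAN(v) || v < min_height) continue;
      double rad = radius(r, c);
      int w = (int)std::floor(rad);
      bool is_max = true;
      for (int dc2 = -w; dc2 <= w && is_max; ++dc2) {
        for (int dr2 = -w; dr2 <= w && is_max; ++dr2) {
          if (dr2 == 0 && dc2 == 0) continue;
          if ((double)dr2 * dr2 + (double)dc2 * dc2 > rad * rad) continue;
          int rr = r + dr2, cc = c + dc2;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          double u = chm(rr, cc);
          if (ISNAN(u)) continue;
          if (u > v) is_max = false;
          else if (u == v) {
            // tie: smaller (row, col) survives
            if (rr < r || (rr == r && cc < c)) is_max = false;
          }
        }
      }
      if (is_max) {
        out_r.push_back(r + 1);
        out_c.push_back(c + 1);
      }
    }
  }
  IntegerMatrix out(out_r.size(), 2);
  for (size_t i = 0; i < out_r.size(); ++i) {
    out(i, 0) = out_r[i];
    out(i, 1) = out_c[i];
  }
  return out;
}
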