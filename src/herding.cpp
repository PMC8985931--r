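#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Zhang-Suen morphological thinning of a binary image down to a 1-px skeleton.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  // padded working copy, 0/1
  std::vector<unsigned char> a((nr + 2) * (nc + 2), 0);
  auto at = [&](int r, int c) -> unsigned char& { return a[(c + 1) * (nr + 2) + r + 1]; };
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (img(r, c)) at(r, c) = 1;

  std::vector<int> kill;
  kill.reserve(1024);
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!at(r, c)) continue;
          // neighbours P2..P9 clockwise starting north (row-1)
          unsigned char p2 = at(r - 1, c),     p3 = at(r - 1, c + 1);
          unsigned char p4 = at(r, c + 1),     p5 = at(r + 1, c + 1);
          unsigned char p6 = at(r + 1, c),     p7 = at(r + 1, c - 1);
          unsigned char p8 = at(r, c - 1),     p9 = at(r - 1, c - 1);
          int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (b < 2 || b > 6) continue;
          int trans = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                      (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                      (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                      (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (trans != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(c * nr + r);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k)
        at(kill[k] % nr, kill[k] / nr) = 0;
    }
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = at(r, c) != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Maximal empty axis-aligned rectangle over the TRUE pixels of `free`
// (histogram-of-heights + monotone stack, row-major first-occurrence ties).
// Returns c(area_px, row, col, height, width), 1-based top-left corner.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_max_rect(LogicalMatrix free) {
  int nr = free.nrow(), nc = free.ncol();
  std::vector<int> h(nc, 0), stk;
  stk.reserve(nc + 1);
  double best = 0;
  int br = 0, bc = 0, bh = 0, bw = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) h[c] = free(r, c) ? h[c] + 1 : 0;
    stk.clear();
    for (int c = 0; c <= nc; ++c) {
      int cur = (c < nc) ? h[c] : 0;
      int start = c;
      while (!stk.empty() && h[stk.back()] >= cur) {
        int top = stk.back();
        stk.pop_back();
        int left = stk.empty() ? 0 : stk.back() + 1;
        double area = (double)h[top] * (c - left);
        if (area > best) {
          best = area;
          bh = h[top];
          bw = c - left;
          br = r - bh + 1;
          bc = left;
        }
        start = left;
      }
      (void)start;
      if (c < nc) stk.push_back(c);
    }
  }
  return NumericVector::create(best, br + 1, bc + 1, bh, bw);
}

// ---------------------------------------------------------------------------
// Skeleton path tracing with chord-based length estimation, split by label.
//
// Decomposes the 8-connected skeleton into chains between junction/end
// pixels (plus cycles), then measures each chain as a sum of straight chords
// spanning `step` pixels. Chord length is assigned to the label of the
// chain's mid-chord pixel; `lab` holds 0 (gap) or 1 (branch).
// Returns c(len_on_0, len_on_1) in pixel units.
// ---------------------------------------------------------------------------

static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// [[Rcpp::export]]
NumericVector cpp_skel_lengths(LogicalMatrix skel, IntegerMatrix lab, int step = 4) {
  int nr = skel.nrow(), nc = skel.ncol();
  std::vector<unsigned char> deg(nr * nc, 0);
  std::vector<unsigned char> evis(nr * nc, 0);  // visited-edge bitmask per pixel
  auto idx = [&](int r, int c) { return c * nr + r; };
  auto on = [&](int r, int c) {
    return r >= 0 && r < nr && c >= 0 && c < nc && skel(r, c);
  };
  // graph edge along direction k; diagonal edges are dropped when a shared
  // 4-neighbour provides the connection (avoids triangle double counts on
  // staircase skeletons)
  auto edge = [&](int r, int c, int k) {
    if (!on(r + DR[k], c + DC[k])) return false;
    if (DR[k] != 0 && DC[k] != 0) {
      if (on(r + DR[k], c) || on(r, c + DC[k])) return false;
    }
    return true;
  };
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (skel(r, c)) {
        int d = 0;
        for (int k = 0; k < 8; ++k) d += edge(r, c, k);
        deg[idx(r, c)] = (unsigned char)d;
      }

  double len[2] = {0.0, 0.0};
  // skeletonization erodes ~1 px from each free line end; compensated per
  // open (degree-1) chain terminus
  const double end_corr = 1.2;
  std::vector<int> chain_r, chain_c;
  chain_r.reserve(4096);
  chain_c.reserve(4096);

  // measure a chain as chords of `step` pixels, anchored at sharp corners so
  // right-angle turns are not cut; staircase wiggle is smoothed through
  auto measure = [&](const std::vector<int>& cr, const std::vector<int>& cc) {
    int n = (int)cr.size();
    if (n < 2) return;
    std::vector<int> anchors;
    anchors.push_back(0);
    int w = step;
    int last = 0;
    for (int i = w; i + w < n; ++i) {
      double ar = cr[i] - cr[i - w], ac = cc[i] - cc[i - w];
      double br = cr[i + w] - cr[i], bc = cc[i + w] - cc[i];
      double dot = ar * br + ac * bc;
      double na = std::sqrt(ar * ar + ac * ac), nb = std::sqrt(br * br + bc * bc);
      if (na > 0 && nb > 0 && dot / (na * nb) < 0.5 && i - last >= w) {
        anchors.push_back(i);
        last = i;
      }
    }
    anchors.push_back(n - 1);
    if (deg[idx(cr[0], cc[0])] == 1)
      len[lab(cr[0], cc[0]) == 1 ? 1 : 0] += end_corr;
    if (deg[idx(cr[n - 1], cc[n - 1])] == 1)
      len[lab(cr[n - 1], cc[n - 1]) == 1 ? 1 : 0] += end_corr;
    for (size_t a = 0; a + 1 < anchors.size(); ++a) {
      for (int i = anchors[a]; i < anchors[a + 1]; i += step) {
        int j = std::min(i + step, anchors[a + 1]);
        double dr = cr[j] - cr[i], dc = cc[j] - cc[i];
        double L = std::sqrt(dr * dr + dc * dc);
        int m = (i + j) / 2;
        int l = lab(cr[m], cc[m]);
        len[l == 1 ? 1 : 0] += L;
      }
    }
  };

  auto walk = [&](int r0, int c0, int k0) {
    // walk from (r0,c0) along direction k0 until a non-degree-2 pixel,
    // a visited edge, or return to start
    chain_r.clear();
    chain_c.clear();
    chain_r.push_back(r0);
    chain_c.push_back(c0);
    int r = r0, c = c0, k = k0;
    while (true) {
      evis[idx(r, c)] |= (1 << k);
      int rn = r + DR[k], cn = c + DC[k];
      evis[idx(rn, cn)] |= (1 << (7 - k));  // reverse direction bit
      chain_r.push_back(rn);
      chain_c.push_back(cn);
      if (deg[idx(rn, cn)] != 2) break;
      // continue through the degree-2 pixel
      int knext = -1;
      for (int kk = 0; kk < 8; ++kk) {
        if (!edge(rn, cn, kk)) continue;
        int rr = rn + DR[kk], cc2 = cn + DC[kk];
        if (rr == r && cc2 == c) continue;
        knext = kk;
      }
      if (knext < 0) break;
      if (evis[idx(rn, cn)] & (1 << knext)) break;  // closing a cycle
      r = rn;
      c = cn;
      k = knext;
    }
    measure(chain_r, chain_c);
  };

  // chains from junctions and endpoints
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!skel(r, c) || deg[idx(r, c)] == 2) continue;
      for (int k = 0; k < 8; ++k) {
        if (!edge(r, c, k)) continue;
        if (evis[idx(r, c)] & (1 << k)) continue;
        walk(r, c, k);
      }
    }
  // remaining pure cycles
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!skel(r, c) || deg[idx(r, c)] != 2) continue;
      for (int k = 0; k < 8; ++k) {
        if (!edge(r, c, k)) continue;
        if (evis[idx(r, c)] & (1 << k)) continue;
        walk(r, c, k);
      }
    }
  return NumericVector::create(_["gap"] = len[0], _["cnt"] = len[1]);
}

// ---------------------------------------------------------------------------
// Rasterize polylines into an intensity image. Each pixel within `halo`
// of a segment receives max-composited intensity 1 - d/halo (a soft ~1-2 px
// wide curve with a continuous core regardless of angle; coincident curves
// do not stack). Coordinates are continuous pixel units, 0-based,
// x = column, y = row.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_draw_polylines(int nrow, int ncol, List polylines,
                                 double intensity = 1.0, double halo = 1.5) {
  NumericMatrix img(nrow, ncol);
  const double sub = 8.0;   // split segments to keep bounding boxes tight
  for (int p = 0; p < polylines.size(); ++p) {
    NumericMatrix pts = polylines[p];
    int n = pts.nrow();
    for (int i = 0; i + 1 < n; ++i) {
      double X0 = pts(i, 0), Y0 = pts(i, 1);
      double X1 = pts(i + 1, 0), Y1 = pts(i + 1, 1);
      double L = std::sqrt((X1 - X0) * (X1 - X0) + (Y1 - Y0) * (Y1 - Y0));
      int nseg = std::max(1, (int)std::ceil(L / sub));
      for (int s = 0; s < nseg; ++s) {
        double x0 = X0 + (X1 - X0) * s / nseg, y0 = Y0 + (Y1 - Y0) * s / nseg;
        double x1 = X0 + (X1 - X0) * (s + 1) / nseg,
               y1 = Y0 + (Y1 - Y0) * (s + 1) / nseg;
        int clo = std::max(0, (int)std::floor(std::min(x0, x1) - halo - 1));
        int chi = std::min(ncol - 1, (int)std::ceil(std::max(x0, x1) + halo + 1));
        int rlo = std::max(0, (int)std::floor(std::min(y0, y1) - halo - 1));
        int rhi = std::min(nrow - 1, (int)std::ceil(std::max(y0, y1) + halo + 1));
        double dx = x1 - x0, dy = y1 - y0;
        double seg2 = dx * dx + dy * dy;
        for (int c = clo; c <= chi; ++c) {
          for (int r = rlo; r <= rhi; ++r) {
            double px = c - x0, py = r - y0;
            double t = seg2 > 0 ? (px * dx + py * dy) / seg2 : 0.0;
            t = std::max(0.0, std::min(1.0, t));
            double ex = px - t * dx, ey = py - t * dy;
            double d = std::sqrt(ex * ex + ey * ey);
            if (d < halo) {
              double w = intensity * (1.0 - d / halo);
              if (w > img(r, c)) img(r, c) = w;
            }
          }
        }
      }
    }
  }
  return img;
}

// ---------------------------------------------------------------------------
// Union-of-disks rasterization: pixel TRUE iff its center lies inside any
// disk. Centers/radii in pixel units (0-based continuous coordinates).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalMatrix cpp_fill_disks(int nrow, int ncol, NumericVector x,
                             NumericVector y, NumericVector r) {
  LogicalMatrix img(nrow, ncol);
  for (int i = 0; i < x.size(); ++i) {
    double cx = x[i], cy = y[i], rad = r[i], r2 = rad * rad;
    int rlo = std::max(0, (int)std::floor(cy - rad - 1));
    int rhi = std::min(nrow - 1, (int)std::ceil(cy + rad + 1));
    int clo = std::max(0, (int)std::floor(cx - rad - 1));
    int chi = std::min(ncol - 1, (int)std::ceil(cx + rad + 1));
    for (int c = clo; c <= chi; ++c) {
      double dx = (c + 0.5) - cx;
      for (int rr = rlo; rr <= rhi; ++rr) {
        double dy = (rr + 0.5) - cy;
        if (dx * dx + dy * dy <= r2) img(rr, c) = true;
      }
    }
  }
  return img;
}

// ---------------------------------------------------------------------------
// Exact split of polyline length by raster label. Each segment is cut at
// every pixel-boundary crossing; each piece is assigned the label of the
// pixel containing its midpoint. Coordinates in physical units with pixel
// size `res` and origin (`ox`,`oy`) at the lower-left corner of pixel [1,1]
// (row = y index, col = x index). Points outside the grid count as gap.
// Returns c(gap, cnt) in physical units.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_polyline_label_len(NumericMatrix pts, LogicalMatrix cnt,
                                     double res, double ox, double oy) {
  int nr = cnt.nrow(), nc = cnt.ncol();
  double len[2] = {0.0, 0.0};
  std::vector<double> ts;
  for (int i = 0; i + 1 < pts.nrow(); ++i) {
    double x0 = pts(i, 0), y0 = pts(i, 1);
    double x1 = pts(i + 1, 0), y1 = pts(i + 1, 1);
    double dx = x1 - x0, dy = y1 - y0;
    double L = std::sqrt(dx * dx + dy * dy);
    if (L <= 0) continue;
    ts.clear();
    ts.push_back(0.0);
    ts.push_back(1.0);
    if (dx != 0) {
      int klo = (int)std::ceil((std::min(x0, x1) - ox) / res);
      int khi = (int)std::floor((std::max(x0, x1) - ox) / res);
      for (int k = klo; k <= khi; ++k) {
        double t = (ox + k * res - x0) / dx;
        if (t > 0 && t < 1) ts.push_back(t);
      }
    }
    if (dy != 0) {
      int klo = (int)std::ceil((std::min(y0, y1) - oy) / res);
      int khi = (int)std::floor((std::max(y0, y1) - oy) / res);
      for (int k = klo; k <= khi; ++k) {
        double t = (oy + k * res - y0) / dy;
        if (t > 0 && t < 1) ts.push_back(t);
      }
    }
    std::sort(ts.begin(), ts.end());
    for (size_t j = 0; j + 1 < ts.size(); ++j) {
      double tm = 0.5 * (ts[j] + ts[j + 1]);
      double xm = x0 + tm * dx, ym = y0 + tm * dy;
      int c = (int)std::floor((xm - ox) / res);
      int r = (int)std::floor((ym - oy) / res);
      int l = (r >= 0 && r < nr && c >= 0 && c < nc && cnt(r, c)) ? 1 : 0;
      len[l] += (ts[j + 1] - ts[j]) * L;
    }
  }
  return NumericVector::create(_["gap"] = len[0], _["cnt"] = len[1]);
}
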