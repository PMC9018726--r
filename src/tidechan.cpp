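#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Connected-component labelling by flood fill.
// mask: integer matrix, nonzero = foreground. connectivity: 4 or 8.
// Returns integer matrix of labels 1..k (0 = background), labelled in
// row-major scan order so label ids are deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr8[8] = {-1,-1,-1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1,-1, 1,-1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = { 0,-1, 1, 0};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r * nc + c);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p / nc, pc = p % nc;
        for (int k = 0; k < nn; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (mask(qr, qc) != 0 && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(qr * nc + qc);
          }
        }
      }
    }
  }
  return lab;
}

// Exact Euclidean distance transform with nearest-site allocation.
// sites: integer matrix; >0 entries are site pixels carrying a label
// (e.g. channel component id), 0 elsewhere. For every pixel returns the
// squared pixel distance to the nearest site pixel (centre to centre)
// and the label of that site; ties broken toward the smaller label,
// matching a brute-force scan over all sites.
// Exactness: for a fixed column j the nearest site to row r is either the
// closest site row above or below r in that column, so scanning columns
// outward from c and testing those two candidates covers every possible
// global minimiser; the scan stops when (c-j)^2 alone exceeds the best
// squared distance found so far.
// [[Rcpp::export]]
List cpp_edt_alloc(const IntegerMatrix& sites) {
  const int nr = sites.nrow(), nc = sites.ncol();
  // per-column nearest site row at-or-above / at-or-below each row
  std::vector<int> up(nr * nc, -1), down(nr * nc, -1);
  for (int c = 0; c < nc; ++c) {
    int last = -1;
    for (int r = 0; r < nr; ++r) {
      if (sites(r, c) > 0) last = r;
      up[r * nc + c] = last;
    }
    last = -1;
    for (int r = nr - 1; r >= 0; --r) {
      if (sites(r, c) > 0) last = r;
      down[r * nc + c] = last;
    }
  }
  NumericMatrix d2(nr, nc);
  IntegerMatrix alloc(nr, nc);
  std::fill(alloc.begin(), alloc.end(), 0);
  const double INF = R_PosInf;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double best = INF;
      int bestLab = 0;
      for (int off = 0; off < nc; ++off) {
        double dx2 = (double)off * off;
        if (dx2 > best) break;
        for (int s = 0; s < 2; ++s) {
          int j = (s == 0) ? c - off : c + off;
          if (off == 0 && s == 1) continue;
          if (j < 0 || j >= nc) continue;
          int cand[2] = { up[r * nc + j], down[r * nc + j] };
          for (int t = 0; t < 2; ++t) {
            int rr = cand[t];
            if (rr < 0) continue;
            double dd = dx2 + (double)(r - rr) * (r - rr);
            int labv = sites(rr, j);
            if (dd < best || (dd == best && labv < bestLab)) {
              if (dd < best) { best = dd; bestLab = labv; }
              else bestLab = labv;
            }
          }
        }
      }
      d2(r, c) = best;
      alloc(r, c) = bestLab;
    }
  }
  return List::create(_["dist2"] = d2, _["label"] = alloc);
}

static inline int nbr_sum(const IntegerMatrix& m, int r, int c) {
  int s = 0;
  for (int dr = -1; dr <= 1; ++dr)
    for (int dc = -1; dc <= 1; ++dc) {
      if (dr == 0 && dc == 0) continue;
      int rr = r + dr, cc = c + dc;
      if (rr >= 0 && rr < m.nrow() && cc >= 0 && cc < m.ncol()) s += m(rr, cc);
    }
  return s;
}

// Zhang-Suen morphological thinning to a 1-pixel, 8-connected skeleton.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img = clone(mask);
  for (int i = 0; i < nr * nc; ++i) img[i] = img[i] ? 1 : 0;
  auto P = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return img(r, c);
  };
  bool changed = true;
  std::vector<int> kill;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (!img(r, c)) continue;
          // neighbours clockwise from north: p2..p9
          int p2 = P(r-1,c),   p3 = P(r-1,c+1), p4 = P(r,c+1), p5 = P(r+1,c+1);
          int p6 = P(r+1,c),   p7 = P(r+1,c-1), p8 = P(r,c-1), p9 = P(r-1,c-1);
          int B = p2+p3+p4+p5+p6+p7+p8+p9;
          if (B < 2 || B > 6) continue;
          int A = (p2==0&&p3==1) + (p3==0&&p4==1) + (p4==0&&p5==1) +
                  (p5==0&&p6==1) + (p6==0&&p7==1) + (p7==0&&p8==1) +
                  (p8==0&&p9==1) + (p9==0&&p2==1);
          if (A != 1) continue;
          if (step == 0) {
            if (p2*p4*p6 != 0 || p4*p6*p8 != 0) continue;
          } else {
            if (p2*p4*p8 != 0 || p2*p6*p8 != 0) continue;
          }
          kill.push_back(r * nc + c);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (int p : kill) img(p / nc, p % nc) = 0;
      }
    }
  }
  // minimal-skeleton post-pass: sequentially delete non-endpoint pixels
  // whose foreground neighbours form a single 8-connected set without
  // them (staircase elbows and 2x2 clumps the parallel passes leave);
  // simple-point removal preserves topology, so components are kept.
  changed = true;
  while (changed) {
    changed = false;
    for (int r = 0; r < nr; ++r) {
      for (int c = 0; c < nc; ++c) {
        if (!img(r, c)) continue;
        int nrr[8], ncc[8], n = 0;
        for (int dr = -1; dr <= 1; ++dr)
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            if (P(r + dr, c + dc)) { nrr[n] = r + dr; ncc[n] = c + dc; ++n; }
          }
        if (n <= 1) continue;                // endpoint or isolated
        // count components among neighbours (Chebyshev adjacency)
        int compid[8];
        for (int i = 0; i < n; ++i) compid[i] = i;
        for (int i = 0; i < n; ++i)
          for (int j = i + 1; j < n; ++j)
            if (std::abs(nrr[i] - nrr[j]) <= 1 &&
                std::abs(ncc[i] - ncc[j]) <= 1) {
              int a = compid[i], b = compid[j];
              if (a != b)
                for (int t = 0; t < n; ++t)
                  if (compid[t] == b) compid[t] = a;
            }
        int ncomp = 0;
        for (int i = 0; i < n; ++i) if (compid[i] == i) ++ncomp;
        if (ncomp == 1) { img(r, c) = 0; changed = true; }
      }
    }
  }
  return img;
}

// Moving-median filter over a window x window neighbourhood, truncated at
// the grid border; NA cells are excluded from each window and stay NA.
// [[Rcpp::export]]
NumericMatrix cpp_moving_median(const NumericMatrix& x, int window) {
  const int nr = x.nrow(), nc = x.ncol();
  const int h = window / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)window * window);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (NumericMatrix::is_na(x(r, c))) { out(r, c) = NA_REAL; continue; }
      buf.clear();
      int r0 = std::max(0, r - h), r1 = std::min(nr - 1, r + h);
      int c0 = std::max(0, c - h), c1 = std::min(nc - 1, c + h);
      for (int rr = r0; rr <= r1; ++rr)
        for (int cc = c0; cc <= c1; ++cc)
          if (!NumericMatrix::is_na(x(rr, cc))) buf.push_back(x(rr, cc));
      if (buf.empty()) { out(r, c) = NA_REAL; continue; }
      size_t n = buf.size(), mid = n / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (n % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + mid);
        med = 0.5 * (med + lo);
      }
      out(r, c) = med;
    }
  }
  return out;
}

// Count of 8-neighbours for every foreground pixel (0 for background);
// used to split a skeleton into junctions, endpoints and chains.
// With reduce = true, a diagonal adjacency is ignored when the two
// pixels share a rook neighbour in the mask (the thinning's staircase
// elbows otherwise read as spurious junction triangles).
// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_count(const IntegerMatrix& mask, bool reduce) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return mask(r, c) ? 1 : 0;
  };
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c)) { out(r, c) = 0; continue; }
      int s = 0;
      for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          if (!at(r + dr, c + dc)) continue;
          if (reduce && dr != 0 && dc != 0 &&
              (at(r, c + dc) || at(r + dr, c))) continue;
          ++s;
        }
      out(r, c) = s;
    }
  return out;
}
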