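#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 8-connected labelling of a binary mask (column-major, matching R matrices).
// [[Rcpp::export(name = ".label_components8")]]
IntegerMatrix label_components8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int k = stack.back(); stack.pop_back();
        int ci = k % nr, cj = k / nr;
        for (int d = 0; d < 8; ++d) {
          int ni = ci + dr[d], nj = cj + dc[d];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Outer boundary of one label traced along pixel edges ("crack" boundary,
// right-hand rule: the region stays on the right of the walking direction).
// Corner lattice: corner (r,c) is the top-left corner of pixel (r,c), 0-based.
static std::vector<std::pair<int,int> > trace_crack(const IntegerMatrix& lab,
                                                    int l, int r0, int c0) {
  const int nr = lab.nrow(), nc = lab.ncol();
  auto is = [&](int r, int c) {
    return r >= 0 && r < nr && c >= 0 && c < nc && lab(r, c) == l;
  };
  // directions on the corner lattice: 0 = +c (right), 1 = +r (down),
  // 2 = -c (left), 3 = -r (up)
  const int drr[4] = {0, 1, 0, -1};
  const int dcc[4] = {1, 0, -1, 0};
  // pixel on the right of direction d when standing at corner (r,c):
  auto right_pixel = [&](int r, int c, int d, int& pr, int& pc) {
    switch (d) {
      case 0: pr = r;     pc = c;     break;
      case 1: pr = r;     pc = c - 1; break;
      case 2: pr = r - 1; pc = c - 1; break;
      default: pr = r - 1; pc = c;    break;
    }
  };
  auto left_pixel = [&](int r, int c, int d, int& pr, int& pc) {
    switch (d) {
      case 0: pr = r - 1; pc = c;     break;
      case 1: pr = r;     pc = c;     break;
      case 2: pr = r;     pc = c - 1; break;
      default: pr = r - 1; pc = c - 1; break;
    }
  };
  std::vector<std::pair<int,int> > verts;
  // start at the top-left corner of pixel (r0, c0); pixel above is not l
  int r = r0, c = c0, d = 0;
  verts.push_back(std::make_pair(r, c));
  const long maxsteps = 8L * (long)nr * (long)nc + 16;
  for (long s = 0; s < maxsteps; ++s) {
    r += drr[d]; c += dcc[d];
    if (r == r0 && c == c0 && d >= 0 && verts.size() > 1) break;
    verts.push_back(std::make_pair(r, c));
    bool turned = false;
    for (int t = 0; t < 3; ++t) {           // prefer right, straight, left
      int ndir = (d + (t == 0 ? 1 : (t == 1 ? 0 : 3))) % 4;
      int rp, cp, lp, lc2;
      right_pixel(r, c, ndir, rp, cp);
      left_pixel(r, c, ndir, lp, lc2);
      if (is(rp, cp) && !is(lp, lc2)) { d = ndir; turned = true; break; }
    }
    if (!turned) d = (d + 2) % 4;           // dead end: reverse
  }
  return verts;
}

// Perimeter of the closed crack polygon after circular moving-average
// smoothing of the vertices (odd window w); smoothing removes the staircase
// over-estimate on oblique and curved edges while axis-aligned runs stay
// exact up to slight corner rounding.
static double smoothed_length(const std::vector<std::pair<int,int> >& v, int w) {
  const int n = (int)v.size();
  if (n < 2) return 0.0;
  double raw = 0.0;
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    raw += std::hypot((double)(v[j].first - v[i].first),
                      (double)(v[j].second - v[i].second));
  }
  if (n < 2 * w) return raw;
  const int h = w / 2;
  std::vector<double> sr(n), sc(n);
  for (int i = 0; i < n; ++i) {
    double ar = 0.0, ac = 0.0;
    for (int k = -h; k <= h; ++k) {
      int idx = ((i + k) % n + n) % n;
      ar += v[idx].first; ac += v[idx].second;
    }
    sr[i] = ar / w; sc[i] = ac / w;
  }
  double len = 0.0;
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    len += std::hypot(sr[j] - sr[i], sc[j] - sc[i]);
  }
  return len;
}

// Perimeters (pixel units) of labels 1..nlab from a label image whose holes
// have been filled; only the outer boundary of each label is traced.
// [[Rcpp::export(name = ".crack_perimeters")]]
NumericVector crack_perimeters(IntegerMatrix lab, int nlab, int window) {
  const int nr = lab.nrow(), nc = lab.ncol();
  NumericVector per(nlab, NA_REAL);
  std::vector<bool> done(nlab + 1, false);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l <= 0 || l > nlab || done[l]) continue;
      // first pixel of label l in this column scan: pixel above is not l
      std::vector<std::pair<int,int> > v = trace_crack(lab, l, i, j);
      per[l - 1] = smoothed_length(v, window);
      done[l] = true;
    }
  }
  return per;
}
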