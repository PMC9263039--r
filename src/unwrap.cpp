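#include <Rcpp.h>
#include <algorithm>
#include <functional>
#include <vector>
using namespace Rcpp;

// Reliability-sorted two-dimensional phase unwrapping.
//
// Pixels are merged into groups along 4-neighbour edges in order of
// decreasing edge reliability (reliability = inverse second-difference
// magnitude), adding the 2*pi multiple that makes the joined groups
// continuous.  Invalid pixels take no part and keep their input value.

static inline double wrap2pi(double d) {
  return d - 2.0 * M_PI * std::floor(d / (2.0 * M_PI) + 0.5);
}

struct Edge {
  double rel;
  int a, b; // linear pixel indices
};

// [[Rcpp::export(name = ".unwrap_reliability")]]
NumericMatrix unwrap_reliability(NumericMatrix wrapped, LogicalMatrix valid) {
  const int nr = wrapped.nrow(), nc = wrapped.ncol();
  const int n = nr * nc;
  if (valid.nrow() != nr || valid.ncol() != nc)
    stop("mask geometry mismatch");

  std::vector<double> val(wrapped.begin(), wrapped.end());
  std::vector<double> rel(n, 0.0);

  // pixel reliability: 1 / sqrt(sum of squared wrapped second differences)
  for (int j = 1; j < nc - 1; ++j) {
    for (int i = 1; i < nr - 1; ++i) {
      int k = i + j * nr;
      if (!valid[k]) continue;
      bool ok = valid[k - 1] && valid[k + 1] && valid[k - nr] && valid[k + nr] &&
                valid[k - nr - 1] && valid[k - nr + 1] &&
                valid[k + nr - 1] && valid[k + nr + 1];
      if (!ok) continue;
      double H  = wrap2pi(val[k - nr] - val[k]) - wrap2pi(val[k] - val[k + nr]);
      double V  = wrap2pi(val[k - 1]  - val[k]) - wrap2pi(val[k] - val[k + 1]);
      double D1 = wrap2pi(val[k - nr - 1] - val[k]) - wrap2pi(val[k] - val[k + nr + 1]);
      double D2 = wrap2pi(val[k + nr - 1] - val[k]) - wrap2pi(val[k] - val[k - nr + 1]);
      double d = std::sqrt(H * H + V * V + D1 * D1 + D2 * D2);
      rel[k] = 1.0 / (d + 1e-12);
    }
  }

  std::vector<Edge> edges;
  edges.reserve(2 * (size_t)n);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = i + j * nr;
      if (!valid[k]) continue;
      if (i + 1 < nr && valid[k + 1])
        edges.push_back({rel[k] + rel[k + 1], k, k + 1});
      if (j + 1 < nc && valid[k + nr])
        edges.push_back({rel[k] + rel[k + nr], k, k + nr});
    }
  }
  std::stable_sort(edges.begin(), edges.end(),
                   [](const Edge& x, const Edge& y) { return x.rel > y.rel; });

  // union-find; group members kept in linked lists so the smaller group can
  // be shifted eagerly by its 2*pi offset when two groups join
  std::vector<int> parent(n), nxt(n, -1), head(n), tail(n), size(n, 1);
  for (int k = 0; k < n; ++k) { parent[k] = k; head[k] = k; tail[k] = k; }
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };

  for (const Edge& e : edges) {
    int ra = find(e.a), rb = find(e.b);
    if (ra == rb) continue;
    // shift that makes val[b]-side continuous with val[a]-side
    double k2pi = 2.0 * M_PI *
      std::floor((val[e.a] - val[e.b]) / (2.0 * M_PI) + 0.5);
    if (size[ra] < size[rb]) {
      // shift the a-group by -k2pi instead
      for (int p = head[ra]; p != -1; p = nxt[p]) val[p] -= k2pi;
      parent[ra] = rb;
      nxt[tail[rb]] = head[ra]; tail[rb] = tail[ra];
      size[rb] += size[ra];
    } else {
      for (int p = head[rb]; p != -1; p = nxt[p]) val[p] += k2pi;
      parent[rb] = ra;
      nxt[tail[ra]] = head[rb]; tail[ra] = tail[rb];
      size[ra] += size[rb];
    }
  }

  NumericMatrix out(nr, nc);
  std::copy(val.begin(), val.end(), out.begin());
  return out;
}
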