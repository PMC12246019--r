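#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Voxel grids arrive as flat vectors in R's column-major order with an
// explicit dim; all linear indices crossing the R boundary are 1-based.

namespace {

struct Grid {
  int d1, d2, d3;
  Grid(IntegerVector dim) : d1(dim[0]), d2(dim[1]), d3(dim[2]) {}
  inline R_xlen_t n() const { return (R_xlen_t)d1 * d2 * d3; }
  inline void coords(R_xlen_t idx, int &i, int &j, int &k) const {
    i = idx % d1; idx /= d1; j = idx % d2; k = idx / d2;
  }
  inline R_xlen_t index(int i, int j, int k) const {
    return (R_xlen_t)i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
  }
  inline bool inside(int i, int j, int k) const {
    return i >= 0 && i < d1 && j >= 0 && j < d2 && k >= 0 && k < d3;
  }
};

// neighbour offsets for 6- or 26-connectivity
std::vector<std::array<int,3>> offsets(int conn) {
  std::vector<std::array<int,3>> off;
  if (conn == 6) {
    off = {{{1,0,0}},{{-1,0,0}},{{0,1,0}},{{0,-1,0}},{{0,0,1}},{{0,0,-1}}};
  } else {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          if (dx || dy || dz) off.push_back({{dx,dy,dz}});
  }
  return off;
}

} // namespace

// Breadth-first region growing over `allowed` starting from `seeds`.
// [[Rcpp::export]]
LogicalVector cpp_flood_fill(LogicalVector allowed, IntegerVector dim,
                             IntegerVector seeds, int conn) {
  Grid g(dim);
  std::vector<char> vis(g.n(), 0);
  std::queue<R_xlen_t> q;
  for (int s = 0; s < seeds.size(); ++s) {
    R_xlen_t idx = (R_xlen_t)seeds[s] - 1;
    if (idx < 0 || idx >= g.n())
      stop("flood fill seed out of range");
    if (allowed[idx] && !vis[idx]) { vis[idx] = 1; q.push(idx); }
  }
  std::vector<std::array<int,3>> off = offsets(conn);
  while (!q.empty()) {
    R_xlen_t cur = q.front(); q.pop();
    int i, j, k; g.coords(cur, i, j, k);
    for (size_t o = 0; o < off.size(); ++o) {
      int ni = i + off[o][0], nj = j + off[o][1], nk = k + off[o][2];
      if (!g.inside(ni, nj, nk)) continue;
      R_xlen_t nidx = g.index(ni, nj, nk);
      if (allowed[nidx] && !vis[nidx]) { vis[nidx] = 1; q.push(nidx); }
    }
  }
  LogicalVector out(g.n());
  for (R_xlen_t i = 0; i < g.n(); ++i) out[i] = vis[i] != 0;
  out.attr("dim") = dim;
  return out;
}

// Connected-component labels (1..K) of a binary mask; 0 outside the mask.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int conn) {
  Grid g(dim);
  IntegerVector lab(g.n(), 0);
  std::vector<std::array<int,3>> off = offsets(conn);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t start = 0; start < g.n(); ++start) {
    if (!mask[start] || lab[start]) continue;
    ++next;
    lab[start] = next; q.push(start);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int i, j, k; g.coords(cur, i, j, k);
      for (size_t o = 0; o < off.size(); ++o) {
        int ni = i + off[o][0], nj = j + off[o][1], nk = k + off[o][2];
        if (!g.inside(ni, nj, nk)) continue;
        R_xlen_t nidx = g.index(ni, nj, nk);
        if (mask[nidx] && !lab[nidx]) { lab[nidx] = next; q.push(nidx); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Multi-source BFS: propagate seed ids (nonzero entries of seed_ids) across
// `allowed`; each reachable voxel receives the id of the first seed front to
// arrive (FIFO order, deterministic). Unreached voxels keep 0.
// [[Rcpp::export]]
IntegerVector cpp_nearest_seed(IntegerVector seed_ids, LogicalVector allowed,
                               IntegerVector dim, int conn) {
  Grid g(dim);
  IntegerVector out(g.n(), 0);
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < g.n(); ++i)
    if (seed_ids[i] != 0) { out[i] = seed_ids[i]; q.push(i); }
  std::vector<std::array<int,3>> off = offsets(conn);
  while (!q.empty()) {
    R_xlen_t cur = q.front(); q.pop();
    int i, j, k; g.coords(cur, i, j, k);
    for (size_t o = 0; o < off.size(); ++o) {
      int ni = i + off[o][0], nj = j + off[o][1], nk = k + off[o][2];
      if (!g.inside(ni, nj, nk)) continue;
      R_xlen_t nidx = g.index(ni, nj, nk);
      if (allowed[nidx] && out[nidx] == 0) { out[nidx] = out[cur]; q.push(nidx); }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Naive per-voxel reference dilation with tie voxels: n synchronous rounds of
// unit Chebyshev growth. A background voxel bordered by exactly one distinct
// label takes it; by two or more distinct labels it becomes a permanent tie
// (assigned to no bone). Used as the brute-force oracle in tests.
// [[Rcpp::export]]
List cpp_dilate_brute(IntegerVector labels, IntegerVector dim, int n) {
  Grid g(dim);
  std::vector<int> cur(labels.begin(), labels.end());
  std::vector<char> tie(g.n(), 0);
  std::vector<std::array<int,3>> off = offsets(26);
  for (int round = 0; round < n; ++round) {
    std::vector<int> nxt(cur);
    std::vector<char> ntie(tie);
    for (R_xlen_t idx = 0; idx < g.n(); ++idx) {
      if (cur[idx] != 0 || tie[idx]) continue;
      int i, j, k; g.coords(idx, i, j, k);
      int first = 0; bool multi = false;
      for (size_t o = 0; o < off.size(); ++o) {
        int ni = i + off[o][0], nj = j + off[o][1], nk = k + off[o][2];
        if (!g.inside(ni, nj, nk)) continue;
        int v = cur[g.index(ni, nj, nk)];
        if (v == 0) continue;
        if (first == 0) first = v;
        else if (v != first) { multi = true; break; }
      }
      if (multi) { ntie[idx] = 1; }
      else if (first != 0) nxt[idx] = first;
    }
    cur.swap(nxt); tie.swap(ntie);
  }
  IntegerVector outl(cur.begin(), cur.end());
  outl.attr("dim") = dim;
  LogicalVector outt(g.n());
  for (R_xlen_t i = 0; i < g.n(); ++i) outt[i] = tie[i] != 0;
  outt.attr("dim") = dim;
  return List::create(_["labels"] = outl, _["ties"] = outt);
}

// Naive per-voxel reference majority filter over a (2r+1)^3 window clipped at
// the borders; strict majority of the clipped window keeps/creates the voxel.
// [[Rcpp::export]]
LogicalVector cpp_majority_brute(LogicalVector mask, IntegerVector dim, int r) {
  Grid g(dim);
  LogicalVector out(g.n());
  for (R_xlen_t idx = 0; idx < g.n(); ++idx) {
    int i, j, k; g.coords(idx, i, j, k);
    int lo1 = std::max(0, i - r), hi1 = std::min(g.d1 - 1, i + r);
    int lo2 = std::max(0, j - r), hi2 = std::min(g.d2 - 1, j + r);
    int lo3 = std::max(0, k - r), hi3 = std::min(g.d3 - 1, k + r);
    long cnt = 0, tot = 0;
    for (int kk = lo3; kk <= hi3; ++kk)
      for (int jj = lo2; jj <= hi2; ++jj)
        for (int ii = lo1; ii <= hi1; ++ii) {
          ++tot;
          if (mask[g.index(ii, jj, kk)]) ++cnt;
        }
    out[idx] = 2 * cnt > tot;
  }
  out.attr("dim") = dim;
  return out;
}

// Multi-source BFS recording, per voxel, the first two distinct seed ids to
// arrive. Used to attribute each suture voxel to its flanking bone pair.
// [[Rcpp::export]]
List cpp_first_two_ids(IntegerVector seed_ids, LogicalVector allowed,
                       IntegerVector dim, int conn) {
  Grid g(dim);
  IntegerVector id1(g.n(), 0), id2(g.n(), 0);
  // queue carries (voxel, id) pairs
  std::queue<std::pair<R_xlen_t,int>> q;
  for (R_xlen_t i = 0; i < g.n(); ++i)
    if (seed_ids[i] != 0) { id1[i] = seed_ids[i]; q.push({i, seed_ids[i]}); }
  std::vector<std::array<int,3>> off = offsets(conn);
  while (!q.empty()) {
    R_xlen_t cur = q.front().first;
    int id = q.front().second;
    q.pop();
    int i, j, k; g.coords(cur, i, j, k);
    for (size_t o = 0; o < off.size(); ++o) {
      int ni = i + off[o][0], nj = j + off[o][1], nk = k + off[o][2];
      if (!g.inside(ni, nj, nk)) continue;
      R_xlen_t nidx = g.index(ni, nj, nk);
      if (!allowed[nidx]) continue;
      if (id1[nidx] == 0) { id1[nidx] = id; q.push({nidx, id}); }
      else if (id1[nidx] != id && id2[nidx] == 0) {
        id2[nidx] = id; q.push({nidx, id});
      }
    }
  }
  id1.attr("dim") = dim; id2.attr("dim") = dim;
  return List::create(_["id1"] = id1, _["id2"] = id2);
}

// ---- nearest neighbours (k-d tree) for rigid surface registration ----

namespace {

struct KDTree {
  const double *pts; // 3 x n? stored n x 3 column-major from R: pts[i + n*c]
  R_xlen_t n;
  std::vector<int> idx;    // permutation of point indices
  std::vector<int> left, right, axis;
  std::vector<double> split_;
  std::vector<int> lo_, hi_; // leaf ranges
  int build(int lo, int hi) {
    int node = (int)axis.size();
    axis.push_back(-1); left.push_back(-1); right.push_back(-1);
    split_.push_back(0.0);
    lo_.push_back(lo); hi_.push_back(hi);
    if (hi - lo <= 8) return node; // leaf
    // split on widest axis at the median
    double mn[3], mx[3];
    for (int c = 0; c < 3; ++c) { mn[c] = R_PosInf; mx[c] = R_NegInf; }
    for (int t = lo; t < hi; ++t)
      for (int c = 0; c < 3; ++c) {
        double v = pts[idx[t] + n * c];
        if (v < mn[c]) mn[c] = v;
        if (v > mx[c]) mx[c] = v;
      }
    int ax = 0;
    for (int c = 1; c < 3; ++c) if (mx[c] - mn[c] > mx[ax] - mn[ax]) ax = c;
    int mid = (lo + hi) / 2;
    const double *p = pts; R_xlen_t nn = n;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [p, nn, ax](int a, int b) {
                       return p[a + nn * ax] < p[b + nn * ax];
                     });
    axis[node] = ax;
    split_[node] = pts[idx[mid] + n * ax];
    int l = build(lo, mid), r = build(mid, hi);
    left[node] = l; right[node] = r;
    return node;
  }
  void search(int node, const double *q, int &best, double &bd) const {
    if (axis[node] < 0) { // leaf
      for (int t = lo_[node]; t < hi_[node]; ++t) {
        int i = idx[t];
        double d = 0;
        for (int c = 0; c < 3; ++c) {
          double diff = pts[i + n * c] - q[c];
          d += diff * diff;
        }
        if (d < bd) { bd = d; best = i; }
      }
      return;
    }
    int ax = axis[node];
    double split = split_[node];
    int near = q[ax] < split ? left[node] : right[node];
    int far = q[ax] < split ? right[node] : left[node];
    search(near, q, best, bd);
    double diff = q[ax] - split;
    if (diff * diff < bd) search(far, q, best, bd);
  }
};

} // namespace

// Index (1-based) of the nearest reference point for each query point.
// [[Rcpp::export]]
IntegerVector cpp_nn_index(NumericMatrix query, NumericMatrix ref) {
  KDTree tree;
  tree.pts = REAL(ref);
  tree.n = ref.nrow();
  tree.idx.resize(tree.n);
  for (R_xlen_t i = 0; i < tree.n; ++i) tree.idx[i] = (int)i;
  tree.build(0, (int)tree.n);
  R_xlen_t m = query.nrow(), nq = m;
  IntegerVector out(m);
  for (R_xlen_t i = 0; i < nq; ++i) {
    double q[3] = { query(i, 0), query(i, 1), query(i, 2) };
    int best = -1; double bd = R_PosInf;
    tree.search(0, q, best, bd);
    out[i] = best + 1;
  }
  return out;
}
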