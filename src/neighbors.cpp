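// Exact spatial queries over point clouds in log10 parameter coordinates:
// a KD-tree supporting fixed-radius retrieval (spanning-forest construction)
// and k-nearest-neighbour queries (connectivity-graph refinement).

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct KDTree {
  int n, d;
  std::vector<double> pts;   // row-major n x d
  struct Node { int lo, hi, axis, left, right; double split; };
  std::vector<Node> nodes;
  std::vector<int> perm;
  static const int LEAF = 12;

  KDTree(const NumericMatrix& m) : n(m.nrow()), d(m.ncol()), pts(n * d) {
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < d; ++j) pts[i * d + j] = m(i, j);
    perm.resize(n);
    for (int i = 0; i < n; ++i) perm[i] = i;
    if (n > 0) build(0, n);
  }

  int build(int lo, int hi) {
    Node nd;
    nd.lo = lo; nd.hi = hi; nd.left = nd.right = -1;
    nd.axis = -1; nd.split = 0.0;
    int id = (int)nodes.size();
    nodes.push_back(nd);
    if (hi - lo <= LEAF) return id;
    // widest axis
    int ax = 0;
    double best = -1.0;
    for (int j = 0; j < d; ++j) {
      double mn = pts[perm[lo] * d + j], mx = mn;
      for (int i = lo + 1; i < hi; ++i) {
        double v = pts[perm[i] * d + j];
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      if (mx - mn > best) { best = mx - mn; ax = j; }
    }
    int mid = (lo + hi) / 2;
    std::nth_element(perm.begin() + lo, perm.begin() + mid,
                     perm.begin() + hi,
                     [&](int a, int b) {
                       return pts[a * d + ax] < pts[b * d + ax];
                     });
    nodes[id].axis = ax;
    nodes[id].split = pts[perm[mid] * d + ax];
    int L = build(lo, mid);
    int R = build(mid, hi);
    nodes[id].left = L;
    nodes[id].right = R;
    return id;
  }

  double dist2(const double* q, int i) const {
    double s = 0.0;
    const double* p = &pts[i * d];
    for (int j = 0; j < d; ++j) { double t = q[j] - p[j]; s += t * t; }
    return s;
  }

  // indices within radius r of q, optionally skipping flagged points
  void radius(const double* q, double r, std::vector<int>& out,
              const std::vector<char>* skip) const {
    if (n == 0) return;
    double r2 = r * r;
    std::vector<int> stack;
    stack.push_back(0);
    while (!stack.empty()) {
      int id = stack.back(); stack.pop_back();
      const Node& nd = nodes[id];
      if (nd.axis < 0) {
        for (int i = nd.lo; i < nd.hi; ++i) {
          int p = perm[i];
          if (skip && (*skip)[p]) continue;
          if (dist2(q, p) <= r2) out.push_back(p);
        }
        continue;
      }
      double diff = q[nd.axis] - nd.split;
      if (diff <= r) stack.push_back(nd.left);
      if (diff >= -r) stack.push_back(nd.right);
    }
  }

  // k nearest neighbours (exact); returns indices sorted by distance
  void knn(const double* q, int k, std::vector<int>& idx,
           std::vector<double>& dd) const {
    typedef std::pair<double, int> P;
    std::priority_queue<P> heap;   // max-heap on distance
    knn_rec(0, q, k, heap);
    idx.clear(); dd.clear();
    while (!heap.empty()) {
      idx.push_back(heap.top().second);
      dd.push_back(std::sqrt(heap.top().first));
      heap.pop();
    }
    std::reverse(idx.begin(), idx.end());
    std::reverse(dd.begin(), dd.end());
  }

  void knn_rec(int id, const double* q, int k,
               std::priority_queue<std::pair<double, int> >& heap) const {
    const Node& nd = nodes[id];
    if (nd.axis < 0) {
      for (int i = nd.lo; i < nd.hi; ++i) {
        int p = perm[i];
        double d2 = dist2(q, p);
        if ((int)heap.size() < k) heap.push(std::make_pair(d2, p));
        else if (d2 < heap.top().first) {
          heap.pop();
          heap.push(std::make_pair(d2, p));
        }
      }
      return;
    }
    double diff = q[nd.axis] - nd.split;
    int near = diff < 0 ? nd.left : nd.right;
    int far = diff < 0 ? nd.right : nd.left;
    knn_rec(near, q, k, heap);
    if ((int)heap.size() < k || diff * diff < heap.top().first)
      knn_rec(far, q, k, heap);
  }
};

} // namespace

// Spanning forest of the Delta-graph by the queue algorithm: BFS from each
// unvisited point, adding edges only to yet-unvisited points within Delta.
// Component labels equal those of the full Delta-graph.
// [[Rcpp::export]]
List cpp_spanning_forest(NumericMatrix points, double delta) {
  int n = points.nrow(), d = points.ncol();
  IntegerVector labels(n, 0);
  std::vector<int> efrom, eto;
  if (n == 0)
    return List::create(_["labels"] = labels,
                        _["edges"] = IntegerMatrix(0, 2));
  KDTree tree(points);
  std::vector<char> visited(n, 0);
  std::vector<double> q(d);
  int label = 0;
  std::vector<int> queue_;
  std::vector<int> nbrs;
  for (int s = 0; s < n; ++s) {
    if (visited[s]) continue;
    ++label;
    visited[s] = 1;
    queue_.clear();
    queue_.push_back(s);
    size_t head = 0;
    while (head < queue_.size()) {
      int j = queue_[head++];
      labels[j] = label;
      for (int t = 0; t < d; ++t) q[t] = points(j, t);
      nbrs.clear();
      tree.radius(q.data(), delta, nbrs, &visited);
      for (size_t a = 0; a < nbrs.size(); ++a) {
        int k = nbrs[a];
        visited[k] = 1;
        efrom.push_back(j + 1);
        eto.push_back(k + 1);
        queue_.push_back(k);
      }
      if (head % 8192 == 0) Rcpp::checkUserInterrupt();
    }
  }
  IntegerMatrix edges((int)efrom.size(), 2);
  for (size_t i = 0; i < efrom.size(); ++i) {
    edges(i, 0) = efrom[i];
    edges(i, 1) = eto[i];
  }
  return List::create(_["labels"] = labels, _["edges"] = edges);
}

// [[Rcpp::export]]
List cpp_knn(NumericMatrix ref, NumericMatrix query, int k) {
  if (ref.ncol() != query.ncol()) stop("dimension mismatch");
  int nq = query.nrow(), d = query.ncol();
  if (k > ref.nrow()) k = ref.nrow();
  KDTree tree(ref);
  IntegerMatrix idx(nq, k);
  NumericMatrix dist(nq, k);
  std::vector<double> q(d);
  std::vector<int> ii;
  std::vector<double> dd;
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < d; ++j) q[j] = query(i, j);
    tree.knn(q.data(), k, ii, dd);
    for (int j = 0; j < k; ++j) {
      idx(i, j) = ii[j] + 1;
      dist(i, j) = dd[j];
    }
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}
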