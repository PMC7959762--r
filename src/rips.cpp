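// Vietoris-Rips persistence over Z2 for dimensions 0 and 1.
//
// Dim 0 is computed by Kruskal-style union-find on the edge filtration
// (finite deaths are the MST edge diameters).  Dim 1 is computed as
// persistent cohomology: the coboundary columns of the edges are reduced
// in reverse filtration order, with
//   - clearing: MST edges are death simplexes of dim-0 pairs and skipped;
//   - lazy heap columns: the working column is a binary heap in which
//     duplicate entries cancel (Z2) when the pivot is popped, so column
//     additions never materialize the full column;
//   - lazy column storage: only pivot -> owning edge is kept, a reduced
//     column is reconstructed on demand and memoized.
// This is the standard design for Rips persistence at this scale; the
// barcode is identical to the one from boundary-matrix reduction.
//
// All values returned are simplex diameters; the R wrapper converts to
// the radius (epsilon) scale.  Simplexes are ordered by (diameter, then
// lexicographic vertex tuple), fixing the pairing deterministically.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

namespace {

struct DisjointSet {
  std::vector<int> parent, rank_;
  explicit DisjointSet(int n) : parent(n), rank_(n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    if (rank_[a] == rank_[b]) ++rank_[a];
    return true;
  }
};

struct Edge { double diam; int i, j; };

// a triangle entry of a coboundary column, ordered by forward filtration
// position (diameter, then lexicographic vertex tuple)
struct Tri {
  double diam; int i, j, k;
  bool operator<(const Tri& o) const {
    if (diam != o.diam) return diam < o.diam;
    if (i != o.i) return i < o.i;
    if (j != o.j) return j < o.j;
    return k < o.k;
  }
  bool operator>(const Tri& o) const { return o < *this; }
  bool operator==(const Tri& o) const {
    return i == o.i && j == o.j && k == o.k;
  }
};

// min-heap on the forward order; the top is the column's pivot
// (the row that comes last in the reversed order used for cohomology)
typedef std::priority_queue<Tri, std::vector<Tri>, std::greater<Tri>> Column;

// pop the pivot, cancelling duplicate entries mod 2
bool pop_pivot(Column& col, Tri& out) {
  while (!col.empty()) {
    Tri t = col.top();
    col.pop();
    if (!col.empty() && col.top() == t) {
      col.pop(); // pair cancels over Z2
    } else {
      out = t;
      return true;
    }
  }
  return false;
}

class Dim1Reducer {
public:
  Dim1Reducer(const NumericMatrix& dist, const std::vector<Edge>& edges,
              double max_diam)
    : dist_(dist), edges_(edges), n_(dist.nrow()), max_diam_(max_diam) {
    owner_.reserve(edges.size());
  }

  // process one non-MST edge column (callers go in reverse filtration
  // order); appends a (birth, death) pair when one is found
  void process(int e, std::vector<double>& births, std::vector<double>& deaths) {
    Column col;
    push_cofacets(e, col);
    const double de = edges_[e].diam;
    Tri piv;
    while (pop_pivot(col, piv)) {
      auto it = owner_.find(key(piv));
      if (it == owner_.end()) {
        owner_.emplace(key(piv), e);
        if (piv.diam > de) { births.push_back(de); deaths.push_back(piv.diam); }
        return;
      }
      add_owner_column(it->second, col); // piv cancels against owner's pivot
    }
    // reduced to zero: essential 1-cycle (only under a finite max_diam)
    births.push_back(de);
    deaths.push_back(R_PosInf);
  }

private:
  int64_t key(const Tri& t) const {
    return (static_cast<int64_t>(t.i) * n_ + t.j) * n_ + t.k;
  }

  void push_cofacets(int e, Column& col) const {
    const int vi = edges_[e].i, vj = edges_[e].j;
    const double de = edges_[e].diam;
    for (int k = 0; k < n_; ++k) {
      if (k == vi || k == vj) continue;
      double d = std::max(de, std::max(dist_(vi, k), dist_(vj, k)));
      if (d > max_diam_) continue;
      int a = vi, b = vj, c = k;
      if (c < a) std::swap(a, c);
      if (c < b) std::swap(b, c);
      if (b < a) std::swap(a, b);
      col.push({d, a, b, c});
    }
  }

  // add the reduced column owned by edge e, except its pivot (which
  // cancels against the pivot just popped by the caller)
  void add_owner_column(int e, Column& col) {
    const std::vector<Tri>& rc = reduced_column(e);
    for (size_t i = 1; i < rc.size(); ++i) col.push(rc[i]);
  }

  // reconstruct the fully reduced column owned by edge e as a sorted
  // vector (pivot first); the owner map is already final for every
  // pivot this reduction can touch
  const std::vector<Tri>& reduced_column(int e) {
    auto hit = memo_.find(e);
    if (hit != memo_.end()) return hit->second;
    Column col;
    push_cofacets(e, col);
    Tri piv;
    std::vector<Tri> out;
    while (pop_pivot(col, piv)) {
      if (owner_.at(key(piv)) == e) {
        out.push_back(piv);
        Tri t;
        while (pop_pivot(col, t)) out.push_back(t);
        break;
      }
      add_owner_column(owner_.at(key(piv)), col);
    }
    return memo_.emplace(e, std::move(out)).first->second;
  }

  const NumericMatrix& dist_;
  const std::vector<Edge>& edges_;
  const int n_;
  const double max_diam_;
  std::unordered_map<int64_t, int> owner_; // pivot triangle -> owning edge
  std::unordered_map<int, std::vector<Tri>> memo_;
};

} // namespace

// dist: full n x n symmetric distance matrix
// max_diam: simplexes with diameter > max_diam are excluded (Inf = none)
// do_dim1: whether to run the edge-coboundary reduction
// [[Rcpp::export(name = ".rips_persistence_cpp")]]
List rips_persistence_cpp(NumericMatrix dist, double max_diam, bool do_dim1) {
  const int n = dist.nrow();

  std::vector<Edge> edges;
  edges.reserve(static_cast<size_t>(n) * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = dist(i, j);
      if (d <= max_diam) edges.push_back({d, i, j});
    }
  std::sort(edges.begin(), edges.end(), [](const Edge& a, const Edge& b) {
    if (a.diam != b.diam) return a.diam < b.diam;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  const int m = static_cast<int>(edges.size());

  // ---- dim 0: union-find over the sorted edges -------------------------
  DisjointSet ds(n);
  std::vector<double> deaths0;
  std::vector<char> in_mst(m, 0);
  for (int e = 0; e < m; ++e) {
    if (ds.unite(edges[e].i, edges[e].j)) {
      deaths0.push_back(edges[e].diam);
      in_mst[e] = 1;
    }
  }
  int n_components = n - static_cast<int>(deaths0.size());

  // ---- dim 1: reverse-order coboundary reduction with clearing ---------
  std::vector<double> births1, deaths1;
  if (do_dim1 && n >= 3) {
    Dim1Reducer red(dist, edges, max_diam);
    for (int e = m - 1; e >= 0; --e) {
      if (in_mst[e]) continue;
      red.process(e, births1, deaths1);
    }
  }

  return List::create(
    _["deaths0"] = deaths0,
    _["n_components"] = n_components,
    _["births1"] = births1,
    _["deaths1"] = deaths1);
}
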