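// Vietoris-Rips persistent homology over Z/2 from a dense distance matrix.
//
// Persistent cohomology with implicit coboundaries, following the standard
// scheme for VR filtrations: dimension 0 by union-find over sorted edges,
// higher dimensions by left-to-right reduction of the coboundary matrix in
// reverse filtration order, with the clearing optimisation and the
// emergent-pair shortcut.  Simplices are addressed in the combinatorial
// number system; k-simplex with vertices v_0 > v_1 > ... > v_k has index
// sum_i C(v_i, k+1-i).  Within a dimension the filtration order is
// (diameter ascending, index descending), so the reduction processes columns
// by (diameter descending, index ascending) and the pivot of a column is its
// cofacet with (smallest diameter, largest index).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <limits>
#include <queue>
#include <unordered_map>
#include <vector>

typedef int64_t index_t;
typedef double value_t;

static const value_t INF = std::numeric_limits<value_t>::infinity();

struct binomial_table {
  std::vector<std::vector<index_t>> B;
  binomial_table(index_t n, index_t k) : B(n + 1, std::vector<index_t>(k + 1, 0)) {
    for (index_t i = 0; i <= n; ++i) {
      B[i][0] = 1;
      for (index_t j = 1; j <= std::min(i, k); ++j)
        B[i][j] = B[i - 1][j - 1] + B[i - 1][j];
    }
  }
  index_t operator()(index_t n, index_t k) const {
    if (k < 0 || n < 0 || k > n) return 0;
    return B[n][k];
  }
};

struct diameter_index_t {
  value_t diameter;
  index_t index;
};

// Filtration-later comparator: larger diameter, ties broken by smaller index.
struct greater_diameter_or_smaller_index {
  bool operator()(const diameter_index_t& a, const diameter_index_t& b) const {
    return (a.diameter > b.diameter) ||
           ((a.diameter == b.diameter) && (a.index < b.index));
  }
};

class rips_complex {
public:
  index_t n;
  const Rcpp::NumericMatrix& D;
  binomial_table binom;
  value_t threshold;

  rips_complex(const Rcpp::NumericMatrix& dist, value_t thresh, index_t max_dim)
      : n(dist.nrow()), D(dist), binom(dist.nrow() + 1, max_dim + 3), threshold(thresh) {}

  value_t dist(index_t i, index_t j) const { return D(i, j); }

  // Largest v with C(v, k) <= idx, searching downward from upper bound.
  index_t get_max_vertex(index_t idx, index_t k, index_t upper) const {
    index_t top = upper, bottom = k - 1;
    if (binom(top, k) > idx) {
      // binary search in (bottom, top]
      while (top - bottom > 1) {
        index_t mid = (top + bottom) / 2;
        if (binom(mid, k) > idx) top = mid; else bottom = mid;
      }
      top = bottom;
    }
    return top;
  }

  // Decode simplex index into vertices (descending order).
  void get_simplex_vertices(index_t idx, index_t dim, std::vector<index_t>& vertices) const {
    vertices.resize(dim + 1);
    index_t v = n - 1;
    for (index_t k = dim + 1; k > 0; --k) {
      v = get_max_vertex(idx, k, v);
      vertices[dim + 1 - k] = v;
      idx -= binom(v, k);
    }
  }

  value_t simplex_diameter(const std::vector<index_t>& vertices) const {
    value_t diam = 0;
    for (size_t i = 0; i < vertices.size(); ++i)
      for (size_t j = i + 1; j < vertices.size(); ++j)
        diam = std::max(diam, dist(vertices[i], vertices[j]));
    return diam;
  }
};

// Enumerates cofacets of a simplex in decreasing cofacet-index order
// (new vertex v runs from n-1 downward, skipping simplex vertices).
class coboundary_enumerator {
  const rips_complex& C;
  index_t idx_below, idx_above, v, k;
  std::vector<index_t> vertices;  // of the simplex, descending
  value_t simplex_diam;

public:
  coboundary_enumerator(const rips_complex& complex, index_t simplex_index,
                        index_t dim, value_t diam)
      : C(complex), idx_below(simplex_index), idx_above(0), v(complex.n - 1),
        k(dim + 1), simplex_diam(diam) {
    C.get_simplex_vertices(simplex_index, dim, vertices);
  }

  bool has_next() {
    while (v != -1 && C.binom(v, k) <= idx_below) {
      idx_below -= C.binom(v, k);
      idx_above += C.binom(v, k + 1);
      --v;
      --k;
    }
    return v != -1;
  }

  diameter_index_t next() {
    value_t diam = simplex_diam;
    for (size_t i = 0; i < vertices.size(); ++i)
      diam = std::max(diam, C.dist(v, vertices[i]));
    diameter_index_t cofacet = {diam, idx_above + C.binom(v, k + 1) + idx_below};
    --v;
    return cofacet;
  }
};

typedef std::priority_queue<diameter_index_t, std::vector<diameter_index_t>,
                            greater_diameter_or_smaller_index>
    coboundary_heap;  // top = filtration-earliest cofacet (the pivot)

// Pop the current pivot of a Z/2 column heap; entries appearing an even
// number of times cancel.  Returns false if the column is zero.
static bool pop_pivot(coboundary_heap& column, diameter_index_t& pivot) {
  while (!column.empty()) {
    pivot = column.top();
    column.pop();
    if (column.empty() || column.top().index != pivot.index) return true;
    column.pop();  // cancel the pair mod 2
  }
  return false;
}

struct union_find {
  std::vector<index_t> parent;
  union_find(index_t n) : parent(n) {
    for (index_t i = 0; i < n; ++i) parent[i] = i;
  }
  index_t find(index_t x) {
    index_t r = x;
    while (parent[r] != r) r = parent[r];
    while (parent[x] != r) {
      index_t next = parent[x];
      parent[x] = r;
      x = next;
    }
    return r;
  }
  void link(index_t x, index_t y) { parent[find(x)] = find(y); }
};

struct bar {
  int dim;
  value_t birth, death;
};

// [[Rcpp::export(name = ".rips_persistence_cpp")]]
Rcpp::DataFrame rips_persistence_cpp(Rcpp::NumericMatrix dist, int max_dim,
                                     double threshold) {
  const index_t n = dist.nrow();
  rips_complex C(dist, threshold, max_dim);
  std::vector<bar> bars;

  // ---- dimension 0: union-find over edges sorted by filtration order ----
  std::vector<diameter_index_t> edges;
  edges.reserve((size_t)(n * (n - 1) / 2));
  for (index_t i = 0; i < n; ++i)
    for (index_t j = 0; j < i; ++j) {
      value_t d = C.dist(i, j);
      if (d <= threshold)
        edges.push_back({d, C.binom(i, 2) + C.binom(j, 1)});
    }
  {
    // ascending filtration order for the union-find pass
    std::sort(edges.begin(), edges.end(),
              [](const diameter_index_t& a, const diameter_index_t& b) {
                return (a.diameter < b.diameter) ||
                       ((a.diameter == b.diameter) && (a.index > b.index));
              });
  }
  union_find dset(n);
  std::vector<diameter_index_t> columns_to_reduce;  // cycle-creating edges
  std::vector<index_t> vertices_of_edge;
  for (const auto& e : edges) {
    C.get_simplex_vertices(e.index, 1, vertices_of_edge);
    index_t u = dset.find(vertices_of_edge[0]), v = dset.find(vertices_of_edge[1]);
    if (u != v) {
      if (e.diameter > 0) bars.push_back({0, 0.0, e.diameter});
      dset.link(u, v);
    } else {
      columns_to_reduce.push_back(e);
    }
  }
  for (index_t i = 0; i < n; ++i)
    if (dset.find(i) == i) bars.push_back({0, 0.0, INF});

  // columns for dim-1 reduction: reverse filtration order
  std::reverse(columns_to_reduce.begin(), columns_to_reduce.end());

  // ---- dimensions >= 1: persistent cohomology reduction ----
  for (int dim = 1; dim <= max_dim; ++dim) {
    std::unordered_map<index_t, index_t> pivot_column_index;
    pivot_column_index.reserve(columns_to_reduce.size());
    std::vector<std::vector<index_t>> reduction_matrix(columns_to_reduce.size());

    std::vector<diameter_index_t> cofacet_entries;
    for (index_t i = 0; i < (index_t)columns_to_reduce.size(); ++i) {
      const diameter_index_t column = columns_to_reduce[i];
      coboundary_heap working_coboundary;
      // V-column entries (positions into columns_to_reduce), implicit +i
      std::priority_queue<index_t> working_reduction;

      diameter_index_t pivot;
      bool have_pivot = false;

      // initial coboundary with emergent-pair shortcut
      {
        cofacet_entries.clear();
        bool check_emergent = true;
        coboundary_enumerator cofacets(C, column.index, dim, column.diameter);
        while (cofacets.has_next()) {
          diameter_index_t cofacet = cofacets.next();
          if (cofacet.diameter > threshold) continue;
          cofacet_entries.push_back(cofacet);
          if (check_emergent && cofacet.diameter == column.diameter) {
            if (pivot_column_index.find(cofacet.index) == pivot_column_index.end()) {
              pivot = cofacet;
              have_pivot = true;
              break;
            }
            check_emergent = false;
          }
        }
        if (!have_pivot) {
          for (const auto& cf : cofacet_entries) working_coboundary.push(cf);
          have_pivot = pop_pivot(working_coboundary, pivot);
          if (have_pivot) working_coboundary.push(pivot);
        }
      }

      while (true) {
        if (!have_pivot) {
          // zero column: essential class
          bars.push_back({dim, column.diameter, INF});
          break;
        }
        auto it = pivot_column_index.find(pivot.index);
        if (it == pivot_column_index.end()) {
          pivot_column_index[pivot.index] = i;
          if (pivot.diameter > column.diameter)
            bars.push_back({dim, column.diameter, pivot.diameter});
          // store the reduced V-column (mod-2 collapse of the heap)
          std::vector<index_t>& stored = reduction_matrix[i];
          while (!working_reduction.empty()) {
            index_t p = working_reduction.top();
            working_reduction.pop();
            if (!working_reduction.empty() && working_reduction.top() == p) {
              working_reduction.pop();
              continue;
            }
            stored.push_back(p);
          }
          break;
        }
        // add column j (its V-column coboundaries) to the working column
        index_t j = it->second;
        working_reduction.push(j);
        {
          coboundary_enumerator cofacets(C, columns_to_reduce[j].index, dim,
                                         columns_to_reduce[j].diameter);
          while (cofacets.has_next()) {
            diameter_index_t cf = cofacets.next();
            if (cf.diameter <= threshold) working_coboundary.push(cf);
          }
        }
        for (index_t p : reduction_matrix[j]) {
          working_reduction.push(p);
          coboundary_enumerator cofacets(C, columns_to_reduce[p].index, dim,
                                         columns_to_reduce[p].diameter);
          while (cofacets.has_next()) {
            diameter_index_t cf = cofacets.next();
            if (cf.diameter <= threshold) working_coboundary.push(cf);
          }
        }
        have_pivot = pop_pivot(working_coboundary, pivot);
        if (have_pivot) working_coboundary.push(pivot);
      }
      Rcpp::checkUserInterrupt();
    }

    // assemble columns for the next dimension (with clearing)
    if (dim < max_dim) {
      std::vector<diameter_index_t> next_columns;
      if (dim + 1 == 2) {
        for (index_t c = 2; c < n; ++c)
          for (index_t b = 1; b < c; ++b) {
            value_t dcb = C.dist(c, b);
            if (dcb > threshold) continue;
            for (index_t a = 0; a < b; ++a) {
              value_t diam = std::max(dcb, std::max(C.dist(c, a), C.dist(b, a)));
              if (diam > threshold) continue;
              index_t idx = C.binom(c, 3) + C.binom(b, 2) + C.binom(a, 1);
              if (pivot_column_index.find(idx) == pivot_column_index.end())
                next_columns.push_back({diam, idx});
            }
          }
      } else {  // dim + 1 == 3
        for (index_t d4 = 3; d4 < n; ++d4)
          for (index_t c = 2; c < d4; ++c) {
            if (C.dist(d4, c) > threshold) continue;
            for (index_t b = 1; b < c; ++b) {
              value_t diam3 = std::max(C.dist(d4, c),
                                       std::max(C.dist(d4, b), C.dist(c, b)));
              if (diam3 > threshold) continue;
              for (index_t a = 0; a < b; ++a) {
                value_t diam = std::max(
                    diam3, std::max(C.dist(d4, a),
                                    std::max(C.dist(c, a), C.dist(b, a))));
                if (diam > threshold) continue;
                index_t idx = C.binom(d4, 4) + C.binom(c, 3) + C.binom(b, 2) +
                              C.binom(a, 1);
                if (pivot_column_index.find(idx) == pivot_column_index.end())
                  next_columns.push_back({diam, idx});
              }
            }
          }
      }
      std::sort(next_columns.begin(), next_columns.end(),
                greater_diameter_or_smaller_index());
      columns_to_reduce.swap(next_columns);
    }
  }

  const index_t m = bars.size();
  Rcpp::IntegerVector out_dim(m);
  Rcpp::NumericVector out_birth(m), out_death(m);
  for (index_t i = 0; i < m; ++i) {
    out_dim[i] = bars[i].dim;
    out_birth[i] = bars[i].birth;
    out_death[i] = bars[i].death == INF ? R_PosInf : bars[i].death;
  }
  return Rcpp::DataFrame::create(Rcpp::Named("dimension") = out_dim,
                                 Rcpp::Named("birth") = out_birth,
                                 Rcpp::Named("death") = out_death);
}
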