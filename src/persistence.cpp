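#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Vietoris-Rips complex enumeration (dimension <= 2)
// ---------------------------------------------------------------------------

// Enumerate edges (pairs within max_radius) and triangles (triples pairwise
// within max_radius). Entry value convention is the diameter: an edge enters
// at the distance between its endpoints, a triangle at its longest edge.
// Returns 1-based vertex indices for use from R, and for each triangle the
// 1-based indices of its three edges in the returned edge list.
// [[Rcpp::export]]
List cpp_rips_complex(NumericVector x, NumericVector y, double max_radius) {
  const int n = x.size();
  std::vector<int> ei, ej;
  std::vector<double> ed;
  // adjacency with edge ids for triangle enumeration
  std::vector<std::vector<std::pair<int, int>>> nbr(n); // (j, edge id), j > i
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j], dy = y[i] - y[j];
      const double d = std::sqrt(dx * dx + dy * dy);
      if (d <= max_radius) {
        const int id = (int)ei.size();
        ei.push_back(i);
        ej.push_back(j);
        ed.push_back(d);
        nbr[i].push_back(std::make_pair(j, id));
      }
    }
  }
  std::vector<int> ta, tb, tc, te1, te2, te3;
  std::vector<double> td;
  for (int i = 0; i < n; ++i) {
    const std::vector<std::pair<int, int>>& ni = nbr[i];
    for (size_t a = 0; a < ni.size(); ++a) {
      const int j = ni[a].first;
      size_t pb = 0;
      for (size_t b = a + 1; b < ni.size(); ++b) {
        const int k = ni[b].first;
        while (pb < nbr[j].size() && nbr[j][pb].first < k) ++pb;
        if (pb < nbr[j].size() && nbr[j][pb].first == k) {
          const int e_jk = nbr[j][pb].second;
          ta.push_back(i);
          tb.push_back(j);
          tc.push_back(k);
          te1.push_back(ni[a].second);
          te2.push_back(ni[b].second);
          te3.push_back(e_jk);
          td.push_back(std::max(ed[ni[a].second],
                                std::max(ed[ni[b].second], ed[e_jk])));
        }
      }
    }
  }
  const int m = (int)ei.size(), t = (int)ta.size();
  IntegerMatrix edges(m, 2), tris(t, 3), tre(t, 3);
  NumericVector edge_d(m), tri_d(t);
  for (int e = 0; e < m; ++e) {
    edges(e, 0) = ei[e] + 1;
    edges(e, 1) = ej[e] + 1;
    edge_d[e] = ed[e];
  }
  for (int s = 0; s < t; ++s) {
    tris(s, 0) = ta[s] + 1;
    tris(s, 1) = tb[s] + 1;
    tris(s, 2) = tc[s] + 1;
    tre(s, 0) = te1[s] + 1;
    tre(s, 1) = te2[s] + 1;
    tre(s, 2) = te3[s] + 1;
    tri_d[s] = td[s];
  }
  return List::create(_["edges"] = edges, _["edge_values"] = edge_d,
                      _["triangles"] = tris, _["triangle_edges"] = tre,
                      _["triangle_values"] = tri_d);
}

// ---------------------------------------------------------------------------
// Z2 persistence: shared machinery
// ---------------------------------------------------------------------------

namespace {

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int v) {
    int r = v;
    while (parent[r] != r) r = parent[r];
    while (parent[v] != r) {
      int nxt = parent[v];
      parent[v] = r;
      v = nxt;
    }
    return r;
  }
};

// immutable per-complex structure shared by all slices of a bifiltration
struct ComplexTopology {
  int n_vertices = 0;
  std::vector<int> e_i, e_j;        // edge endpoints (0-based)
  std::vector<int> t_e1, t_e2, t_e3; // triangle -> edge ids (0-based)
  std::vector<std::int64_t> ekey;   // lexicographic edge tie-break key
  std::vector<std::int64_t> tkey;   // lexicographic triangle tie-break key
  // CSR adjacency: edge -> cofacet triangles
  std::vector<int> cof_ptr, cof;

  void finalize() {
    const int m = (int)e_i.size(), t = (int)t_e1.size();
    const std::int64_t N = std::max(1, n_vertices);
    ekey.resize(m);
    for (int e = 0; e < m; ++e) ekey[e] = (std::int64_t)e_i[e] * N + e_j[e];
    tkey.resize(t);
    const std::int64_t M = std::max(1, m);
    for (int s = 0; s < t; ++s) {
      // unique deterministic key: the sorted triple of edge ids
      std::int64_t k1 = t_e1[s], k2 = t_e2[s], k3 = t_e3[s];
      std::int64_t lo = std::min(k1, std::min(k2, k3));
      std::int64_t hi = std::max(k1, std::max(k2, k3));
      std::int64_t mid = k1 + k2 + k3 - lo - hi;
      tkey[s] = (hi * M + mid) * M + lo;
    }
    cof_ptr.assign(m + 1, 0);
    for (int s = 0; s < t; ++s) {
      ++cof_ptr[t_e1[s] + 1];
      ++cof_ptr[t_e2[s] + 1];
      ++cof_ptr[t_e3[s] + 1];
    }
    for (int e = 0; e < m; ++e) cof_ptr[e + 1] += cof_ptr[e];
    cof.resize(cof_ptr[m]);
    std::vector<int> fill(cof_ptr.begin(), cof_ptr.end() - 1);
    for (int s = 0; s < t; ++s) {
      cof[fill[t_e1[s]]++] = s;
      cof[fill[t_e2[s]]++] = s;
      cof[fill[t_e3[s]]++] = s;
    }
  }
};

ComplexTopology make_topology(int n_vertices, const IntegerMatrix& edges,
                              const IntegerMatrix& tri_edges) {
  ComplexTopology topo;
  topo.n_vertices = n_vertices;
  const int m = edges.nrow(), t = tri_edges.nrow();
  topo.e_i.resize(m);
  topo.e_j.resize(m);
  for (int e = 0; e < m; ++e) {
    topo.e_i[e] = edges(e, 0) - 1;
    topo.e_j[e] = edges(e, 1) - 1;
  }
  topo.t_e1.resize(t);
  topo.t_e2.resize(t);
  topo.t_e3.resize(t);
  for (int s = 0; s < t; ++s) {
    topo.t_e1[s] = tri_edges(s, 0) - 1;
    topo.t_e2[s] = tri_edges(s, 1) - 1;
    topo.t_e3[s] = tri_edges(s, 2) - 1;
  }
  topo.finalize();
  return topo;
}

// ascending filtration order of simplices given entries and tie-break keys
std::vector<int> order_asc(const std::vector<double>& entry,
                           const std::vector<std::int64_t>& key) {
  std::vector<int> ord(entry.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (entry[a] != entry[b]) return entry[a] < entry[b];
    return key[a] < key[b];
  });
  return ord;
}

// symmetric difference of two ascending int vectors, result into out
void sym_diff(const std::vector<int>& a, const std::vector<int>& b,
              std::vector<int>& out) {
  out.clear();
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j])
      out.push_back(a[i++]);
    else if (b[j] < a[i])
      out.push_back(b[j++]);
    else {
      ++i;
      ++j;
    }
  }
  while (i < a.size()) out.push_back(a[i++]);
  while (j < b.size()) out.push_back(b[j++]);
}

struct Bars {
  std::vector<double> birth, death;
};

// union-find pass over edges in ascending filtration order: marks positive
// (cycle-creating) edges; with want_h0, emits H0 bars by the elder rule.
void h0_scan(const ComplexTopology& topo, const std::vector<double>& v_entry,
             const std::vector<double>& e_entry,
             const std::vector<int>& eord_asc, std::vector<char>& positive,
             bool want_h0, Bars* h0) {
  const int m = (int)e_entry.size();
  positive.assign(m, 0);
  UnionFind uf(topo.n_vertices);
  std::vector<double> comp_birth(v_entry);
  std::vector<int> comp_vert(topo.n_vertices);
  for (int v = 0; v < topo.n_vertices; ++v) comp_vert[v] = v;
  for (int r = 0; r < m; ++r) {
    const int e = eord_asc[r];
    int ra = uf.find(topo.e_i[e]), rb = uf.find(topo.e_j[e]);
    if (ra == rb) {
      positive[e] = 1;
      continue;
    }
    bool a_elder =
        (comp_birth[ra] < comp_birth[rb]) ||
        (comp_birth[ra] == comp_birth[rb] && comp_vert[ra] < comp_vert[rb]);
    int elder = a_elder ? ra : rb, young = a_elder ? rb : ra;
    if (want_h0 && e_entry[e] > comp_birth[young]) {
      h0->birth.push_back(comp_birth[young]);
      h0->death.push_back(e_entry[e]);
    }
    uf.parent[young] = elder;
  }
  if (want_h0) {
    for (int v = 0; v < topo.n_vertices; ++v)
      if (uf.find(v) == v) {
        h0->birth.push_back(comp_birth[v]);
        h0->death.push_back(R_PosInf);
      }
  }
}

// Reusable workspace for the coboundary reduction, so the per-slice loop of
// the landscape computation does not reallocate.
struct CohomologyWorkspace {
  std::vector<int> tord_desc, rrank;
  std::vector<int> owner_edge; // by reversed triangle rank; -1 if unclaimed
  std::vector<int> owner_col;  // stored column id, or -1 if column is raw
  std::vector<std::vector<int>> stored;
  std::vector<int> heap, drain;
};

// H1 pairs by reduction of the edge coboundary matrix, processed in reverse
// filtration order (persistent cohomology). Columns are edges, rows their
// cofacet triangles, so the number of columns scales with the edges rather
// than the triangles -- this is what makes dense Rips slices tractable.
// The working column is a lazy max-heap with parity cancellation; a column
// that claims its pivot without any additions is left implicit (it equals
// the raw cofacet list, rebuilt from the CSR adjacency when needed), which
// covers the zero-persistence "apparent" pairs dominating Rips filtrations.
// Produces the same (edge, triangle) pairs as the homology reduction.
void h1_pairs_cohomology(const ComplexTopology& topo,
                         const std::vector<double>& e_entry,
                         const std::vector<double>& t_entry,
                         const std::vector<int>& eord_asc,
                         const std::vector<char>& positive,
                         CohomologyWorkspace& ws, Bars* h1,
                         bool tord_ready = false) {
  const int m = (int)e_entry.size();
  const int t = (int)t_entry.size();
  // triangles in descending filtration order; reversed row index = position
  if (!tord_ready) {
    ws.tord_desc.resize(t);
    for (int s = 0; s < t; ++s) ws.tord_desc[s] = s;
    std::sort(ws.tord_desc.begin(), ws.tord_desc.end(), [&](int a, int b) {
      if (t_entry[a] != t_entry[b]) return t_entry[a] > t_entry[b];
      return topo.tkey[a] > topo.tkey[b];
    });
  }
  ws.rrank.assign(t, 0);
  for (int r = 0; r < t; ++r) ws.rrank[ws.tord_desc[r]] = r;
  ws.owner_edge.assign(t, -1);
  ws.owner_col.assign(t, -1);
  ws.stored.clear();
  std::vector<int>& heap = ws.heap;

  // pop the current pivot (maximal reversed rank with odd multiplicity)
  auto pop_pivot = [&heap]() -> int {
    while (!heap.empty()) {
      std::pop_heap(heap.begin(), heap.end());
      const int v = heap.back();
      heap.pop_back();
      int count = 1;
      while (!heap.empty() && heap.front() == v) {
        std::pop_heap(heap.begin(), heap.end());
        heap.pop_back();
        ++count;
      }
      if (count % 2) return v;
    }
    return -1;
  };
  auto push_entry = [&heap](int v) {
    heap.push_back(v);
    std::push_heap(heap.begin(), heap.end());
  };

  std::vector<char> edge_paired(m, 0);
  // edges in descending filtration order = reversed ascending order.
  // Clearing: negative (component-merging) edges are pivots of the
  // dimension-0 coboundary reduction, so their columns here provably
  // reduce to zero and are skipped.
  for (int r = m - 1; r >= 0; --r) {
    const int e = eord_asc[r];
    if (!positive[e]) continue;
    heap.clear();
    for (int c = topo.cof_ptr[e]; c < topo.cof_ptr[e + 1]; ++c)
      push_entry(ws.rrank[topo.cof[c]]);
    bool raw = true;
    for (;;) {
      const int p = pop_pivot();
      if (p < 0) break; // zero column: negative or essential edge
      const int owner = ws.owner_edge[p];
      if (owner < 0) {
        ws.owner_edge[p] = e;
        if (!raw) {
          // canonicalize the remaining heap into a stored sorted column
          ws.drain.clear();
          int v;
          auto drain_pivot = pop_pivot;
          while ((v = drain_pivot()) >= 0) ws.drain.push_back(v);
          std::reverse(ws.drain.begin(), ws.drain.end());
          ws.drain.push_back(p);
          ws.owner_col[p] = (int)ws.stored.size();
          ws.stored.push_back(ws.drain);
        }
        const int s = ws.tord_desc[p];
        edge_paired[e] = 1;
        if (t_entry[s] > e_entry[e]) {
          h1->birth.push_back(e_entry[e]);
          h1->death.push_back(t_entry[s]);
        }
        break;
      }
      // add the owner's column (its copy of p cancels the popped pivot)
      raw = false;
      if (ws.owner_col[p] < 0) {
        for (int c = topo.cof_ptr[owner]; c < topo.cof_ptr[owner + 1]; ++c) {
          const int q = ws.rrank[topo.cof[c]];
          if (q != p) push_entry(q);
        }
      } else {
        const std::vector<int>& sc = ws.stored[ws.owner_col[p]];
        for (size_t ci = 0; ci < sc.size(); ++ci)
          if (sc[ci] != p) push_entry(sc[ci]);
      }
    }
  }
  for (int e = 0; e < m; ++e)
    if (positive[e] && !edge_paired[e]) {
      h1->birth.push_back(e_entry[e]);
      h1->death.push_back(R_PosInf);
    }
}

// Naive H1 reduction of the triangle boundary matrix in ascending
// filtration order (the textbook algorithm); retained as the reference
// implementation that the cohomology path is checked against.
void h1_pairs_homology(const ComplexTopology& topo,
                       const std::vector<double>& e_entry,
                       const std::vector<double>& t_entry,
                       const std::vector<int>& eord_asc,
                       const std::vector<char>& positive, Bars* h1) {
  const int m = (int)e_entry.size();
  const int t = (int)t_entry.size();
  std::vector<int> erank(m);
  for (int r = 0; r < m; ++r) erank[eord_asc[r]] = r;
  std::vector<int> tord(t);
  for (int s = 0; s < t; ++s) tord[s] = s;
  std::sort(tord.begin(), tord.end(), [&](int a, int b) {
    if (t_entry[a] != t_entry[b]) return t_entry[a] < t_entry[b];
    return topo.tkey[a] < topo.tkey[b];
  });
  std::vector<int> pivot_owner(m, -1);
  std::vector<std::vector<int>> stored;
  std::vector<char> edge_paired(m, 0);
  std::vector<int> col, tmp;
  for (int si = 0; si < t; ++si) {
    const int s = tord[si];
    col.clear();
    col.push_back(erank[topo.t_e1[s]]);
    col.push_back(erank[topo.t_e2[s]]);
    col.push_back(erank[topo.t_e3[s]]);
    std::sort(col.begin(), col.end());
    while (!col.empty()) {
      const int low = col.back();
      const int owner = pivot_owner[low];
      if (owner < 0) {
        pivot_owner[low] = (int)stored.size();
        stored.push_back(col);
        const int e = eord_asc[low];
        edge_paired[e] = 1;
        if (t_entry[s] > e_entry[e]) {
          h1->birth.push_back(e_entry[e]);
          h1->death.push_back(t_entry[s]);
        }
        break;
      }
      sym_diff(col, stored[owner], tmp);
      col.swap(tmp);
    }
  }
  for (int e = 0; e < m; ++e)
    if (positive[e] && !edge_paired[e]) {
      h1->birth.push_back(e_entry[e]);
      h1->death.push_back(R_PosInf);
    }
}

} // namespace

// [[Rcpp::export]]
List cpp_barcode(int n_vertices, NumericVector v_entry, IntegerMatrix edges,
                 NumericVector e_entry, IntegerMatrix tri_edges,
                 NumericVector t_entry, bool want_h0, bool want_h1,
                 bool naive = false) {
  ComplexTopology topo = make_topology(n_vertices, edges, tri_edges);
  std::vector<double> ve(v_entry.begin(), v_entry.end());
  std::vector<double> ee(e_entry.begin(), e_entry.end());
  std::vector<double> te(t_entry.begin(), t_entry.end());
  std::vector<int> eord = order_asc(ee, topo.ekey);
  std::vector<char> positive;
  Bars h0, h1;
  h0_scan(topo, ve, ee, eord, positive, want_h0, &h0);
  if (want_h1) {
    if (naive) {
      h1_pairs_homology(topo, ee, te, eord, positive, &h1);
    } else {
      CohomologyWorkspace ws;
      h1_pairs_cohomology(topo, ee, te, eord, positive, ws, &h1);
    }
  }
  return List::create(
      _["h0_birth"] = wrap(h0.birth), _["h0_death"] = wrap(h0.death),
      _["h1_birth"] = wrap(h1.birth), _["h1_death"] = wrap(h1.death));
}

// ---------------------------------------------------------------------------
// MPH landscape by diagonal slicing of a one-critical bifiltration
// ---------------------------------------------------------------------------

// Grades are normalized to [0,1] on both axes. The grid is the square
// g x g lattice over [0,1]^2; slices are the lines y = x + offset through
// grid anti-diagonals, so every grid point lies on exactly one slice and no
// interpolation is needed. On the slice parametrized by u (the x coordinate)
// a simplex with grade (a, b) enters at u = max(a, b - offset). The H1
// barcode of the sliced filtration gives the landscape along the slice:
// lambda(k, u) = k-th largest of max(0, min(u - birth, death - u)).
// [[Rcpp::export]]
NumericVector cpp_mph_landscape(int n_vertices, NumericVector va,
                                IntegerMatrix edges, NumericVector ea,
                                NumericVector eb, IntegerMatrix tri_edges,
                                NumericVector ta, NumericVector tb, int g,
                                int k_max) {
  if (g < 2) stop("grid size must be at least 2");
  ComplexTopology topo = make_topology(n_vertices, edges, tri_edges);
  const int m = edges.nrow(), t = tri_edges.nrow();
  const double delta = 1.0 / (g - 1);
  NumericVector out(Dimension(k_max, g, g)); // zero-initialized
  std::vector<double> ve(n_vertices), ee(m), te(t);
  std::vector<char> positive;
  CohomologyWorkspace ws;
  // The slice entry of a triangle is max(ta, tb - off): it sorts by ta
  // where ta dominates and by tb where tb - off does. Precomputing the two
  // per-axis ascending orders once lets each slice build its descending
  // order by an O(t) filtered merge instead of a fresh sort.
  std::vector<double> tav(ta.begin(), ta.end()), tbv(tb.begin(), tb.end());
  std::vector<int> ordA = order_asc(tav, topo.tkey);
  std::vector<int> ordB = order_asc(tbv, topo.tkey);
  for (int d = -(g - 1); d <= g - 1; ++d) {
    const double off = d * delta;
    for (int v = 0; v < n_vertices; ++v) ve[v] = std::max(va[v], -off);
    for (int e = 0; e < m; ++e) ee[e] = std::max(ea[e], eb[e] - off);
    for (int s = 0; s < t; ++s) te[s] = std::max(ta[s], tb[s] - off);
    std::vector<int> eord = order_asc(ee, topo.ekey);
    // descending merge of the a-dominated and b-dominated triangle sets
    ws.tord_desc.resize(t);
    {
      auto a_dom = [&](int s) { return tav[s] >= tbv[s] - off; };
      auto before_desc = [&](int sa, int sb) {
        if (te[sa] != te[sb]) return te[sa] > te[sb];
        return topo.tkey[sa] > topo.tkey[sb];
      };
      int ia = t - 1, ib = t - 1, outp = 0;
      while (ia >= 0 && !a_dom(ordA[ia])) --ia;
      while (ib >= 0 && a_dom(ordB[ib])) --ib;
      while (ia >= 0 || ib >= 0) {
        int pick;
        if (ia < 0) {
          pick = ordB[ib--];
        } else if (ib < 0) {
          pick = ordA[ia--];
        } else if (before_desc(ordA[ia], ordB[ib])) {
          pick = ordA[ia--];
        } else {
          pick = ordB[ib--];
        }
        ws.tord_desc[outp++] = pick;
        while (ia >= 0 && !a_dom(ordA[ia])) --ia;
        while (ib >= 0 && a_dom(ordB[ib])) --ib;
      }
    }
    Bars h1;
    h0_scan(topo, ve, ee, eord, positive, false, nullptr);
    h1_pairs_cohomology(topo, ee, te, eord, positive, ws, &h1, true);
    const int i0 = std::max(0, -d), i1 = std::min(g - 1, g - 1 - d);
    for (size_t bar = 0; bar < h1.birth.size(); ++bar) {
      const double b = h1.birth[bar], dd = h1.death[bar];
      for (int i = i0; i <= i1; ++i) {
        const double u = i * delta;
        double val = u - b;
        if (R_finite(dd)) val = std::min(val, dd - u);
        if (val <= 0) continue;
        const int j = i + d;
        // insert into the descending top-k list at grid point (i, j)
        double* cell = &out[(std::size_t)k_max * (i + (std::size_t)g * j)];
        for (int k = 0; k < k_max; ++k) {
          if (val > cell[k]) {
            for (int q = k_max - 1; q > k; --q) cell[q] = cell[q - 1];
            cell[k] = val;
            break;
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Z2 linear algebra (rank / nullspace) for the rank-invariant oracle
// ---------------------------------------------------------------------------

namespace {

typedef std::vector<std::uint64_t> BitCol;

inline int high_bit(const BitCol& c) {
  for (int w = (int)c.size() - 1; w >= 0; --w)
    if (c[w]) return w * 64 + (63 - __builtin_clzll(c[w]));
  return -1;
}

inline void xor_into(BitCol& a, const BitCol& b) {
  for (size_t w = 0; w < a.size(); ++w) a[w] ^= b[w];
}

} // namespace

// cols: list of integer vectors of 1-based row indices. Returns the Z2 rank.
// [[Rcpp::export]]
int cpp_z2_rank(List cols, int n_rows) {
  const int words = (n_rows + 63) / 64;
  std::vector<BitCol> pivots(n_rows);
  std::vector<char> have(n_rows, 0);
  int rank = 0;
  for (int c = 0; c < cols.size(); ++c) {
    IntegerVector rows = cols[c];
    BitCol col(words, 0);
    for (int k = 0; k < rows.size(); ++k) {
      const int r = rows[k] - 1;
      col[r / 64] ^= (std::uint64_t)1 << (r % 64);
    }
    int hb;
    while ((hb = high_bit(col)) >= 0) {
      if (!have[hb]) {
        pivots[hb] = col;
        have[hb] = 1;
        ++rank;
        break;
      }
      xor_into(col, pivots[hb]);
    }
  }
  return rank;
}

// Nullspace basis of the Z2 matrix given by cols. Each basis vector is
// returned as the 1-based indices of the columns in the combination.
// [[Rcpp::export]]
List cpp_z2_nullspace(List cols, int n_rows) {
  const int nc = cols.size();
  const int words = (n_rows + 63) / 64;
  const int cwords = (nc + 63) / 64;
  std::vector<BitCol> pivots(n_rows), combos(n_rows);
  std::vector<char> have(n_rows, 0);
  List basis;
  for (int c = 0; c < nc; ++c) {
    IntegerVector rows = cols[c];
    BitCol col(words, 0), combo(cwords, 0);
    for (int k = 0; k < rows.size(); ++k) {
      const int r = rows[k] - 1;
      col[r / 64] ^= (std::uint64_t)1 << (r % 64);
    }
    combo[c / 64] ^= (std::uint64_t)1 << (c % 64);
    int hb;
    bool zero = true;
    while ((hb = high_bit(col)) >= 0) {
      if (!have[hb]) {
        pivots[hb] = col;
        combos[hb] = combo;
        have[hb] = 1;
        zero = false;
        break;
      }
      xor_into(col, pivots[hb]);
      xor_into(combo, combos[hb]);
    }
    if (zero) {
      std::vector<int> supp;
      for (int q = 0; q < nc; ++q)
        if (combo[q / 64] >> (q % 64) & 1) supp.push_back(q + 1);
      basis.push_back(wrap(supp));
    }
  }
  return basis;
}

// ---------------------------------------------------------------------------
// ABM: pairwise overdamped spring forces between cell centers
// ---------------------------------------------------------------------------

// Linear spring with rest length `rest`: repulsive below rest, adhesive
// between rest and rmax with magnitude tapering linearly to zero at rmax.
// Also counts neighbours within `ncount_radius` (for contact inhibition).
// [[Rcpp::export]]
List cpp_abm_forces(NumericVector x, NumericVector y, double k, double rest,
                    double rmax, double ncount_radius) {
  const int n = x.size();
  NumericVector fx(n), fy(n);
  IntegerVector ncount(n);
  const double nc2 = ncount_radius * ncount_radius;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j], dy = y[i] - y[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 < nc2) {
        ++ncount[i];
        ++ncount[j];
      }
      if (d2 >= rmax * rmax) continue;
      double d = std::sqrt(d2);
      double ux, uy;
      if (d < 1e-9) { // coincident centers: deterministic push-apart axis
        ux = (i + j) % 2 ? 1.0 : -1.0;
        uy = 0.0;
        d = 1e-9;
      } else {
        ux = dx / d;
        uy = dy / d;
      }
      double mag;
      if (d < rest)
        mag = -k * (d - rest); // > 0, repulsion
      else
        mag = -k * (d - rest) * (rmax - d) / (rmax - rest); // adhesion
      fx[i] += mag * ux;
      fy[i] += mag * uy;
      fx[j] -= mag * ux;
      fy[j] -= mag * uy;
    }
  }
  return List::create(_["fx"] = fx, _["fy"] = fy, _["ncount"] = ncount);
}
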