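// Core graphlet machinery: canonical bit-string lookup tables for the 29
// connected graphlets of orders 3-5, ESU-style enumeration of connected
// induced subgraphs, incremental count deltas for single edge/node edits,
// the Monte-Carlo possible-world sampling loop, and a small clique search.
//
// Bit-string convention: for a subgraph on nodes v_1..v_k (1-based local
// indices), the pair (v_i, v_j), i < j, maps to bit position
// (j-1)(j-2)/2 + (i-1), least significant bit at position zero.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>
using namespace Rcpp;

static inline int pair_pos(int i, int j) {  // 1-based, i < j
  return (j - 1) * (j - 2) / 2 + (i - 1);
}

// ---------------------------------------------------------------------------
// Catalog: lookup tables bits -> global type id (1..29), 0 = disconnected.
// Types ordered by (order, edge count asc, max degree desc, canonical asc),
// which anchors M1 = 3-path, M2 = triangle, M3 = 4-star, M8 = 4-clique,
// M9 = 5-star, M29 = 5-clique.
// ---------------------------------------------------------------------------

struct Catalog {
  std::vector<int> table[6];   // indexed by order 3..5
  std::vector<int> type_order; // per global type id (0-based vector)
  std::vector<int> type_edges;
  std::vector<int> type_canon;
  bool built = false;
};

static Catalog g_cat;

static bool bits_connected(int bits, int k) {
  // adjacency from bit-string, BFS from node 0
  int adj[5] = {0, 0, 0, 0, 0};
  for (int j = 2; j <= k; ++j)
    for (int i = 1; i < j; ++i)
      if (bits & (1 << pair_pos(i, j))) {
        adj[i - 1] |= (1 << (j - 1));
        adj[j - 1] |= (1 << (i - 1));
      }
  int seen = 1, frontier = 1;
  while (frontier) {
    int nxt = 0;
    for (int v = 0; v < k; ++v)
      if (frontier & (1 << v)) nxt |= adj[v];
    frontier = nxt & ~seen;
    seen |= nxt;
  }
  return seen == (1 << k) - 1;
}

static int remap_bits(int bits, int k, const int *perm) {
  // node local index i (1-based) becomes perm[i-1]+1
  int out = 0;
  for (int j = 2; j <= k; ++j)
    for (int i = 1; i < j; ++i)
      if (bits & (1 << pair_pos(i, j))) {
        int a = perm[i - 1] + 1, b = perm[j - 1] + 1;
        if (a > b) std::swap(a, b);
        out |= (1 << pair_pos(a, b));
      }
  return out;
}

static int max_degree_bits(int bits, int k) {
  int deg[5] = {0, 0, 0, 0, 0};
  for (int j = 2; j <= k; ++j)
    for (int i = 1; i < j; ++i)
      if (bits & (1 << pair_pos(i, j))) { deg[i - 1]++; deg[j - 1]++; }
  return *std::max_element(deg, deg + k);
}

static void build_catalog() {
  if (g_cat.built) return;
  int next_id = 1;
  for (int k = 3; k <= 5; ++k) {
    int nb = k * (k - 1) / 2;
    int nstr = 1 << nb;
    std::vector<int> canon(nstr, -1);  // canonical form per connected string
    std::map<int, std::vector<int>> classes;  // canonical -> (edges, maxdeg)
    int perm[5];
    for (int b = 0; b < nstr; ++b) {
      if (!bits_connected(b, k)) continue;
      for (int i = 0; i < k; ++i) perm[i] = i;
      int best = b;
      do {
        int r = remap_bits(b, k, perm);
        if (r < best) best = r;
      } while (std::next_permutation(perm, perm + k));
      canon[b] = best;
      if (!classes.count(best)) {
        int ec = 0;
        for (int p = 0; p < nb; ++p) if (best & (1 << p)) ec++;
        classes[best] = {ec, max_degree_bits(best, k)};
      }
    }
    // order classes: edge count asc, max degree desc, canonical asc
    std::vector<int> keys;
    for (auto &kv : classes) keys.push_back(kv.first);
    std::sort(keys.begin(), keys.end(), [&](int a, int b2) {
      const std::vector<int> &ca = classes[a], &cb = classes[b2];
      if (ca[0] != cb[0]) return ca[0] < cb[0];
      if (ca[1] != cb[1]) return ca[1] > cb[1];
      return a < b2;
    });
    std::map<int, int> id_of;
    for (int key : keys) {
      id_of[key] = next_id++;
      g_cat.type_order.push_back(k);
      g_cat.type_edges.push_back(classes[key][0]);
      g_cat.type_canon.push_back(key);
    }
    g_cat.table[k].assign(nstr, 0);
    for (int b = 0; b < nstr; ++b)
      if (canon[b] >= 0) g_cat.table[k][b] = id_of[canon[b]];
  }
  g_cat.built = true;
}

// [[Rcpp::export]]
DataFrame cpp_catalog() {
  build_catalog();
  int n = g_cat.type_order.size();
  IntegerVector ord(n), ec(n), canon(n);
  CharacterVector id(n);
  for (int i = 0; i < n; ++i) {
    id[i] = "M" + std::to_string(i + 1);
    ord[i] = g_cat.type_order[i];
    ec[i] = g_cat.type_edges[i];
    canon[i] = g_cat.type_canon[i];
  }
  return DataFrame::create(_["id"] = id, _["order"] = ord,
                           _["edges"] = ec, _["canonical_bits"] = canon);
}

// [[Rcpp::export]]
IntegerVector cpp_lookup_table(int order) {
  build_catalog();
  if (order < 3 || order > 5) stop("order must be 3, 4 or 5");
  return wrap(g_cat.table[order]);
}

// [[Rcpp::export]]
int cpp_classify_bits(int order, int bits) {
  build_catalog();
  if (order < 3 || order > 5) stop("order must be 3, 4 or 5");
  int nstr = 1 << (order * (order - 1) / 2);
  if (bits < 0 || bits >= nstr) stop("bit-string out of range for this order");
  return g_cat.table[order][bits];
}

// ---------------------------------------------------------------------------
// Adjacency helpers
// ---------------------------------------------------------------------------

typedef std::vector<std::vector<int>> AdjList;

static AdjList adj_from_list(List adj) {
  int n = adj.size();
  AdjList a(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj[i];
    a[i].reserve(nb.size());
    for (int j = 0; j < nb.size(); ++j) a[i].push_back(nb[j] - 1);
    std::sort(a[i].begin(), a[i].end());
  }
  return a;
}

static inline bool has_edge(const AdjList &a, int u, int v) {
  const std::vector<int> &nb = a[u].size() <= a[v].size() ? a[u] : a[v];
  int w = a[u].size() <= a[v].size() ? v : u;
  return std::binary_search(nb.begin(), nb.end(), w);
}

// ---------------------------------------------------------------------------
// ESU enumeration. `Enum` enumerates every connected node set of size <= K
// exactly once, either over the whole graph (min-label root scheme) or as
// supersets of a fixed anchor set. Each emitted set is classified through
// the lookup tables; a callback hook accumulates counts or deltas.
// ---------------------------------------------------------------------------

struct Enum {
  const AdjList *adj;
  int K;
  int root;                 // -1 for anchored mode (no label filter)
  std::vector<char> mark;   // node in S or in N(S)
  std::vector<int> S;
  long long work = 0;

  virtual void emit(const std::vector<int> &S) = 0;
  virtual ~Enum() {}

  int subgraph_bits(const std::vector<int> &S) const {
    int bits = 0, k = S.size();
    for (int j = 2; j <= k; ++j)
      for (int i = 1; i < j; ++i)
        if (has_edge(*adj, S[i - 1], S[j - 1])) bits |= (1 << pair_pos(i, j));
    return bits;
  }

  void extend(std::vector<int> ext) {
    if ((int)S.size() >= 3) { work++; emit(S); }
    if ((int)S.size() == K) return;
    while (!ext.empty()) {
      int w = ext.back();
      ext.pop_back();
      std::vector<int> ext2 = ext;
      std::vector<int> newly;
      for (int u : (*adj)[w]) {
        if (root >= 0 && u <= root) continue;
        if (!mark[u]) { mark[u] = 1; newly.push_back(u); ext2.push_back(u); }
      }
      S.push_back(w);
      extend(ext2);
      S.pop_back();
      for (int u : newly) mark[u] = 0;
    }
  }

  void run_full() {  // all connected sets of size 3..K
    int n = adj->size();
    mark.assign(n, 0);
    for (int v = 0; v < n; ++v) {
      root = v;
      S.assign(1, v);
      std::vector<int> ext;
      mark[v] = 1;
      for (int u : (*adj)[v])
        if (u > v) { mark[u] = 1; ext.push_back(u); }
      extend(ext);
      mark[v] = 0;
      for (int u : (*adj)[v]) if (u > v) mark[u] = 0;
    }
  }

  void run_anchored(const std::vector<int> &anchors) {
    int n = adj->size();
    root = -1;
    mark.assign(n, 0);
    S = anchors;
    std::vector<int> ext;
    for (int v : anchors) mark[v] = 1;
    for (int v : anchors)
      for (int u : (*adj)[v])
        if (!mark[u]) { mark[u] = 1; ext.push_back(u); }
    extend(ext);
  }
};

struct CountEnum : Enum {
  std::vector<double> counts;
  CountEnum() : counts(29, 0.0) {}
  void emit(const std::vector<int> &Sv) override {
    int t = g_cat.table[Sv.size()][subgraph_bits(Sv)];
    if (t) counts[t - 1] += 1.0;
  }
};

// [[Rcpp::export]]
NumericVector cpp_count_all(List adj, int ng) {
  build_catalog();
  AdjList a = adj_from_list(adj);
  CountEnum e;
  e.adj = &a;
  e.K = ng;
  e.run_full();
  NumericVector out = wrap(e.counts);
  out.attr("work") = (double)e.work;
  return out;
}

// Delta for adding edge (u,v): adjacency must ALREADY contain the edge.
// Returns counts(with edge) - counts(without edge); caller negates for
// removal. Anchors are placed first in S, so the (u,v) bit is position 0.
struct EdgeDeltaEnum : Enum {
  std::vector<double> delta;
  EdgeDeltaEnum() : delta(29, 0.0) {}
  void emit(const std::vector<int> &Sv) override {
    int bits = subgraph_bits(Sv);  // has bit 0 set: (u,v) present
    int t1 = g_cat.table[Sv.size()][bits];
    int t0 = g_cat.table[Sv.size()][bits & ~1];
    if (t1) delta[t1 - 1] += 1.0;
    if (t0) delta[t0 - 1] -= 1.0;
  }
};

// [[Rcpp::export]]
NumericVector cpp_delta_edge(List adj, int u, int v, int ng) {
  build_catalog();
  AdjList a = adj_from_list(adj);
  int u0 = u - 1, v0 = v - 1;
  if (!has_edge(a, u0, v0))
    stop("internal: delta enumeration requires the edge to be present");
  EdgeDeltaEnum e;
  e.adj = &a;
  e.K = ng;
  e.run_anchored({u0, v0});
  NumericVector out = wrap(e.delta);
  out.attr("work") = (double)e.work;
  return out;
}

// Delta for adding node u (adjacency must already contain u and its edges):
// + counts of every connected set through u. Caller negates for removal.
// [[Rcpp::export]]
NumericVector cpp_delta_node(List adj, int u, int ng) {
  build_catalog();
  AdjList a = adj_from_list(adj);
  CountEnum e;
  e.adj = &a;
  e.K = ng;
  e.run_anchored({u - 1});
  NumericVector out = wrap(e.counts);
  out.attr("work") = (double)e.work;
  return out;
}

struct CollectEnum : Enum {
  std::vector<std::vector<int>> sets;
  void emit(const std::vector<int> &Sv) override {
    // anchors need not be mutually adjacent; keep connected sets only
    if (g_cat.table[Sv.size()][subgraph_bits(Sv)] == 0) return;
    std::vector<int> s = Sv;
    std::sort(s.begin(), s.end());
    sets.push_back(s);
  }
};

// [[Rcpp::export]]
List cpp_enumerate_sets(List adj, IntegerVector anchors, int max_order) {
  build_catalog();
  AdjList a = adj_from_list(adj);
  CollectEnum e;
  e.adj = &a;
  e.K = max_order;
  if (anchors.size() == 0) {
    e.run_full();
  } else {
    std::vector<int> an;
    for (int i = 0; i < anchors.size(); ++i) an.push_back(anchors[i] - 1);
    e.run_anchored(an);
  }
  List out(e.sets.size());
  for (size_t i = 0; i < e.sets.size(); ++i) {
    IntegerVector s(e.sets[i].size());
    for (size_t j = 0; j < e.sets[i].size(); ++j) s[j] = e.sets[i][j] + 1;
    out[i] = s;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Monte-Carlo possible-world sampling: per world keep each edge with its
// probability (draws consumed in the stored edge order), take the largest
// connected component (first max in node-scan order = smallest-label
// tie-break), accumulate moments of n, m, degree histogram and graphlet
// counts. Uses R's RNG so runs are seed-reproducible from R.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_sample_statistics(IntegerMatrix edges, NumericVector probs, int nv,
                           int S, int ng) {
  build_catalog();
  int m = edges.nrow();
  // max backbone degree bounds the histogram support
  std::vector<int> bdeg(nv, 0);
  for (int e = 0; e < m; ++e) { bdeg[edges(e, 0) - 1]++; bdeg[edges(e, 1) - 1]++; }
  int K = 0;
  for (int v = 0; v < nv; ++v) K = std::max(K, bdeg[v]);
  if (K == 0) K = 1;

  double sn1 = 0, sn2 = 0, sm1 = 0, sm2 = 0;
  std::vector<double> sN1(K, 0.0), sN2(K, 0.0), occN(K, 0.0);
  std::vector<double> sC1(29, 0.0), sC2(29, 0.0);

  std::vector<char> keep(m);
  std::vector<int> deg(nv), comp(nv), queue(nv);
  AdjList world(nv);
  RNGScope scope;

  for (int s = 0; s < S; ++s) {
    for (int e = 0; e < m; ++e) keep[e] = unif_rand() < probs[e];
    std::fill(deg.begin(), deg.end(), 0);
    for (int e = 0; e < m; ++e)
      if (keep[e]) { deg[edges(e, 0) - 1]++; deg[edges(e, 1) - 1]++; }
    for (int v = 0; v < nv; ++v) { world[v].clear(); world[v].reserve(deg[v]); }
    for (int e = 0; e < m; ++e)
      if (keep[e]) {
        int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
        world[a].push_back(b);
        world[b].push_back(a);
      }
    // components; first component of max size wins (smallest-label tie-break)
    std::fill(comp.begin(), comp.end(), -1);
    int best_comp = -1, best_size = 0, nc = 0;
    for (int v = 0; v < nv; ++v) {
      if (comp[v] >= 0) continue;
      int head = 0, tail = 0, size = 0;
      comp[v] = nc;
      queue[tail++] = v;
      while (head < tail) {
        int x = queue[head++];
        size++;
        for (int y : world[x])
          if (comp[y] < 0) { comp[y] = nc; queue[tail++] = y; }
      }
      if (size > best_size) { best_size = size; best_comp = nc; }
      nc++;
    }
    // collect LCC, reindex
    std::vector<int> members, index(nv, -1);
    members.reserve(best_size);
    for (int v = 0; v < nv; ++v)
      if (comp[v] == best_comp) { index[v] = members.size(); members.push_back(v); }
    int ns = members.size();
    double ms = 0;
    std::vector<char> seen_deg(K + 1, 0);
    for (int v : members) {
      ms += deg[v];
      if (deg[v] >= 1) {
        sN1[deg[v] - 1] += 1.0;
        if (!seen_deg[deg[v]]) { seen_deg[deg[v]] = 1; occN[deg[v] - 1] += 1.0; }
      }
    }
    ms /= 2.0;
    // per-sample histogram second moments need per-degree counts
    std::vector<int> histw(K, 0);
    for (int v : members) if (deg[v] >= 1) histw[deg[v] - 1]++;
    for (int k = 0; k < K; ++k) sN2[k] += (double)histw[k] * histw[k];
    sn1 += ns; sn2 += (double)ns * ns;
    sm1 += ms; sm2 += ms * ms;

    AdjList sub(ns);
    for (int v : members) {
      sub[index[v]].reserve(deg[v]);
      for (int y : world[v]) sub[index[v]].push_back(index[y]);
      std::sort(sub[index[v]].begin(), sub[index[v]].end());
    }
    CountEnum ce;
    ce.adj = &sub;
    ce.K = ng;
    ce.run_full();
    for (int t = 0; t < 29; ++t) {
      sC1[t] += ce.counts[t];
      sC2[t] += ce.counts[t] * ce.counts[t];
    }
  }

  return List::create(
      _["sum_n"] = sn1, _["sumsq_n"] = sn2, _["sum_m"] = sm1,
      _["sumsq_m"] = sm2, _["sum_N"] = wrap(sN1), _["sumsq_N"] = wrap(sN2),
      _["occ_N"] = wrap(occN), _["sum_C"] = wrap(sC1),
      _["sumsq_C"] = wrap(sC2), _["max_degree"] = K);
}

// ---------------------------------------------------------------------------
// Largest clique containing a given node: Bron-Kerbosch (with pivoting) on
// the subgraph induced by the neighborhood of v, size-capped. Used by the
// node-insertion proposal to extend order >= 4 cliques.
// ---------------------------------------------------------------------------

static void bk(const AdjList &a, std::vector<int> &R, std::vector<int> P,
               std::vector<int> X, std::vector<int> &best, int cap) {
  if ((int)best.size() >= cap) return;
  if (P.empty() && X.empty()) {
    if (R.size() > best.size()) best = R;
    return;
  }
  if (R.size() + P.size() <= best.size()) return;
  // pivot: node of P u X with most neighbors in P
  int pivot = -1, bestdeg = -1;
  for (int u : P) {
    int d = 0;
    for (int w : P) if (w != u && has_edge(a, u, w)) d++;
    if (d > bestdeg) { bestdeg = d; pivot = u; }
  }
  for (int u : X) {
    int d = 0;
    for (int w : P) if (has_edge(a, u, w)) d++;
    if (d > bestdeg) { bestdeg = d; pivot = u; }
  }
  std::vector<int> cand;
  for (int u : P)
    if (pivot < 0 || !has_edge(a, u, pivot)) cand.push_back(u);
  for (int u : cand) {
    std::vector<int> P2, X2;
    for (int w : P) if (w != u && has_edge(a, u, w)) P2.push_back(w);
    for (int w : X) if (has_edge(a, u, w)) X2.push_back(w);
    R.push_back(u);
    bk(a, R, P2, X2, best, cap);
    R.pop_back();
    P.erase(std::find(P.begin(), P.end(), u));
    X.push_back(u);
    if ((int)best.size() >= cap) return;
  }
}

// [[Rcpp::export]]
IntegerVector cpp_largest_clique_with(List adj, int v, int cap) {
  AdjList a = adj_from_list(adj);
  int v0 = v - 1;
  std::vector<int> P = a[v0], X, R, best;
  bk(a, R, P, X, best, cap - 1);  // clique within N(v); v joins afterwards
  IntegerVector out(best.size() + 1);
  out[0] = v;
  for (size_t i = 0; i < best.size(); ++i) out[i + 1] = best[i] + 1;
  return out;
}
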