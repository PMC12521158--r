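// Core unweighted-graph primitives for the sparsity sweep.
// All functions take a dense 0/1 integer adjacency matrix (symmetric, zero
// diagonal). Graphs are converted once to CSR adjacency; BFS uses flat
// preallocated queues (hot path: null-network ensembles at connectome
// scale, N ~ 90, repeated tens of thousands of times). RNG draws go
// through R's generator so set.seed() on the R side controls every swap.
#include <Rcpp.h>
using namespace Rcpp;

struct CSR {
  int n;
  std::vector<int> off;  // size n + 1
  std::vector<int> nb;   // size 2m
};

static CSR build_csr(const IntegerMatrix& a) {
  CSR g;
  int n = a.nrow();
  g.n = n;
  g.off.assign(n + 1, 0);
  const int* p = a.begin();  // column-major; symmetric, so columns = rows
  for (int j = 0; j < n; ++j) {
    const int* col = p + (size_t) j * n;
    int d = 0;
    for (int i = 0; i < n; ++i) d += (col[i] != 0);
    g.off[j + 1] = g.off[j] + d;
  }
  g.nb.resize(g.off[n]);
  for (int j = 0; j < n; ++j) {
    const int* col = p + (size_t) j * n;
    int k = g.off[j];
    for (int i = 0; i < n; ++i)
      if (col[i] != 0) g.nb[k++] = i;
  }
  return g;
}

// BFS from src; dist must be length n (overwritten, -1 = unreachable),
// queue must be length n scratch space.
static void bfs(const CSR& g, int src, int* dist, int* queue) {
  for (int i = 0; i < g.n; ++i) dist[i] = -1;
  int head = 0, tail = 0;
  dist[src] = 0;
  queue[tail++] = src;
  while (head < tail) {
    int v = queue[head++];
    int dv = dist[v] + 1;
    for (int k = g.off[v]; k < g.off[v + 1]; ++k) {
      int w = g.nb[k];
      if (dist[w] < 0) {
        dist[w] = dv;
        queue[tail++] = w;
      }
    }
  }
}

// All-pairs shortest-path lengths; unreachable pairs are +Inf.
// [[Rcpp::export]]
NumericMatrix cpp_distances(IntegerMatrix adj) {
  CSR g = build_csr(adj);
  int n = g.n;
  NumericMatrix d(n, n);
  std::vector<int> dist(n), queue(n);
  for (int s = 0; s < n; ++s) {
    bfs(g, s, dist.data(), queue.data());
    for (int j = 0; j < n; ++j)
      d(s, j) = dist[j] < 0 ? R_PosInf : (double) dist[j];
  }
  return d;
}

// Brandes' accumulation of shortest-path dependencies; undirected,
// unnormalized, each unordered pair counted once.
// [[Rcpp::export]]
NumericVector cpp_betweenness(IntegerMatrix adj) {
  CSR g = build_csr(adj);
  int n = g.n;
  NumericVector bc(n);
  std::vector<int> dist(n), order(n);
  std::vector<double> sigma(n), delta(n);
  for (int s = 0; s < n; ++s) {
    for (int i = 0; i < n; ++i) { dist[i] = -1; sigma[i] = 0.0; delta[i] = 0.0; }
    // first BFS pass: distances and path counts in visit order
    int head = 0, tail = 0;
    dist[s] = 0;
    sigma[s] = 1.0;
    order[tail++] = s;
    while (head < tail) {
      int v = order[head++];
      int dv = dist[v] + 1;
      for (int k = g.off[v]; k < g.off[v + 1]; ++k) {
        int w = g.nb[k];
        if (dist[w] < 0) {
          dist[w] = dv;
          order[tail++] = w;
        }
        if (dist[w] == dv) sigma[w] += sigma[v];
      }
    }
    // dependency accumulation in reverse visit order; predecessors of w
    // are neighbours at distance dist[w] - 1
    for (int i = tail - 1; i > 0; --i) {
      int w = order[i];
      double coef = (1.0 + delta[w]) / sigma[w];
      for (int k = g.off[w]; k < g.off[w + 1]; ++k) {
        int v = g.nb[k];
        if (dist[v] == dist[w] - 1) delta[v] += sigma[v] * coef;
      }
      bc[w] += delta[w];
    }
  }
  for (int i = 0; i < n; ++i) bc[i] /= 2.0;  // each pair visited from both ends
  return bc;
}

static void clustering_csr(const CSR& g, const IntegerMatrix& adj, double* cc) {
  int n = g.n;
  const int* p = adj.begin();
  for (int i = 0; i < n; ++i) {
    int k = g.off[i + 1] - g.off[i];
    if (k < 2) {
      cc[i] = 0.0;
      continue;
    }
    int t = 0;
    for (int a = g.off[i]; a < g.off[i + 1]; ++a) {
      const int* col = p + (size_t) g.nb[a] * n;
      for (int b = a + 1; b < g.off[i + 1]; ++b)
        t += (col[g.nb[b]] != 0);
    }
    cc[i] = 2.0 * t / ((double) k * (k - 1));
  }
}

// Per-node clustering coefficient 2*t_i / (k_i * (k_i - 1)); 0 when k < 2.
// [[Rcpp::export]]
NumericVector cpp_clustering(IntegerMatrix adj) {
  CSR g = build_csr(adj);
  NumericVector cc(g.n);
  clustering_csr(g, adj, cc.begin());
  return cc;
}

// Per-node local efficiency: global efficiency of the subgraph induced by
// the node's neighbours; 0 when k < 2.
// [[Rcpp::export]]
NumericVector cpp_local_efficiency(IntegerMatrix adj) {
  CSR g = build_csr(adj);
  int n = g.n;
  const int* p = adj.begin();
  NumericVector eloc(n);
  std::vector<int> sub_off, sub_nb, dist, queue;
  for (int i = 0; i < n; ++i) {
    int k = g.off[i + 1] - g.off[i];
    if (k < 2) {
      eloc[i] = 0.0;
      continue;
    }
    const int* nbrs = g.nb.data() + g.off[i];
    // induced subgraph on the neighbours, in CSR form
    sub_off.assign(k + 1, 0);
    sub_nb.clear();
    for (int a = 0; a < k; ++a) {
      const int* col = p + (size_t) nbrs[a] * n;
      for (int b = 0; b < k; ++b)
        if (b != a && col[nbrs[b]] != 0) sub_nb.push_back(b);
      sub_off[a + 1] = (int) sub_nb.size();
    }
    CSR sub;
    sub.n = k;
    sub.off = sub_off;
    sub.nb = sub_nb;
    dist.assign(k, 0);
    queue.assign(k, 0);
    double acc = 0.0;
    for (int a = 0; a < k; ++a) {
      bfs(sub, a, dist.data(), queue.data());
      for (int b = 0; b < k; ++b)
        if (b != a && dist[b] > 0) acc += 1.0 / dist[b];
    }
    eloc[i] = acc / ((double) k * (k - 1));
  }
  return eloc;
}

// Fast path used for null ensembles: mean nodal clustering and
// characteristic path length over connected ordered pairs.
// [[Rcpp::export]]
NumericVector cpp_cp_lp(IntegerMatrix adj) {
  CSR g = build_csr(adj);
  int n = g.n;
  std::vector<double> cc(n);
  clustering_csr(g, adj, cc.data());
  double cp = 0.0;
  for (int i = 0; i < n; ++i) cp += cc[i];
  cp /= n;
  double lsum = 0.0;
  long lcount = 0;
  std::vector<int> dist(n), queue(n);
  for (int s = 0; s < n; ++s) {
    bfs(g, s, dist.data(), queue.data());
    for (int j = 0; j < n; ++j)
      if (j != s && dist[j] > 0) {
        lsum += dist[j];
        ++lcount;
      }
  }
  double lp = lcount > 0 ? lsum / lcount : R_PosInf;
  return NumericVector::create(cp, lp);
}

// Degree-preserving randomization by double-edge swaps (Maslov-Sneppen).
// Two edges (a,b),(c,d) are rewired to (a,d),(c,b); swaps creating
// self-loops or multi-edges are rejected. Uses R's RNG.
// [[Rcpp::export]]
List cpp_double_edge_swap(IntegerMatrix adj, int n_attempts) {
  IntegerMatrix a = clone(adj);
  int n = a.nrow();
  int* p = a.begin();
  std::vector<std::pair<int, int> > edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (p[i + (size_t) j * n] != 0) edges.push_back(std::make_pair(i, j));
  int m = (int) edges.size();
  int successes = 0;
  if (m >= 2) {
    for (int att = 0; att < n_attempts; ++att) {
      int e1 = (int) (unif_rand() * m);
      int e2 = (int) (unif_rand() * m);
      if (e1 >= m) e1 = m - 1;
      if (e2 >= m) e2 = m - 1;
      if (e1 == e2) continue;
      int aa = edges[e1].first, bb = edges[e1].second;
      int cc = edges[e2].first, dd = edges[e2].second;
      if (unif_rand() < 0.5) std::swap(cc, dd);  // random orientation
      // proposed: (aa,dd) and (cc,bb)
      if (aa == dd || cc == bb) continue;
      if (aa == cc || bb == dd) continue;  // shared endpoint, no-op/multi
      if (p[aa + (size_t) dd * n] != 0 || p[cc + (size_t) bb * n] != 0) continue;
      p[aa + (size_t) bb * n] = p[bb + (size_t) aa * n] = 0;
      p[cc + (size_t) dd * n] = p[dd + (size_t) cc * n] = 0;
      p[aa + (size_t) dd * n] = p[dd + (size_t) aa * n] = 1;
      p[cc + (size_t) bb * n] = p[bb + (size_t) cc * n] = 1;
      edges[e1] = std::make_pair(std::min(aa, dd), std::max(aa, dd));
      edges[e2] = std::make_pair(std::min(cc, bb), std::max(cc, bb));
      ++successes;
    }
  }
  return List::create(Named("adjacency") = a,
                      Named("n_swaps") = successes);
}

// Null-ensemble normalization in one call: generates n_nulls rewired
// graphs (swaps_per_edge * m attempts each) and returns each null's mean
// clustering and characteristic path length. Equivalent to calling
// cpp_double_edge_swap + cpp_cp_lp per null, without per-null R overhead.
// [[Rcpp::export]]
NumericMatrix cpp_null_cp_lp(IntegerMatrix adj, int n_nulls, int swaps_per_edge) {
  NumericMatrix out(n_nulls, 2);
  int m2 = 0;
  for (int i = 0; i < adj.length(); ++i) m2 += (adj[i] != 0);
  int attempts = swaps_per_edge * (m2 / 2);
  for (int r = 0; r < n_nulls; ++r) {
    List res = cpp_double_edge_swap(adj, attempts);
    IntegerMatrix na = res["adjacency"];
    NumericVector s = cpp_cp_lp(na);
    out(r, 0) = s[0];
    out(r, 1) = s[1];
  }
  return out;
}
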