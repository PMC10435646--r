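#include <Rcpp.h>
using namespace Rcpp;

// Compiled kernels for the permutation engine: all-pairs BFS distances,
// Brandes betweenness, and the scalar metric profile over a nested
// density grid. Graph sizes are small (tens of nodes) but the engine
// evaluates hundreds of thousands of thresholded graphs, so these loops
// are the package's one piece of compiled code.

// All-pairs shortest-path hop counts of a binary undirected graph;
// unreachable pairs get Inf.
// [[Rcpp::export(".cppBfsDistances")]]
NumericMatrix cppBfsDistances(NumericMatrix adj) {
  const int n = adj.nrow();
  std::vector< std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j) != 0) nb[i].push_back(j);
  NumericMatrix D(n, n);
  std::fill(D.begin(), D.end(), R_PosInf);
  std::vector<int> queue(n), dist(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    int head = 0, tail = 0;
    queue[tail++] = s;
    dist[s] = 0;
    while (head < tail) {
      int u = queue[head++];
      for (size_t a = 0; a < nb[u].size(); ++a) {
        int v = nb[u][a];
        if (dist[v] < 0) { dist[v] = dist[u] + 1; queue[tail++] = v; }
      }
    }
    for (int j = 0; j < n; ++j)
      if (dist[j] >= 0) D(s, j) = dist[j];
  }
  return D;
}

// Unnormalized betweenness centrality over unordered pairs (Brandes'
// accumulation on the unweighted graph).
// [[Rcpp::export(".cppBetweenness")]]
NumericVector cppBetweenness(NumericMatrix adj) {
  const int n = adj.nrow();
  std::vector< std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j) != 0) nb[i].push_back(j);
  NumericVector bc(n);
  std::vector<int> stack(n), dist(n);
  std::vector<double> sigma(n), delta(n);
  std::vector< std::vector<int> > pred(n);
  for (int s = 0; s < n; ++s) {
    for (int i = 0; i < n; ++i) {
      pred[i].clear(); dist[i] = -1; sigma[i] = 0.0; delta[i] = 0.0;
    }
    dist[s] = 0; sigma[s] = 1.0;
    int head = 0, tail = 0;
    std::vector<int> queue(n);
    queue[tail++] = s;
    int sp = 0;
    while (head < tail) {
      int u = queue[head++];
      stack[sp++] = u;
      for (size_t a = 0; a < nb[u].size(); ++a) {
        int v = nb[u][a];
        if (dist[v] < 0) { dist[v] = dist[u] + 1; queue[tail++] = v; }
        if (dist[v] == dist[u] + 1) { sigma[v] += sigma[u]; pred[v].push_back(u); }
      }
    }
    while (sp > 0) {
      int w = stack[--sp];
      for (size_t a = 0; a < pred[w].size(); ++a) {
        int v = pred[w][a];
        delta[v] += (sigma[v] / sigma[w]) * (1.0 + delta[w]);
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  for (int i = 0; i < n; ++i) bc[i] /= 2.0;  // unordered pairs
  return bc;
}

// Scalar metric profile over a nested density grid. `pairs` is the full
// ranked (i, j) edge list (1-based, strongest correlation first) and `Ks`
// the ascending edge counts to evaluate; edge sets nest, so the graph is
// grown incrementally. Columns: mean clustering, characteristic path
// length (NA when fragmented), transitivity, global efficiency.
// [[Rcpp::export(".cppDensityMetrics")]]
NumericMatrix cppDensityMetrics(IntegerMatrix pairs, IntegerVector Ks,
                                int n) {
  const int nd = Ks.size();
  NumericMatrix out(nd, 4);
  std::vector< std::vector<int> > nb(n);
  std::vector< std::vector<char> > adj(n, std::vector<char>(n, 0));
  int added = 0;
  std::vector<int> queue(n), dist(n);
  const double P = n * (n - 1) / 2.0;
  for (int d = 0; d < nd; ++d) {
    int K = Ks[d];
    for (; added < K; ++added) {
      int i = pairs(added, 0) - 1, j = pairs(added, 1) - 1;
      nb[i].push_back(j); nb[j].push_back(i);
      adj[i][j] = 1; adj[j][i] = 1;
    }
    // clustering and transitivity from per-node triangle counts
    double ccsum = 0.0, sumT = 0.0, triples2 = 0.0;
    for (int v = 0; v < n; ++v) {
      const int k = (int) nb[v].size();
      triples2 += (double) k * (k - 1);
      int t = 0;
      for (size_t a = 0; a < nb[v].size(); ++a)
        for (size_t b = a + 1; b < nb[v].size(); ++b)
          if (adj[nb[v][a]][nb[v][b]]) ++t;
      sumT += t;
      if (k >= 2) ccsum += (2.0 * t) / ((double) k * (k - 1));
    }
    out(d, 0) = ccsum / n;
    out(d, 2) = triples2 > 0 ? 2.0 * sumT / triples2 : 0.0;
    // path length and efficiency from all-pairs BFS
    double pathSum = 0.0, invSum = 0.0;
    bool connected = true;
    for (int s = 0; s < n; ++s) {
      std::fill(dist.begin(), dist.end(), -1);
      int head = 0, tail = 0;
      queue[tail++] = s; dist[s] = 0;
      int reached = 1;
      while (head < tail) {
        int u = queue[head++];
        for (size_t a = 0; a < nb[u].size(); ++a) {
          int v = nb[u][a];
          if (dist[v] < 0) {
            dist[v] = dist[u] + 1; queue[tail++] = v; ++reached;
            pathSum += dist[v]; invSum += 1.0 / dist[v];
          }
        }
      }
      if (reached < n) connected = false;
    }
    out(d, 1) = connected ? pathSum / 2.0 / P : NA_REAL;
    out(d, 3) = invSum / 2.0 / P;
  }
  return out;
}
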