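#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstdlib>
using namespace Rcpp;

// Adjacency list from a symmetric 0/1 matrix (diagonal ignored).
static std::vector< std::vector<int> > adj_list(const IntegerMatrix& A) {
  int n = A.nrow();
  std::vector< std::vector<int> > nb(n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (i != j && A(i, j) != 0) nb[j].push_back(i);
  return nb;
}

// Per-node characteristic path length: mean BFS distance to every node
// reachable from the source. Isolated nodes -> NA.
// [[Rcpp::export]]
NumericVector cpp_path_length(IntegerMatrix A) {
  int n = A.nrow();
  std::vector< std::vector<int> > nb = adj_list(A);
  NumericVector L(n, NA_REAL);
  std::vector<int> dist(n), q(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    int head = 0, tail = 0;
    dist[s] = 0;
    q[tail++] = s;
    double sum = 0.0;
    int cnt = 0;
    while (head < tail) {
      int v = q[head++];
      for (size_t t = 0; t < nb[v].size(); ++t) {
        int w = nb[v][t];
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          sum += dist[w];
          ++cnt;
          q[tail++] = w;
        }
      }
    }
    if (cnt > 0) L[s] = sum / cnt;
  }
  return L;
}

// Local clustering coefficient: edges among neighbours / (k*(k-1)/2),
// 0 when k < 2.
// [[Rcpp::export]]
NumericVector cpp_clustering(IntegerMatrix A) {
  int n = A.nrow();
  std::vector< std::vector<int> > nb = adj_list(A);
  NumericVector c(n, 0.0);
  for (int i = 0; i < n; ++i) {
    int k = (int)nb[i].size();
    if (k < 2) continue;
    long long e = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (A(nb[i][a], nb[i][b]) != 0) ++e;
    c[i] = 2.0 * (double)e / ((double)k * (k - 1));
  }
  return c;
}

// Brandes betweenness centrality, unweighted, each unordered pair counted
// once, no endpoint inclusion, no normalization.
// [[Rcpp::export]]
NumericVector cpp_betweenness(IntegerMatrix A) {
  int n = A.nrow();
  std::vector< std::vector<int> > nb = adj_list(A);
  NumericVector bc(n, 0.0);
  std::vector<int> dist(n), q(n), stack;
  stack.reserve(n);
  std::vector<double> sigma(n), delta(n);
  std::vector< std::vector<int> > pred(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = 0; i < n; ++i) pred[i].clear();
    stack.clear();
    int head = 0, tail = 0;
    dist[s] = 0;
    sigma[s] = 1.0;
    q[tail++] = s;
    while (head < tail) {
      int v = q[head++];
      stack.push_back(v);
      for (size_t t = 0; t < nb[v].size(); ++t) {
        int w = nb[v][t];
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          q[tail++] = w;
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] += sigma[v];
          pred[w].push_back(v);
        }
      }
    }
    for (int i = (int)stack.size() - 1; i >= 0; --i) {
      int w = stack[i];
      for (size_t t = 0; t < pred[w].size(); ++t) {
        int v = pred[w][t];
        delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  for (int i = 0; i < n; ++i) bc[i] /= 2.0; // unordered pairs once
  return bc;
}

// Degree-preserving randomization by double-edge swaps (Maslov-Sneppen).
// Picks two edges (a,b),(c,d), rewires to (a,d),(c,b); rejects self-loops,
// multi-edges and shared endpoints. Uses R's RNG; stops after target_swaps
// accepted swaps or max_tries attempts. swapped_out reports accepted count.
// [[Rcpp::export]]
IntegerMatrix cpp_double_edge_swap(IntegerMatrix A, double target_swaps,
                                   double max_tries) {
  int n = A.nrow();
  IntegerMatrix B = clone(A);
  std::vector< std::pair<int,int> > edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (B(i, j) != 0) edges.push_back(std::make_pair(i, j));
  long long m = (long long)edges.size();
  double accepted = 0.0, tries = 0.0;
  if (m >= 2) {
    while (accepted < target_swaps && tries < max_tries) {
      tries += 1.0;
      int e1 = (int)(unif_rand() * m); if (e1 >= m) e1 = (int)m - 1;
      int e2 = (int)(unif_rand() * m); if (e2 >= m) e2 = (int)m - 1;
      if (e1 == e2) continue;
      int a = edges[e1].first, b = edges[e1].second;
      int c = edges[e2].first, d = edges[e2].second;
      if (unif_rand() < 0.5) std::swap(c, d);
      if (a == c || a == d || b == c || b == d) continue;
      if (B(a, d) != 0 || B(c, b) != 0) continue;
      B(a, b) = B(b, a) = 0;
      B(c, d) = B(d, c) = 0;
      B(a, d) = B(d, a) = 1;
      B(c, b) = B(b, c) = 1;
      edges[e1] = std::make_pair(std::min(a, d), std::max(a, d));
      edges[e2] = std::make_pair(std::min(c, b), std::max(c, b));
      accepted += 1.0;
    }
  }
  B.attr("accepted_swaps") = accepted;
  return B;
}

// Connected-component labelling of a 3D logical mask.
// connectivity: 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector< std::array<int,3> > offs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        std::array<int,3> o = {{dx, dy, dz}};
        offs.push_back(o);
      }
  int ntot = (int)mask.size();
  IntegerVector lab(ntot, 0);
  int cur = 0;
  std::vector<int> q;
  for (int idx = 0; idx < ntot; ++idx) {
    if (!mask[idx] || lab[idx] != 0) continue;
    ++cur;
    lab[idx] = cur;
    q.clear();
    q.push_back(idx);
    size_t head = 0;
    while (head < q.size()) {
      int v = q[head++];
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (size_t t = 0; t < offs.size(); ++t) {
        int X = x + offs[t][0], Y = y + offs[t][1], Z = z + offs[t][2];
        if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
        int w = X + nx * (Y + ny * Z);
        if (mask[w] && lab[w] == 0) {
          lab[w] = cur;
          q.push_back(w);
        }
      }
    }
  }
  return lab;
}
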