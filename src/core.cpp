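#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Bounded simple-path machinery shared by the enumeration and the pairwise
// reachability statistics. Graphs arrive as 1-based adjacency lists with
// neighbours sorted ascending; DFS in that order emits paths in lexicographic
// order of their node sequences.

namespace {

struct Dfs {
  const std::vector<std::vector<int>>& adj; // 0-based
  int lmax;
  std::vector<char> visited;
  std::vector<int> path; // path[0] = source

  Dfs(const std::vector<std::vector<int>>& a, int n, int lmax_)
      : adj(a), lmax(lmax_), visited(n, 0), path(lmax_ + 1, -1) {}
};

std::vector<std::vector<int>> as_adj(const List& adj) {
  int n = adj.size();
  std::vector<std::vector<int>> out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj[i];
    out[i].reserve(nb.size());
    for (int j = 0; j < nb.size(); ++j) out[i].push_back(nb[j] - 1);
  }
  return out;
}

void enum_rec(Dfs& d, int u, int depth, int target, List& out) {
  for (int w : d.adj[u]) {
    if (d.visited[w]) continue;
    if (w == target) {
      IntegerVector p(depth + 2);
      for (int i = 0; i <= depth; ++i) p[i] = d.path[i] + 1;
      p[depth + 1] = w + 1;
      out.push_back(p);
    }
    if (depth + 1 < d.lmax && w != target) {
      d.visited[w] = 1;
      d.path[depth + 1] = w;
      enum_rec(d, w, depth + 1, target, out);
      d.visited[w] = 0;
    }
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_bounded_paths(List adj, int from, int to, int lmax) {
  std::vector<std::vector<int>> a = as_adj(adj);
  int n = a.size();
  Dfs d(a, n, lmax);
  int src = from - 1, tgt = to - 1;
  d.visited[src] = 1;
  d.path[0] = src;
  List out;
  enum_rec(d, src, 0, tgt, out);
  return out;
}

// Per-source accumulator for path statistics toward a set of targets.
// For each (source, target) pair it collects, over all simple paths of
// edge-length <= lmax:
//   k_d      : number of paths with d interior nodes (d = len - 1)
//   totlen   : summed edge-lengths
//   cnt[d][v]: how many d-interior paths pass through v as an interior node
// Path diversity over all C(k,2) unordered path pairs,
//   PD = mean(1 - 2 w / (d1 + d2)) with w = shared interior nodes,
// is then recovered exactly from the grouped counts in O(n * lmax) per
// target instead of O(k^2) pair scans.

namespace {

struct PairAcc {
  int n, lmax, ntargets;
  std::vector<int> k;        // ntargets x lmax
  std::vector<double> totlen;
  std::vector<int> cnt;      // ntargets x lmax x n
  PairAcc(int n_, int lmax_, int nt)
      : n(n_), lmax(lmax_), ntargets(nt),
        k(nt * lmax_, 0), totlen(nt, 0.0), cnt((size_t)nt * lmax_ * n_, 0) {}
  void reset() {
    std::fill(k.begin(), k.end(), 0);
    std::fill(totlen.begin(), totlen.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0);
  }
  inline void record(int t, const std::vector<int>& path, int dep) {
    int d = dep - 1; // interior nodes
    k[t * lmax + d] += 1;
    totlen[t] += dep;
    int* c = &cnt[((size_t)t * lmax + d) * n];
    for (int i = 1; i < dep; ++i) c[path[i]] += 1;
  }
};

void stats_rec(Dfs& d, int u, int depth, const std::vector<int>& tindex,
               PairAcc& acc) {
  for (int w : d.adj[u]) {
    if (d.visited[w]) continue;
    int t = tindex[w];
    if (t >= 0) acc.record(t, d.path, depth + 1);
    if (depth + 1 < d.lmax) {
      d.visited[w] = 1;
      d.path[depth + 1] = w;
      stats_rec(d, w, depth + 1, tindex, acc);
      d.visited[w] = 0;
    }
  }
}

void finish_target(const PairAcc& acc, int t, int lmax, int n,
                   double& k_out, double& totlen_out, double& pd_out) {
  const int* kd = &acc.k[t * lmax];
  long ktot = 0;
  for (int d = 0; d < lmax; ++d) ktot += kd[d];
  k_out = (double)ktot;
  totlen_out = acc.totlen[t];
  if (ktot < 2) { pd_out = 0.0; return; }
  // cross-products of interior-membership counts between length groups
  std::vector<double> sums(lmax * lmax, 0.0);
  const int* base = &acc.cnt[(size_t)t * lmax * n];
  for (int v = 0; v < n; ++v) {
    int c[8];
    bool any = false;
    for (int d = 1; d < lmax; ++d) {
      c[d] = base[(size_t)d * n + v];
      if (c[d]) any = true;
    }
    if (!any) continue;
    for (int d1 = 1; d1 < lmax; ++d1) {
      if (!c[d1]) continue;
      for (int d2 = d1; d2 < lmax; ++d2)
        sums[d1 * lmax + d2] += (double)c[d1] * c[d2];
    }
  }
  double npairs = 0.5 * (double)ktot * (ktot - 1);
  double total = npairs;
  for (int d1 = 1; d1 < lmax; ++d1) {
    if (kd[d1] >= 2) {
      double sw = 0.5 * (sums[d1 * lmax + d1] - (double)d1 * kd[d1]);
      total -= sw / d1; // 2*sw / (2*d1)
    }
    for (int d2 = d1 + 1; d2 < lmax; ++d2)
      total -= 2.0 * sums[d1 * lmax + d2] / (d1 + d2);
  }
  double pd = total / npairs;
  if (pd < 0.0) pd = 0.0;
  if (pd > 1.0) pd = 1.0;
  pd_out = pd;
}

} // namespace

// [[Rcpp::export]]
List cpp_source_stats(List adj, int source, IntegerVector targets, int lmax) {
  std::vector<std::vector<int>> a = as_adj(adj);
  int n = a.size(), nt = targets.size();
  std::vector<int> tindex(n, -1);
  for (int t = 0; t < nt; ++t) tindex[targets[t] - 1] = t;
  PairAcc acc(n, lmax, nt);
  Dfs d(a, n, lmax);
  int src = source - 1;
  tindex[src] = -1; // never a target of itself
  d.visited[src] = 1;
  d.path[0] = src;
  stats_rec(d, src, 0, tindex, acc);
  NumericVector k(nt), totlen(nt), pd(nt);
  for (int t = 0; t < nt; ++t) finish_target(acc, t, lmax, n, k[t], totlen[t], pd[t]);
  return List::create(_["k"] = k, _["totlen"] = totlen, _["pd"] = pd);
}

// Full pairwise statistics over the vital-node set; exploits symmetry of
// undirected simple paths (row j < i mirrored from earlier sources).
// [[Rcpp::export]]
List cpp_vital_pair_stats(List adj, IntegerVector vital, int lmax) {
  std::vector<std::vector<int>> a = as_adj(adj);
  int n = a.size(), l = vital.size();
  NumericMatrix k(l, l), totlen(l, l), pd(l, l);
  if (l < 2) return List::create(_["k"] = k, _["totlen"] = totlen, _["pd"] = pd);
  std::vector<int> tindex(n, -1);
  PairAcc acc(n, lmax, l);
  for (int i = 0; i + 1 < l; ++i) {
    std::fill(tindex.begin(), tindex.end(), -1);
    int nt = 0;
    for (int j = i + 1; j < l; ++j) tindex[vital[j] - 1] = nt++;
    acc.reset();
    Dfs d(a, n, lmax);
    int src = vital[i] - 1;
    d.visited[src] = 1;
    d.path[0] = src;
    stats_rec(d, src, 0, tindex, acc);
    for (int j = i + 1; j < l; ++j) {
      int t = j - i - 1;
      double kk, tl, pp;
      finish_target(acc, t, lmax, n, kk, tl, pp);
      k(i, j) = k(j, i) = kk;
      totlen(i, j) = totlen(j, i) = tl;
      pd(i, j) = pd(j, i) = pp;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["k"] = k, _["totlen"] = totlen, _["pd"] = pd);
}

// Size of the largest connected component of the subgraph induced on the
// kept nodes (edges retained only when both endpoints are kept).
// [[Rcpp::export]]
int cpp_gcc_size(List adj, LogicalVector keep) {
  std::vector<std::vector<int>> a = as_adj(adj);
  int n = a.size();
  std::vector<char> seen(n, 0);
  std::vector<int> queue;
  int best = 0;
  for (int s = 0; s < n; ++s) {
    if (seen[s] || !keep[s]) continue;
    queue.clear();
    queue.push_back(s);
    seen[s] = 1;
    int sz = 0;
    while (!queue.empty()) {
      int u = queue.back();
      queue.pop_back();
      ++sz;
      for (int w : a[u])
        if (keep[w] && !seen[w]) { seen[w] = 1; queue.push_back(w); }
    }
    if (sz > best) best = sz;
  }
  return best;
}

// Discrete-time synchronous SIR step loop. States: 0 = S, 1 = I, 2 = R.
// Each step: every susceptible node receives an independent Bernoulli(beta)
// transmission trial per infected neighbour (aggregate infection probability
// 1 - (1 - beta)^m); simultaneously every node infected at the start of the
// step recovers with probability gamma. Nodes infected this step cannot
// recover in the same step. Nodes are processed in index order so the RNG
// stream, hence the whole trajectory, is reproducible under set.seed().
// [[Rcpp::export]]
List cpp_sir_run(List adj, IntegerVector state0, double beta, double gamma,
                 int max_steps) {
  std::vector<std::vector<int>> a = as_adj(adj);
  int n = a.size();
  std::vector<int> state(state0.begin(), state0.end());
  std::vector<char> newly(n, 0), recov(n, 0);
  std::vector<int> sC, iC, rC;
  int s = 0, i = 0, r = 0;
  for (int v = 0; v < n; ++v) {
    if (state[v] == 0) ++s; else if (state[v] == 1) ++i; else ++r;
  }
  sC.push_back(s); iC.push_back(i); rC.push_back(r);
  int steps = 0;
  while (i > 0 && steps < max_steps) {
    std::fill(newly.begin(), newly.end(), 0);
    std::fill(recov.begin(), recov.end(), 0);
    for (int v = 0; v < n; ++v) {
      if (state[v] != 1) continue;
      for (int w : a[v])
        if (state[w] == 0 && unif_rand() < beta) newly[w] = 1;
      if (unif_rand() < gamma) recov[v] = 1;
    }
    for (int v = 0; v < n; ++v) {
      if (newly[v]) { state[v] = 1; --s; ++i; }
      else if (recov[v]) { state[v] = 2; --i; ++r; }
    }
    ++steps;
    sC.push_back(s); iC.push_back(i); rC.push_back(r);
    if ((steps & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["s"] = wrap(sC), _["i"] = wrap(iC), _["r"] = wrap(rC),
                      _["steps"] = steps, _["extinct"] = (i == 0));
}
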