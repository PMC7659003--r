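#include <Rcpp.h>
#include <unordered_set>
#include <map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Directed-edge key inside a graph on nv nodes
static inline long long ekey(int a, int b, int nv) {
  return (long long)a * nv + b;
}

struct CensusCtx {
  int nv, k;
  const std::vector<std::vector<int> > *adj;   // undirected neighbor lists
  const std::unordered_set<long long> *eset;   // directed edges
  const int *canon;                            // canonical map, length 2^(k*k)
  std::map<int, double> counts;
  int collect_id;                              // -1 = no collection
  std::vector<int> instances;                  // flattened collected subsets
};

static void record_subset(CensusCtx &ctx, const std::vector<int> &sub) {
  int k = ctx.k;
  int kk = k * k;
  std::vector<int> s(sub);
  std::sort(s.begin(), s.end());
  int mask = 0;
  for (int a = 0; a < k; ++a) {
    for (int b = 0; b < k; ++b) {
      if (a == b) continue;
      if (ctx.eset->count(ekey(s[a], s[b], ctx.nv))) {
        mask |= 1 << (kk - (k * a + b + 1));
      }
    }
  }
  int c = ctx.canon[mask];
  ctx.counts[c] += 1.0;
  if (ctx.collect_id >= 0 && c == ctx.collect_id) {
    for (int a = 0; a < k; ++a) ctx.instances.push_back(s[a]);
  }
}

// true if u is adjacent (either direction) to any node of sub
static inline bool nbr_of_sub(const CensusCtx &ctx, int u,
                              const std::vector<int> &sub) {
  for (size_t i = 0; i < sub.size(); ++i) {
    if (ctx.eset->count(ekey(u, sub[i], ctx.nv)) ||
        ctx.eset->count(ekey(sub[i], u, ctx.nv))) return true;
  }
  return false;
}

static void esu_extend(CensusCtx &ctx, std::vector<int> &sub,
                       std::vector<int> ext, int v) {
  if ((int)sub.size() == ctx.k) {
    record_subset(ctx, sub);
    return;
  }
  while (!ext.empty()) {
    int w = ext.back();
    ext.pop_back();
    std::vector<int> ext2(ext);
    const std::vector<int> &nw = (*ctx.adj)[w];
    for (size_t t = 0; t < nw.size(); ++t) {
      int u = nw[t];
      if (u <= v) continue;
      if (std::find(sub.begin(), sub.end(), u) != sub.end()) continue;
      if (u == w) continue;
      if (nbr_of_sub(ctx, u, sub)) continue;  // exclusive neighborhood of w
      if (std::find(ext2.begin(), ext2.end(), u) == ext2.end()) {
        ext2.push_back(u);
      }
    }
    sub.push_back(w);
    esu_extend(ctx, sub, ext2, v);
    sub.pop_back();
  }
}

// Exact enumeration (ESU) of connected induced k-node subgraphs.
// from/to are 0-based node indices; canon_map has length 2^(k*k).
// [[Rcpp::export]]
List esu_census_cpp(int nv, IntegerVector from, IntegerVector to, int k,
                    IntegerVector canon_map, int collect_id) {
  std::unordered_set<long long> eset;
  std::vector<std::vector<int> > adj(nv);
  for (int e = 0; e < from.size(); ++e) {
    int a = from[e], b = to[e];
    if (a == b) continue;
    if (eset.insert(ekey(a, b, nv)).second) {
      adj[a].push_back(b);
      adj[b].push_back(a);
    }
  }
  for (int v = 0; v < nv; ++v) {
    std::sort(adj[v].begin(), adj[v].end());
    adj[v].erase(std::unique(adj[v].begin(), adj[v].end()), adj[v].end());
  }
  CensusCtx ctx;
  ctx.nv = nv; ctx.k = k; ctx.adj = &adj; ctx.eset = &eset;
  ctx.canon = INTEGER(canon_map);
  ctx.collect_id = collect_id;

  std::vector<int> sub;
  for (int v = 0; v < nv; ++v) {
    std::vector<int> ext;
    for (size_t t = 0; t < adj[v].size(); ++t) {
      if (adj[v][t] > v) ext.push_back(adj[v][t]);
    }
    sub.clear();
    sub.push_back(v);
    esu_extend(ctx, sub, ext, v);
  }

  IntegerVector ids((int)ctx.counts.size());
  NumericVector counts((int)ctx.counts.size());
  int i = 0;
  for (std::map<int, double>::iterator it = ctx.counts.begin();
       it != ctx.counts.end(); ++it, ++i) {
    ids[i] = it->first;
    counts[i] = it->second;
  }
  IntegerMatrix inst(0, k);
  if (ctx.collect_id >= 0 && !ctx.instances.empty()) {
    int ni = (int)ctx.instances.size() / k;
    inst = IntegerMatrix(ni, k);
    for (int r = 0; r < ni; ++r) {
      for (int c = 0; c < k; ++c) inst(r, c) = ctx.instances[r * k + c];
    }
  }
  return List::create(_["ids"] = ids, _["counts"] = counts,
                      _["instances"] = inst);
}

// Degree-preserving edge-switch randomization that also preserves the
// number of reciprocal (mutual) dyads: non-reciprocal arcs are switched
// among themselves (rejecting switches that would create a reciprocal
// pair), and reciprocal dyads are rewired as units.
// [[Rcpp::export]]
List switch_randomize_cpp(int nv, IntegerVector from, IntegerVector to,
                          int n_attempts) {
  std::unordered_set<long long> eset;
  for (int e = 0; e < from.size(); ++e) eset.insert(ekey(from[e], to[e], nv));
  std::vector<std::pair<int, int> > singles, mutuals;
  for (int e = 0; e < from.size(); ++e) {
    int a = from[e], b = to[e];
    if (eset.count(ekey(b, a, nv))) {
      if (a < b) mutuals.push_back(std::make_pair(a, b));
    } else {
      singles.push_back(std::make_pair(a, b));
    }
  }
  int ns = (int)singles.size(), nm = (int)mutuals.size();
  GetRNGstate();
  for (int att = 0; att < n_attempts; ++att) {
    double total = (ns >= 2 ? ns : 0) + (nm >= 2 ? nm : 0);
    if (total == 0) break;
    bool pick_single = false;
    if (ns >= 2 && nm >= 2) {
      pick_single = unif_rand() * total < ns;
    } else {
      pick_single = ns >= 2;
    }
    if (pick_single) {
      int i1 = (int)(unif_rand() * ns); if (i1 >= ns) i1 = ns - 1;
      int i2 = (int)(unif_rand() * ns); if (i2 >= ns) i2 = ns - 1;
      if (i1 == i2) continue;
      int a = singles[i1].first, b = singles[i1].second;
      int c = singles[i2].first, d = singles[i2].second;
      if (a == c || b == d || a == d || c == b) continue;
      if (eset.count(ekey(a, d, nv)) || eset.count(ekey(d, a, nv)) ||
          eset.count(ekey(c, b, nv)) || eset.count(ekey(b, c, nv))) continue;
      eset.erase(ekey(a, b, nv));
      eset.erase(ekey(c, d, nv));
      eset.insert(ekey(a, d, nv));
      eset.insert(ekey(c, b, nv));
      singles[i1].second = d;
      singles[i2].second = b;
    } else {
      int i1 = (int)(unif_rand() * nm); if (i1 >= nm) i1 = nm - 1;
      int i2 = (int)(unif_rand() * nm); if (i2 >= nm) i2 = nm - 1;
      if (i1 == i2) continue;
      int a = mutuals[i1].first, b = mutuals[i1].second;
      int c = mutuals[i2].first, d = mutuals[i2].second;
      if (a == c || a == d || b == c || b == d) continue;
      // propose dyads {a,d} and {c,b}
      if (eset.count(ekey(a, d, nv)) || eset.count(ekey(d, a, nv)) ||
          eset.count(ekey(c, b, nv)) || eset.count(ekey(b, c, nv))) continue;
      eset.erase(ekey(a, b, nv)); eset.erase(ekey(b, a, nv));
      eset.erase(ekey(c, d, nv)); eset.erase(ekey(d, c, nv));
      eset.insert(ekey(a, d, nv)); eset.insert(ekey(d, a, nv));
      eset.insert(ekey(c, b, nv)); eset.insert(ekey(b, c, nv));
      mutuals[i1] = std::make_pair(std::min(a, d), std::max(a, d));
      mutuals[i2] = std::make_pair(std::min(c, b), std::max(c, b));
    }
  }
  PutRNGstate();
  int ne = ns + 2 * nm;
  IntegerVector of(ne), ot(ne);
  int i = 0;
  for (int e = 0; e < ns; ++e, ++i) {
    of[i] = singles[e].first; ot[i] = singles[e].second;
  }
  for (int e = 0; e < nm; ++e) {
    of[i] = mutuals[e].first;  ot[i] = mutuals[e].second;  ++i;
    of[i] = mutuals[e].second; ot[i] = mutuals[e].first;   ++i;
  }
  return List::create(_["from"] = of, _["to"] = ot);
}
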