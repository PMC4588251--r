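// De Bruijn local assembly of an active region.
//
// Reads assigned to the region are decomposed into k-mers and assembled
// into a graph with edges weighted by observation counts, with the
// reference segment as a backbone.  Non-reference edges below the pruning
// weight are dropped.  A graph is degenerate when the backbone k-mers are
// not unique, the backbone is disconnected, or the subgraph reachable from
// the source contains a cycle; degenerate graphs are rebuilt with the next
// (longer) k-mer size in the schedule.  All source-to-sink paths are
// candidate haplotypes, capped at max_haps with higher-weight paths
// (minimum edge weight along the path) preferred.

#include "rapidseq.h"
#include <map>
#include <set>
using namespace Rcpp;

namespace {

struct Graph {
  std::unordered_map<std::string, int> id;
  std::vector<std::string> kmer;
  // adjacency: node -> (next node, weight, is_ref)
  std::vector<std::vector<std::array<int, 3> > > adj;
  int node(const std::string& s) {
    auto it = id.find(s);
    if (it != id.end()) return it->second;
    int i = (int)kmer.size();
    id.emplace(s, i);
    kmer.push_back(s);
    adj.push_back({});
    return i;
  }
  void add_edge(int u, int v, int w, bool is_ref) {
    for (auto& e : adj[u])
      if (e[0] == v) {
        e[1] += w;
        if (is_ref) e[2] = 1;
        return;
      }
    adj[u].push_back({v, w, is_ref ? 1 : 0});
  }
};

bool has_cycle_from(const Graph& g, int src) {
  // iterative DFS with colors over nodes reachable from src
  std::vector<int> color(g.kmer.size(), 0);  // 0 white 1 grey 2 black
  std::vector<std::pair<int, size_t> > stack;
  stack.push_back({src, 0});
  color[src] = 1;
  while (!stack.empty()) {
    auto& top = stack.back();
    if (top.second < g.adj[top.first].size()) {
      int v = g.adj[top.first][top.second][0];
      top.second++;
      if (color[v] == 1) return true;
      if (color[v] == 0) {
        color[v] = 1;
        stack.push_back({v, 0});
      }
    } else {
      color[top.first] = 2;
      stack.pop_back();
    }
  }
  return false;
}

struct PathAcc {
  std::vector<std::string> haps;
  std::vector<double> weights;
  long steps = 0;
};

void enum_paths(const Graph& g, int node, int sink, std::vector<int>& path,
                double min_w, PathAcc& acc, int max_haps, long max_steps) {
  if ((int)acc.haps.size() >= max_haps || acc.steps > max_steps) return;
  acc.steps++;
  if (node == sink && path.size() > 1) {
    std::string h = g.kmer[path[0]];
    for (size_t i = 1; i < path.size(); ++i) h += g.kmer[path[i]].back();
    acc.haps.push_back(h);
    acc.weights.push_back(min_w);
    return;
  }
  // heavier edges first so that the cap keeps high-weight paths
  std::vector<std::array<int, 3> > edges = g.adj[node];
  std::sort(edges.begin(), edges.end(),
            [](const std::array<int, 3>& a, const std::array<int, 3>& b) {
              return a[1] > b[1];
            });
  for (auto& e : edges) {
    path.push_back(e[0]);
    enum_paths(g, e[0], sink, path, std::min(min_w, (double)e[1]), acc,
               max_haps, max_steps);
    path.pop_back();
  }
}

}  // namespace

// [[Rcpp::export(name = ".assemble_region_cpp")]]
List assemble_region_cpp(std::string ref_seg, CharacterVector reads,
                         IntegerVector k_schedule, int prune_weight,
                         int max_haps) {
  int nref = (int)ref_seg.size();
  std::vector<std::string> rd(reads.size());
  for (int i = 0; i < reads.size(); ++i) rd[i] = as<std::string>(reads[i]);

  for (int ki = 0; ki < k_schedule.size(); ++ki) {
    int k = k_schedule[ki];
    if (nref < k + 1) continue;
    // backbone k-mers must be unique for an unambiguous source/sink path
    {
      std::set<std::string> seen;
      bool dup = false;
      for (int p = 0; p + k <= nref; ++p) {
        if (!seen.insert(ref_seg.substr(p, k)).second) { dup = true; break; }
      }
      if (dup) continue;
    }
    Graph g;
    // reference backbone
    int src = g.node(ref_seg.substr(0, k));
    int prev = src;
    for (int p = 1; p + k <= nref; ++p) {
      int v = g.node(ref_seg.substr(p, k));
      g.add_edge(prev, v, 1, true);
      prev = v;
    }
    int sink = prev;
    // read k-mers
    for (const auto& r : rd) {
      int L = (int)r.size();
      if (L < k + 1) continue;
      int u = -1;
      for (int p = 0; p + k <= L; ++p) {
        if (has_non_acgt(r, (size_t)p, (size_t)k)) { u = -1; continue; }
        int v = g.node(r.substr((size_t)p, (size_t)k));
        if (u >= 0) g.add_edge(u, v, 1, false);
        u = v;
      }
    }
    // prune low-weight non-reference edges
    for (auto& edges : g.adj) {
      edges.erase(std::remove_if(edges.begin(), edges.end(),
                                 [&](const std::array<int, 3>& e) {
                                   return e[2] == 0 && e[1] < prune_weight;
                                 }),
                  edges.end());
    }
    if (has_cycle_from(g, src)) continue;
    PathAcc acc;
    std::vector<int> path{src};
    enum_paths(g, src, sink, path, 1e18, acc, max_haps, 500000);
    if (acc.haps.empty()) continue;
    // ensure the reference haplotype itself is present
    bool have_ref = false;
    for (auto& h : acc.haps)
      if (h == ref_seg) { have_ref = true; break; }
    if (!have_ref) {
      if ((int)acc.haps.size() >= max_haps) {
        acc.haps.pop_back();
        acc.weights.pop_back();
      }
      acc.haps.push_back(ref_seg);
      acc.weights.push_back(1.0);
    }
    return List::create(_["haplotypes"] = wrap(acc.haps),
                        _["weights"] = wrap(acc.weights), _["k"] = k,
                        _["degenerate"] = false);
  }
  // every k degenerate: reference haplotype only
  return List::create(_["haplotypes"] = CharacterVector::create(ref_seg),
                      _["weights"] = NumericVector::create(1.0),
                      _["k"] = NA_INTEGER, _["degenerate"] = true);
}
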