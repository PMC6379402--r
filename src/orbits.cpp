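#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Exact graphlet orbit counts (orbits 0-14 of the 2- to 4-node graphlets)
// per node, by ESU enumeration of connected induced subgraphs. Each
// connected induced subgraph of size 3 or 4 is visited exactly once; its
// internal degree sequence identifies the graphlet and each node's orbit.
//
// Orbit numbering (standard 2-4-node catalogue):
//   G0 edge: 0
//   G1 3-path: 1 (end), 2 (middle)
//   G2 triangle: 3
//   G3 4-path: 4 (end), 5 (middle)
//   G4 claw: 6 (leaf), 7 (hub)
//   G5 4-cycle: 8
//   G6 paw (triangle + pendant): 9 (pendant), 10 (triangle, degree 2),
//      11 (attachment, degree 3)
//   G7 diamond: 12 (degree 2), 13 (degree 3)
//   G8 4-clique: 14

class OrbitCounter {
public:
  int n;
  std::vector< std::vector<int> > adj;   // sorted adjacency lists
  IntegerMatrix counts;                  // n x 15
  std::vector<char> blocked;             // in subgraph or adjacent to it
  std::vector<int> sub;                  // current subgraph nodes

  OrbitCounter(int n_) : n(n_), adj(n_), counts(n_, 15), blocked(n_, 0) {}

  bool connected(int u, int v) const {
    const std::vector<int>& a = adj[u];
    return std::binary_search(a.begin(), a.end(), v);
  }

  void record() {
    int k = (int) sub.size();
    int deg[4] = {0, 0, 0, 0};
    int e = 0;
    for (int i = 0; i < k; ++i)
      for (int j = i + 1; j < k; ++j)
        if (connected(sub[i], sub[j])) { ++deg[i]; ++deg[j]; ++e; }
    if (k == 3) {
      if (e == 2) {                       // 3-path
        for (int i = 0; i < k; ++i)
          counts(sub[i], deg[i] == 1 ? 1 : 2)++;
      } else {                            // triangle (e == 3)
        for (int i = 0; i < k; ++i) counts(sub[i], 3)++;
      }
      return;
    }
    // k == 4
    switch (e) {
    case 3: {
      int dmax = std::max(std::max(deg[0], deg[1]), std::max(deg[2], deg[3]));
      if (dmax == 3) {                    // claw
        for (int i = 0; i < k; ++i) counts(sub[i], deg[i] == 3 ? 7 : 6)++;
      } else {                            // 4-path
        for (int i = 0; i < k; ++i) counts(sub[i], deg[i] == 1 ? 4 : 5)++;
      }
      break;
    }
    case 4: {
      int dmax = std::max(std::max(deg[0], deg[1]), std::max(deg[2], deg[3]));
      if (dmax == 2) {                    // 4-cycle
        for (int i = 0; i < k; ++i) counts(sub[i], 8)++;
      } else {                            // paw
        for (int i = 0; i < k; ++i)
          counts(sub[i], deg[i] == 1 ? 9 : (deg[i] == 2 ? 10 : 11))++;
      }
      break;
    }
    case 5:                               // diamond
      for (int i = 0; i < k; ++i) counts(sub[i], deg[i] == 2 ? 12 : 13)++;
      break;
    default:                              // e == 6, 4-clique
      for (int i = 0; i < k; ++i) counts(sub[i], 14)++;
    }
  }

  // ESU extension: ext holds candidate nodes (> root, exclusive neighbors of
  // the current subgraph). Each call may consume ext destructively per branch.
  void extend(std::vector<int>& ext, int root, int target) {
    if ((int) sub.size() == target) { record(); return; }
    while (!ext.empty()) {
      int w = ext.back();
      ext.pop_back();
      // ext' = ext plus exclusive neighbors of w greater than root
      std::vector<int> ext2 = ext;
      std::vector<int> newly;
      for (size_t t = 0; t < adj[w].size(); ++t) {
        int u = adj[w][t];
        if (u > root && !blocked[u]) { ext2.push_back(u); newly.push_back(u); blocked[u] = 1; }
      }
      sub.push_back(w);
      extend(ext2, root, target);
      sub.pop_back();
      for (size_t t = 0; t < newly.size(); ++t) blocked[newly[t]] = 0;
    }
  }

  void run(int target) {
    for (int v = 0; v < n; ++v) {
      std::vector<int> ext;
      blocked[v] = 1;
      for (size_t t = 0; t < adj[v].size(); ++t) {
        int u = adj[v][t];
        if (u > v) { ext.push_back(u); blocked[u] = 1; }
      }
      std::vector<int> ext0 = ext;
      sub.assign(1, v);
      extend(ext0, v, target);
      blocked[v] = 0;
      for (size_t t = 0; t < ext.size(); ++t) blocked[ext[t]] = 0;
    }
  }
};

// [[Rcpp::export(name = ".count_orbits_cpp")]]
IntegerMatrix count_orbits_cpp(IntegerMatrix edges, int n) {
  OrbitCounter oc(n);
  for (int r = 0; r < edges.nrow(); ++r) {
    int u = edges(r, 0), v = edges(r, 1);
    oc.adj[u].push_back(v);
    oc.adj[v].push_back(u);
  }
  for (int v = 0; v < n; ++v) std::sort(oc.adj[v].begin(), oc.adj[v].end());
  // orbit 0 = degree
  for (int v = 0; v < n; ++v) oc.counts(v, 0) = (int) oc.adj[v].size();
  oc.run(3);
  oc.run(4);
  return oc.counts;
}
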