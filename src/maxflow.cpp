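// Boykov-Kolmogorov max-flow / min-cut for grid-structured segmentation
// graphs. Terminal capacities are folded per node (tr_cap = cap(s->p) -
// cap(p->t)); neighbour links are symmetric (capacity c in both directions).
//
// Returns the max-flow value plus the per-node side of the minimum cut
// (true = source side).

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstdint>

using namespace Rcpp;

namespace {

const int TERMINAL = -1; // parent arc id meaning "rooted at a terminal"
const int ORPHAN = -2;

struct BKGraph {
  int n;
  std::vector<double> trCap;          // per-node terminal residual
  std::vector<int> firstArc;          // head of adjacency list (-1 none)
  std::vector<int> nextArc;           // next arc with same tail
  std::vector<int> head;              // arc target node
  std::vector<double> resCap;         // residual capacity of arc
  std::vector<int8_t> tree;           // 0 free, 1 source, 2 sink
  std::vector<int> parent;            // parent arc (into the node), TERMINAL, ORPHAN
  std::vector<int> ts;                // timestamp
  std::vector<int> dist;              // distance to terminal at timestamp
  std::deque<int> active;
  std::deque<int> orphans;
  int time;
  double flow;

  BKGraph(int n_) : n(n_), trCap(n_, 0.0), firstArc(n_, -1),
                    tree(n_, 0), parent(n_, TERMINAL), ts(n_, 0),
                    dist(n_, 0), time(0), flow(0.0) {}

  void addEdge(int u, int v, double cap) {
    int a = head.size();
    head.push_back(v); resCap.push_back(cap);
    nextArc.push_back(firstArc[u]); firstArc[u] = a;
    head.push_back(u); resCap.push_back(cap);
    nextArc.push_back(firstArc[v]); firstArc[v] = a + 1;
  }

  inline int sibling(int a) const { return a ^ 1; }

  void setActive(int p) { active.push_back(p); }

  int nextActive() {
    while (!active.empty()) {
      int p = active.front();
      // lazily discard stale entries: a node may be queued twice
      if (tree[p] != 0) return p;
      active.pop_front();
    }
    return -1;
  }

  // does p have a valid path to its terminal? used during adoption
  bool rootedAtTerminal(int p, int8_t t) {
    int d = 0;
    int q = p;
    while (true) {
      if (ts[q] == time) { d += dist[q]; break; }
      int pa = parent[q];
      if (pa == TERMINAL) { d += 1; break; }
      if (pa == ORPHAN || tree[q] != t) return false;
      q = head[sibling(pa)]; // parent node
      ++d;
    }
    // cache distances along the path
    int q2 = p; int d2 = d;
    while (ts[q2] != time) {
      ts[q2] = time; dist[q2] = d2;
      int pa = parent[q2];
      if (pa == TERMINAL) break;
      q2 = head[sibling(pa)];
      --d2;
    }
    return true;
  }

  void augment(int arc) {
    // path: source tree ... tail(arc) -> head(arc) ... sink tree
    int u = head[sibling(arc)];
    int v = head[arc];
    double bottleneck = resCap[arc];
    for (int p = u;;) {
      int pa = parent[p];
      if (pa == TERMINAL) { bottleneck = std::min(bottleneck, trCap[p]); break; }
      bottleneck = std::min(bottleneck, resCap[pa]);
      p = head[sibling(pa)];
    }
    for (int p = v;;) {
      int pa = parent[p];
      if (pa == TERMINAL) { bottleneck = std::min(bottleneck, -trCap[p]); break; }
      bottleneck = std::min(bottleneck, resCap[sibling(pa)]);
      p = head[sibling(pa)];
    }
    resCap[arc] -= bottleneck;
    resCap[sibling(arc)] += bottleneck;
    for (int p = u;;) {
      int pa = parent[p];
      if (pa == TERMINAL) {
        trCap[p] -= bottleneck;
        if (trCap[p] <= 0) { parent[p] = ORPHAN; orphans.push_back(p); }
        break;
      }
      resCap[pa] -= bottleneck;
      resCap[sibling(pa)] += bottleneck;
      if (resCap[pa] <= 0) { parent[p] = ORPHAN; orphans.push_back(p); }
      p = head[sibling(pa)];
    }
    for (int p = v;;) {
      int pa = parent[p];
      if (pa == TERMINAL) {
        trCap[p] += bottleneck;
        if (trCap[p] >= 0) { parent[p] = ORPHAN; orphans.push_back(p); }
        break;
      }
      resCap[sibling(pa)] -= bottleneck;
      resCap[pa] += bottleneck;
      if (resCap[sibling(pa)] <= 0) { parent[p] = ORPHAN; orphans.push_back(p); }
      p = head[sibling(pa)];
    }
    flow += bottleneck;
  }

  void adopt() {
    while (!orphans.empty()) {
      int p = orphans.front(); orphans.pop_front();
      int8_t t = tree[p];
      int bestArc = -1;
      // look for a new parent: same tree, residual toward p, rooted
      for (int a = firstArc[p]; a != -1; a = nextArc[a]) {
        int q = head[a];
        if (tree[q] != t) continue;
        double rc = (t == 1) ? resCap[sibling(a)] : resCap[a];
        if (rc <= 0) continue;
        if (parent[q] == ORPHAN) continue;
        if (rootedAtTerminal(q, t)) { bestArc = a; break; }
      }
      if (bestArc != -1) {
        parent[p] = sibling(bestArc); // arc from new parent into p
        ts[p] = 0;                    // force re-check next time
        continue;
      }
      // no parent: p leaves the tree; process neighbours
      for (int a = firstArc[p]; a != -1; a = nextArc[a]) {
        int q = head[a];
        if (tree[q] != t) continue;
        double rc = (t == 1) ? resCap[sibling(a)] : resCap[a];
        if (rc > 0) setActive(q);
        if (parent[q] != TERMINAL && parent[q] != ORPHAN &&
            head[sibling(parent[q])] == p) {
          parent[q] = ORPHAN;
          orphans.push_back(q);
        }
      }
      tree[p] = 0;
    }
  }

  double run() {
    for (int p = 0; p < n; ++p) {
      if (trCap[p] > 0) { tree[p] = 1; parent[p] = TERMINAL; setActive(p); }
      else if (trCap[p] < 0) { tree[p] = 2; parent[p] = TERMINAL; setActive(p); }
    }
    ++time;
    while (true) {
      int p = nextActive();
      if (p < 0) break;
      int8_t t = tree[p];
      int boundary = -1;
      for (int a = firstArc[p]; a != -1; a = nextArc[a]) {
        double rc = (t == 1) ? resCap[a] : resCap[sibling(a)];
        if (rc <= 0) continue;
        int q = head[a];
        if (tree[q] == 0) {
          tree[q] = t;
          parent[q] = a; // arc from p into q
          ts[q] = ts[p]; dist[q] = dist[p] + 1;
          setActive(q);
        } else if (tree[q] != t) {
          boundary = (t == 1) ? a : sibling(a); // arc from source side to sink side
          break;
        }
      }
      if (boundary >= 0) {
        // p stays active (may admit more paths)
        augment(boundary);
        ++time;
        adopt();
      } else {
        active.pop_front(); // done with p (it was the front)
        // note: p might not be front if stale entries were dropped; guard:
        // (nextActive always leaves the returned node at the front)
      }
    }
    return flow;
  }
};

} // namespace

// [[Rcpp::export(name = ".bkMaxflow")]]
List bkMaxflow(int n, IntegerVector edgeFrom, IntegerVector edgeTo,
               NumericVector edgeCap, NumericVector srcCap,
               NumericVector snkCap) {
  BKGraph g(n);
  double base = 0.0;
  for (int p = 0; p < n; ++p) {
    double s = srcCap[p], t = snkCap[p];
    base += std::min(s, t);
    g.trCap[p] = s - t;
  }
  int m = edgeFrom.size();
  for (int i = 0; i < m; ++i) {
    if (edgeCap[i] > 0) g.addEdge(edgeFrom[i], edgeTo[i], edgeCap[i]);
  }
  double f = g.run() + base;
  LogicalVector sourceSide(n);
  for (int p = 0; p < n; ++p) sourceSide[p] = (g.tree[p] == 1);
  return List::create(_["flow"] = f, _["sourceSide"] = sourceSide);
}
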