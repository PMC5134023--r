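#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact, centre-anchored maximum common induced subgraph between two small
// neighbourhood graphs, found by depth-first branch and bound.
//
// The mapping grows outward from the anchored pair: a node pair (u, v) may
// only join if some already-mapped pair (a, b) has the edge u-a in graph 1
// AND v-b in graph 2, so the common subgraph stays connected. Induced
// consistency is enforced: for every mapped pair (a, b), u-a is an edge of
// graph 1 exactly when v-b is an edge of graph 2.
//
// Because the graphs are planar embeddings of physical cell packings, the
// counter-clockwise cyclic order of a cell's neighbours is meaningful and
// is preserved between frames (tissues deform but do not mirror). ord1 and
// ord2 give each node's neighbours in CCW order; a pair is only admitted
// if, around every affected cell, the cyclic order of mapped neighbours
// matches the cyclic order of their images.
//
// fixed1[u] / fixed2[v] encode consistency with an enclosing global
// tracking: 0 = unconstrained, -1 = the node may not be mapped at all,
// k > 0 = the node may only be mapped to node k of the other graph.
//
// When requireFull is true the search only accepts mappings that cover all
// of graph 1 (a centre-anchored induced isomorphism test); exclusion
// branches are skipped, which makes the test fast.

namespace {

struct Solver {
    int n1, n2;
    std::vector<std::vector<char> > A1, A2;
    std::vector<std::vector<int> > adjL1, adjL2; // neighbour lists
    std::vector<std::vector<int> > ord1, ord2;   // CCW neighbour order
    std::vector<std::vector<int> > rank1, rank2; // rank of x around a, -1
    std::vector<int> fixed1, fixed2;
    std::vector<double> dist; // n1 x n2, column-major; empty => no cutoff
    double dmax;
    bool useDist;
    bool requireFull;
    std::vector<int> map1, map2; // 0 = unmapped, otherwise 1-based partner
    std::vector<char> dead;     // branch-local exclusions in graph 1
    std::vector<int> best;
    int bestSize, curSize, free2;
    long nodesLeft; // expansion budget safeguard
    bool done;

    // cyclic order of a's mapped neighbours (optionally pretending that
    // (u, v) is mapped) must agree with the order of their images around
    // a's partner
    bool cyclicOK(int a, int b, int u, int v) const {
        int rs[64];
        int m = 0;
        const std::vector<int> &oa = ord1[a];
        for (size_t k = 0; k < oa.size() && m < 64; ++k) {
            int x = oa[k];
            int y = (x == u) ? v + 1 : map1[x];
            if (y == 0) continue;
            int s = rank2[b][y - 1];
            if (s < 0) continue; // image not adjacent to b (non-edge pair)
            rs[m++] = s;
        }
        if (m < 3) return true;
        int descents = 0;
        for (int k = 0; k < m; ++k) {
            if (rs[(k + 1) % m] < rs[k] && ++descents > 1) return false;
        }
        return true;
    }

    // induced consistency reduces to: every mapped neighbour of u has its
    // image adjacent to v, and every mapped neighbour of v has its
    // preimage adjacent to u (mapped non-neighbours then pair up
    // automatically); connectivity needs at least one mapped neighbour
    bool admissible(int u, int v) const {
        if (fixed1[u] != 0 && fixed1[u] != v + 1) return false;
        if (fixed2[v] != 0 && fixed2[v] != u + 1) return false;
        if (useDist && dist[u + n1 * v] > dmax) return false;
        bool connected = false;
        const std::vector<int> &nu = adjL1[u];
        for (size_t k = 0; k < nu.size(); ++k) {
            int b = map1[nu[k]];
            if (b == 0) continue;
            if (!A2[v][b - 1]) return false;
            connected = true;
        }
        const std::vector<int> &nv = adjL2[v];
        for (size_t k = 0; k < nv.size(); ++k) {
            int a = map2[nv[k]];
            if (a != 0 && !A1[u][a - 1]) return false;
        }
        if (!connected && curSize > 0) return false;
        // planar orientation: around u itself and around every mapped
        // neighbour of u
        if (!cyclicOK(u, v, u, v)) return false;
        for (size_t k = 0; k < ord1[u].size(); ++k) {
            int a = ord1[u][k];
            if (map1[a] != 0 && !cyclicOK(a, map1[a] - 1, u, v))
                return false;
        }
        return true;
    }

    void search() {
        if (done || --nodesLeft < 0) { done = true; return; }
        // branching node: smallest-index free, non-dead graph-1 node
        // adjacent to the mapped set
        // branching node and bound: only free nodes reachable from the
        // mapped set through free nodes can ever join the mapping
        int u = -1;
        int avail = 0;
        {
            char seen[64];
            int stack[64];
            int top = 0;
            for (int i = 0; i < n1; ++i) seen[i] = 0;
            for (int i = 0; i < n1; ++i) {
                if (map1[i] == 0) continue;
                const std::vector<int> &ni = adjL1[i];
                for (size_t k = 0; k < ni.size(); ++k) {
                    int j = ni[k];
                    if (map1[j] == 0 && !seen[j]) {
                        seen[j] = 1;
                        if (!dead[j] && fixed1[j] != -1) {
                            if (u < 0 || j < u) u = j;
                            stack[top++] = j;
                            ++avail;
                        }
                    }
                }
            }
            while (top > 0) {
                int i = stack[--top];
                const std::vector<int> &ni = adjL1[i];
                for (size_t k = 0; k < ni.size(); ++k) {
                    int j = ni[k];
                    if (map1[j] == 0 && !seen[j]) {
                        seen[j] = 1;
                        if (!dead[j] && fixed1[j] != -1) {
                            stack[top++] = j;
                            ++avail;
                        }
                    }
                }
            }
        }
        if (u < 0) {
            if (curSize > bestSize) {
                bestSize = curSize;
                best = map1;
                if (bestSize >= n1 || bestSize >= n2) done = true;
            }
            return;
        }
        int bound = curSize + (avail < free2 ? avail : free2);
        if (bound <= bestSize) return;
        for (int v = 0; v < n2 && !done; ++v) {
            if (map2[v] != 0 || !admissible(u, v)) continue;
            map1[u] = v + 1; map2[v] = u + 1;
            ++curSize; --free2;
            if (curSize > bestSize) {
                bestSize = curSize;
                best = map1;
                if (bestSize >= n1 || bestSize >= n2) done = true;
            }
            if (!done) search();
            map1[u] = 0; map2[v] = 0;
            --curSize; ++free2;
        }
        if (done || requireFull) return;
        dead[u] = 1;
        search();
        dead[u] = 0;
    }
};

} // namespace

// [[Rcpp::export(name = ".localMCSCpp")]]
IntegerVector local_mcs_cpp(List adj1, List adj2, int anchor1, int anchor2,
                            IntegerVector fixed1, IntegerVector fixed2,
                            NumericMatrix dist, double dmax,
                            List ord1, List ord2,
                            bool requireFull = false,
                            double nodeBudget = 5e6) {
    Solver s;
    s.n1 = adj1.size();
    s.n2 = adj2.size();
    if (s.n1 > 64 || s.n2 > 64)
        stop("neighbourhood graphs larger than 64 nodes are not supported");
    s.A1.assign(s.n1, std::vector<char>(s.n1, 0));
    s.A2.assign(s.n2, std::vector<char>(s.n2, 0));
    s.adjL1.resize(s.n1);
    s.adjL2.resize(s.n2);
    for (int i = 0; i < s.n1; ++i) {
        IntegerVector nb = adj1[i];
        for (int k = 0; k < nb.size(); ++k) {
            s.A1[i][nb[k] - 1] = 1;
            s.adjL1[i].push_back(nb[k] - 1);
        }
    }
    for (int i = 0; i < s.n2; ++i) {
        IntegerVector nb = adj2[i];
        for (int k = 0; k < nb.size(); ++k) {
            s.A2[i][nb[k] - 1] = 1;
            s.adjL2[i].push_back(nb[k] - 1);
        }
    }
    s.ord1.resize(s.n1);
    s.rank1.assign(s.n1, std::vector<int>(s.n1, -1));
    for (int i = 0; i < s.n1; ++i) {
        IntegerVector o = ord1[i];
        for (int k = 0; k < o.size(); ++k) {
            s.ord1[i].push_back(o[k] - 1);
            s.rank1[i][o[k] - 1] = k;
        }
    }
    s.ord2.resize(s.n2);
    s.rank2.assign(s.n2, std::vector<int>(s.n2, -1));
    for (int i = 0; i < s.n2; ++i) {
        IntegerVector o = ord2[i];
        for (int k = 0; k < o.size(); ++k) {
            s.ord2[i].push_back(o[k] - 1);
            s.rank2[i][o[k] - 1] = k;
        }
    }
    s.fixed1.assign(fixed1.begin(), fixed1.end());
    s.fixed2.assign(fixed2.begin(), fixed2.end());
    s.useDist = dist.nrow() == s.n1 && dist.ncol() == s.n2 && s.n1 > 0;
    if (s.useDist)
        s.dist.assign(dist.begin(), dist.end());
    s.dmax = dmax;
    s.requireFull = requireFull;
    s.map1.assign(s.n1, 0);
    s.map2.assign(s.n2, 0);
    s.dead.assign(s.n1, 0);
    s.best.assign(s.n1, 0);
    s.bestSize = 0;
    s.curSize = 0;
    s.free2 = s.n2;
    s.nodesLeft = (long) nodeBudget;
    s.done = false;

    int a1 = anchor1 - 1, a2 = anchor2 - 1;
    if (a1 < 0 || a1 >= s.n1 || a2 < 0 || a2 >= s.n2)
        stop("anchor out of range");
    if (!s.admissible(a1, a2))
        return IntegerVector(s.n1, 0); // anchors incompatible
    s.map1[a1] = a2 + 1;
    s.map2[a2] = a1 + 1;
    s.curSize = 1;
    --s.free2;
    s.bestSize = 1;
    s.best = s.map1;
    s.search();

    return IntegerVector(s.best.begin(), s.best.end());
}
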