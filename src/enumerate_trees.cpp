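#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive search over rooted labeled trees on n nodes (node 0 = root).
// Every parent vector p[1..n-1] with p[i] in {0..n-1}\{i} is tested for
// acyclicity; valid trees are scored by (a) the number of parent-child pairs
// violating the precedence relation and (b) the number of (node, region)
// pairs where the children's prevalences sum above the parent's plus a
// tolerance. All minimal-cost trees are returned (up to maxTrees).

static bool acyclic(const std::vector<int>& par, int n,
                    std::vector<int>& stamp, int tag) {
    for (int s = 1; s < n; ++s) {
        int cur = s;
        int steps = 0;
        while (cur != 0) {
            if (stamp[cur] == tag) break;      // already verified this pass
            if (++steps > n) return false;     // cycle
            cur = par[cur];
        }
        // mark the path as verified
        cur = s;
        while (cur != 0 && stamp[cur] != tag) {
            stamp[cur] = tag;
            cur = par[cur];
        }
    }
    return true;
}

// [[Rcpp::export(name = ".enumerateTreesCpp")]]
List enumerateTreesCpp(NumericMatrix prev, LogicalMatrix mayParent,
                       double sumTol, int maxTrees) {
    const int n = prev.nrow();
    const int R = prev.ncol();
    if (n < 2)
        stop("need at least the root and one cluster");
    std::vector<int> par(n, -1);
    std::vector<int> stamp(n, -1);
    std::vector<double> childSum(R);
    int bestCost = INT_MAX;
    std::vector<std::vector<int>> best;
    std::vector<std::pair<int,int>> bestParts;
    bool truncated = false;

    // odometer over parent assignments of nodes 1..n-1
    std::vector<int> idx(n, 0);
    for (int i = 1; i < n; ++i) {
        par[i] = (idx[i] == i) ? ++idx[i] : idx[i]; // skip self
    }
    int tag = 0;
    while (true) {
        ++tag;
        if (acyclic(par, n, stamp, tag)) {
            int costPrec = 0;
            for (int c = 1; c < n; ++c)
                if (!mayParent(par[c], c)) ++costPrec;
            int costSum = 0;
            for (int u = 0; u < n; ++u) {
                bool hasChild = false;
                for (int r = 0; r < R; ++r) childSum[r] = 0.0;
                for (int c = 1; c < n; ++c)
                    if (par[c] == u) {
                        hasChild = true;
                        for (int r = 0; r < R; ++r)
                            childSum[r] += prev(c, r);
                    }
                if (hasChild)
                    for (int r = 0; r < R; ++r)
                        if (childSum[r] > prev(u, r) + sumTol) ++costSum;
            }
            int cost = costPrec + costSum;
            if (cost < bestCost) {
                bestCost = cost;
                best.clear();
                bestParts.clear();
                truncated = false;
            }
            if (cost == bestCost) {
                if ((int)best.size() < maxTrees) {
                    best.push_back(par);
                    bestParts.push_back(std::make_pair(costPrec, costSum));
                } else {
                    truncated = true;
                }
            }
        }
        // advance odometer (lexicographic over nodes 1..n-1)
        int i = n - 1;
        for (; i >= 1; --i) {
            int v = par[i] + 1;
            if (v == i) ++v;     // skip self
            if (v < n) { par[i] = v; break; }
            par[i] = (i == 0) ? 1 : 0;  // reset (0 is valid unless i==0)
        }
        if (i == 0) break;
    }

    IntegerMatrix parents(best.size(), n);
    IntegerVector cp(best.size()), cs(best.size());
    for (size_t t = 0; t < best.size(); ++t) {
        for (int j = 0; j < n; ++j) parents(t, j) = best[t][j];
        cp[t] = bestParts[t].first;
        cs[t] = bestParts[t].second;
    }
    return List::create(_["parents"] = parents, _["cost"] = bestCost,
                        _["costPrecedence"] = cp, _["costSumRule"] = cs,
                        _["truncated"] = truncated);
}
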