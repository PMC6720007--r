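#include <Rcpp.h>
#include <vector>
#include <queue>

using namespace Rcpp;

// Exact betweenness centrality of an undirected, unweighted simple graph
// (Brandes' accumulation). Endpoints are excluded and pair contributions
// are split evenly across equal-length shortest paths. Each unordered pair
// is counted once (dependencies from single-source accumulations are
// halved). `edges` holds 0-based endpoints, one edge per row.
// [[Rcpp::export]]
NumericVector brandes_betweenness(int n, IntegerMatrix edges) {
    int m = edges.nrow();
    // CSR adjacency
    std::vector<int> deg(n, 0);
    for (int e = 0; e < m; ++e) {
        ++deg[edges(e, 0)];
        ++deg[edges(e, 1)];
    }
    std::vector<int> start(n + 1, 0);
    for (int v = 0; v < n; ++v) start[v + 1] = start[v] + deg[v];
    std::vector<int> adj(2 * (size_t)m);
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int e = 0; e < m; ++e) {
        int a = edges(e, 0), b = edges(e, 1);
        adj[fill[a]++] = b;
        adj[fill[b]++] = a;
    }

    NumericVector bc(n);
    std::vector<int> dist(n), order;
    std::vector<double> sigma(n), delta(n);
    order.reserve(n);

    for (int s = 0; s < n; ++s) {
        std::fill(dist.begin(), dist.end(), -1);
        std::fill(sigma.begin(), sigma.end(), 0.0);
        std::fill(delta.begin(), delta.end(), 0.0);
        order.clear();
        dist[s] = 0;
        sigma[s] = 1.0;
        std::queue<int> q;
        q.push(s);
        while (!q.empty()) {
            int v = q.front(); q.pop();
            order.push_back(v);
            for (int i = start[v]; i < start[v + 1]; ++i) {
                int w = adj[i];
                if (dist[w] < 0) {
                    dist[w] = dist[v] + 1;
                    q.push(w);
                }
                if (dist[w] == dist[v] + 1) sigma[w] += sigma[v];
            }
        }
        // accumulate dependencies in reverse BFS order
        for (int i = (int)order.size() - 1; i > 0; --i) {
            int w = order[i];
            for (int j = start[w]; j < start[w + 1]; ++j) {
                int v = adj[j];
                if (dist[v] == dist[w] - 1)
                    delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
            }
            if (w != s) bc[w] += delta[w] / 2.0;  // each pair counted twice
        }
    }
    return bc;
}
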