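#include <Rcpp.h>
#include <queue>
#include <deque>
#include <climits>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact min-cost flow by successive shortest paths with node potentials.
// Arc costs may be negative, but the input graph must be free of negative
// cycles (association networks are DAGs between a source and a sink, so this
// holds by construction). Initial potentials come from SPFA; subsequent
// searches are Dijkstra on reduced costs.

struct Arc {
  int head;
  int cap;
  double cost;
  int rev; // index of reverse arc in adj[head]
};

// [[Rcpp::export(name = ".mcf_solve")]]
List mcf_solve(int n, IntegerVector tail, IntegerVector head,
               IntegerVector cap, NumericVector cost,
               int s, int t, bool stop_nonneg, double max_units) {
  const int m = tail.size();
  std::vector<std::vector<Arc> > adj(n);
  std::vector<int> arc_node(m), arc_idx(m);
  for (int i = 0; i < m; ++i) {
    int u = tail[i] - 1, v = head[i] - 1;
    Arc f; f.head = v; f.cap = cap[i]; f.cost = cost[i];
    Arc b; b.head = u; b.cap = 0;      b.cost = -cost[i];
    f.rev = (int)adj[v].size() + (u == v ? 1 : 0);
    b.rev = (int)adj[u].size();
    arc_node[i] = u; arc_idx[i] = (int)adj[u].size();
    adj[u].push_back(f);
    adj[v].push_back(b);
  }
  --s; --t;

  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> pi(n, 0.0), dist(n);
  std::vector<int> pv(n), pe(n);
  std::vector<bool> inq(n, false);

  // SPFA for initial potentials (handles negative costs)
  {
    std::vector<double> d(n, INF);
    std::deque<int> q;
    d[s] = 0; q.push_back(s); inq[s] = true;
    while (!q.empty()) {
      int u = q.front(); q.pop_front(); inq[u] = false;
      for (size_t k = 0; k < adj[u].size(); ++k) {
        const Arc &a = adj[u][k];
        if (a.cap > 0 && d[u] + a.cost < d[a.head] - 1e-12) {
          d[a.head] = d[u] + a.cost;
          if (!inq[a.head]) { q.push_back(a.head); inq[a.head] = true; }
        }
      }
    }
    for (int v = 0; v < n; ++v) pi[v] = (d[v] == INF ? 0.0 : d[v]);
  }

  double total_cost = 0.0, sent = 0.0;
  typedef std::pair<double, int> PD;

  while (sent < max_units) {
    // Dijkstra with reduced costs
    std::fill(dist.begin(), dist.end(), INF);
    std::priority_queue<PD, std::vector<PD>, std::greater<PD> > pq;
    dist[s] = 0.0; pq.push(PD(0.0, s));
    while (!pq.empty()) {
      PD top = pq.top(); pq.pop();
      int u = top.second;
      if (top.first > dist[u] + 1e-12) continue;
      for (size_t k = 0; k < adj[u].size(); ++k) {
        const Arc &a = adj[u][k];
        if (a.cap <= 0) continue;
        double rc = a.cost + pi[u] - pi[a.head];
        if (rc < 0 && rc > -1e-9) rc = 0; // guard fp noise
        double nd = dist[u] + rc;
        if (nd < dist[a.head] - 1e-12) {
          dist[a.head] = nd;
          pv[a.head] = u; pe[a.head] = (int)k;
          pq.push(PD(nd, a.head));
        }
      }
    }
    if (dist[t] == INF) break;
    double path_cost = dist[t] + pi[t] - pi[s];
    if (stop_nonneg && path_cost > -1e-9) break;

    // bottleneck
    int bn = INT_MAX;
    for (int v = t; v != s; v = pv[v]) {
      const Arc &a = adj[pv[v]][pe[v]];
      if (a.cap < bn) bn = a.cap;
    }
    double room = max_units - sent;
    if ((double)bn > room) bn = (int)room;
    if (bn <= 0) break;
    for (int v = t; v != s; v = pv[v]) {
      Arc &a = adj[pv[v]][pe[v]];
      a.cap -= bn;
      adj[v][a.rev].cap += bn;
    }
    sent += bn;
    total_cost += path_cost * bn;
    // potential update (only reached nodes; clamp with dist[t])
    double dt = dist[t];
    for (int v = 0; v < n; ++v)
      pi[v] += (dist[v] < dt ? dist[v] : dt);
  }

  IntegerVector flow(m);
  for (int i = 0; i < m; ++i) {
    const Arc &a = adj[arc_node[i]][arc_idx[i]];
    flow[i] = cap[i] - a.cap;
  }
  return List::create(_["flow"] = flow,
                      _["total_cost"] = total_cost,
                      _["units"] = sent);
}

// Eigenvalues of many symmetric 3x3 matrices (analytic, trigonometric form),
// returning the bright-blob score prod(max(0, -lambda_i)) per matrix.
// [[Rcpp::export(name = ".blob_score_sym3")]]
NumericVector blob_score_sym3(NumericVector a11, NumericVector a22, NumericVector a33,
                              NumericVector a12, NumericVector a13, NumericVector a23) {
  const int n = a11.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p1 = a12[i]*a12[i] + a13[i]*a13[i] + a23[i]*a23[i];
    double l1, l2, l3;
    if (p1 < 1e-300) {
      l1 = a11[i]; l2 = a22[i]; l3 = a33[i];
    } else {
      double q = (a11[i] + a22[i] + a33[i]) / 3.0;
      double b11 = a11[i] - q, b22 = a22[i] - q, b33 = a33[i] - q;
      double p2 = b11*b11 + b22*b22 + b33*b33 + 2.0*p1;
      double p = std::sqrt(p2 / 6.0);
      // det(B/p)/2
      double c11 = b11/p, c22 = b22/p, c33 = b33/p;
      double c12 = a12[i]/p, c13 = a13[i]/p, c23 = a23[i]/p;
      double detB = c11*(c22*c33 - c23*c23) - c12*(c12*c33 - c23*c13)
                  + c13*(c12*c23 - c22*c13);
      double r = detB / 2.0;
      if (r < -1.0) r = -1.0; else if (r > 1.0) r = 1.0;
      double phi = std::acos(r) / 3.0;
      l1 = q + 2.0*p*std::cos(phi);
      l3 = q + 2.0*p*std::cos(phi + 2.0*M_PI/3.0);
      l2 = 3.0*q - l1 - l3;
    }
    double s1 = l1 < 0 ? -l1 : 0.0;
    double s2 = l2 < 0 ? -l2 : 0.0;
    double s3 = l3 < 0 ? -l3 : 0.0;
    out[i] = s1 * s2 * s3;
  }
  return out;
}
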