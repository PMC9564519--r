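#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Time-dependent shortest-time path with frozen per-edge speeds: the speed
// of an edge is chosen by the clock time at which the ambulance ENTERS the
// edge (rush-hour vs off-peak), and held for the whole traversal.  Label
// setting on arrival times; exact whenever the travel-time field is FIFO,
// which holds everywhere except in the minutes just before a rush window
// closes (a vehicle entering a long edge right before the window ends keeps
// the rush speed).  Road networks here are small, so the simple O(n^2)
// extraction loop is fine.

namespace {

inline bool in_rush(double t_min, const NumericMatrix &win) {
  double tod = t_min - 1440.0 * std::floor(t_min / 1440.0);
  for (int k = 0; k < win.nrow(); ++k)
    if (tod >= win(k, 0) && tod < win(k, 1)) return true;
  return false;
}

} // namespace

// from/to: 0-based endpoints; undirected edges are expanded by the caller.
// sp_off/sp_rush: km/h for the routing context (priority already folded in).
// Returns arrival times, parent nodes and parent edge ids for path recovery.
// [[Rcpp::export]]
List tdsp_cpp(int n_nodes, IntegerVector from, IntegerVector to,
              NumericVector len, NumericVector sp_off, NumericVector sp_rush,
              NumericMatrix rush_win, int origin, double depart) {
  int m = from.size();
  std::vector<std::vector<int> > out_edges(n_nodes);
  for (int e = 0; e < m; ++e) out_edges[from[e]].push_back(e);

  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> arr(n_nodes, inf);
  std::vector<int> parent(n_nodes, -1), pedge(n_nodes, -1);
  std::vector<bool> done(n_nodes, false);
  arr[origin] = depart;

  for (int iter = 0; iter < n_nodes; ++iter) {
    int u = -1;
    double bestt = inf;
    for (int v = 0; v < n_nodes; ++v)
      if (!done[v] && arr[v] < bestt) { bestt = arr[v]; u = v; }
    if (u < 0) break;
    done[u] = true;
    double tu = arr[u];
    for (size_t i = 0; i < out_edges[u].size(); ++i) {
      int e = out_edges[u][i];
      int v = to[e];
      if (done[v]) continue;
      double sp = in_rush(tu, rush_win) ? sp_rush[e] : sp_off[e];
      double tt = len[e] / sp * 60.0;
      double cand = tu + tt;
      if (cand < arr[v] ||
          (cand == arr[v] && parent[v] >= 0 && u < parent[v])) {
        arr[v] = cand;
        parent[v] = u;
        pedge[v] = e;
      }
    }
  }

  return List::create(_["arrival"] = NumericVector(arr.begin(), arr.end()),
                      _["parent"] = IntegerVector(parent.begin(), parent.end()),
                      _["pedge"] = IntegerVector(pedge.begin(), pedge.end()));
}
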