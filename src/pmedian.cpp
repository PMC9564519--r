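#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact branch-and-bound for the site-selection form of the p-median
// problem.  Under the uncapacitated assumption every optimal assignment is
// nearest-open, so the MIP (binary location + assignment variables)
// collapses to: choose `pick` rows of t out of `pool`, on top of the
// `forced` rows, minimising sum_j b_j * min_{i open} t[i, j], subject to at
// least `min_keep` of the chosen rows being flagged in `is_cur` (the
// relocation budget at municipality granularity).
//
// Candidates are explored in id order with the include-branch first and a
// strict improvement rule, so the reported optimum is the lexicographically
// smallest optimal site set (deterministic tie-break by lowest id).
// The bound sum_j b_j * min(curmin_j, sufmin[k][j]) is admissible: no
// completion using candidates k..n-1 can beat it.

namespace {

struct BB {
  const NumericMatrix &t;
  const NumericVector &b;
  const std::vector<int> &pool;     // 0-based rows, ascending id order
  const std::vector<bool> &is_cur;
  int pick, min_keep, nJ, npool;
  std::vector<double> curmin;       // best time per zone over forced+chosen
  std::vector<double> sufmin;       // (npool+1) x nJ suffix minima over pool
  std::vector<int> sufcur;          // # current-site candidates in pool[k..]
  std::vector<int> chosen, best_set;
  double best;

  BB(const NumericMatrix &t_, const NumericVector &b_,
     const std::vector<int> &pool_, const std::vector<bool> &cur_,
     int pick_, int min_keep_, const std::vector<double> &base_min)
      : t(t_), b(b_), pool(pool_), is_cur(cur_), pick(pick_),
        min_keep(min_keep_), nJ(t_.ncol()), npool((int)pool_.size()),
        curmin(base_min), best(std::numeric_limits<double>::infinity()) {
    sufmin.assign((size_t)(npool + 1) * nJ,
                  std::numeric_limits<double>::infinity());
    sufcur.assign(npool + 1, 0);
    for (int k = npool - 1; k >= 0; --k) {
      int row = pool[k];
      for (int j = 0; j < nJ; ++j) {
        double lower = sufmin[(size_t)(k + 1) * nJ + j];
        double v = t(row, j);
        sufmin[(size_t)k * nJ + j] = v < lower ? v : lower;
      }
      sufcur[k] = sufcur[k + 1] + (is_cur[k] ? 1 : 0);
    }
  }

  double bound(int k) const {
    double s = 0.0;
    const double *suf = &sufmin[(size_t)k * nJ];
    for (int j = 0; j < nJ; ++j) {
      double m = curmin[j] < suf[j] ? curmin[j] : suf[j];
      s += b[j] * m;
    }
    return s;
  }

  double leaf_cost() const {
    double s = 0.0;
    for (int j = 0; j < nJ; ++j) s += b[j] * curmin[j];
    return s;
  }

  void dfs(int k, int picked, int curpicked) {
    int remaining = pick - picked;
    if (remaining == 0) {
      if (curpicked < min_keep) return;
      double c = leaf_cost();
      if (c < best) { best = c; best_set = chosen; }
      return;
    }
    if (k >= npool || npool - k < remaining) return;
    int cur_left = sufcur[k];
    int can_cur = remaining < cur_left ? remaining : cur_left;
    if (curpicked + can_cur < min_keep) return;
    if (bound(k) >= best) return;

    // include pool[k]
    int row = pool[k];
    std::vector<std::pair<int, double> > undo;
    for (int j = 0; j < nJ; ++j) {
      double v = t(row, j);
      if (v < curmin[j]) { undo.push_back(std::make_pair(j, curmin[j])); curmin[j] = v; }
    }
    chosen.push_back(row);
    dfs(k + 1, picked + 1, curpicked + (is_cur[k] ? 1 : 0));
    chosen.pop_back();
    for (size_t u = 0; u < undo.size(); ++u) curmin[undo[u].first] = undo[u].second;

    // exclude pool[k]
    dfs(k + 1, picked, curpicked);
  }
};

} // namespace

// [[Rcpp::export]]
List pmedian_bb_cpp(NumericMatrix t, NumericVector b, IntegerVector forced,
                    IntegerVector pool, LogicalVector pool_is_current,
                    int pick, int min_keep) {
  int nJ = t.ncol();
  std::vector<double> base(nJ, std::numeric_limits<double>::infinity());
  for (int f = 0; f < forced.size(); ++f) {
    int row = forced[f];
    for (int j = 0; j < nJ; ++j)
      if (t(row, j) < base[j]) base[j] = t(row, j);
  }
  std::vector<int> pv(pool.begin(), pool.end());
  std::vector<bool> cv(pool_is_current.size());
  for (int k = 0; k < pool_is_current.size(); ++k) cv[k] = pool_is_current[k];

  if (pick == 0) {
    double c = 0.0;
    bool finite = true;
    for (int j = 0; j < nJ; ++j) {
      if (!R_FINITE(base[j])) { finite = false; break; }
      c += b[j] * base[j];
    }
    if (!finite || 0 < min_keep)
      return List::create(_["feasible"] = false);
    return List::create(_["feasible"] = true,
                        _["objective"] = c,
                        _["chosen"] = IntegerVector(0));
  }

  BB bb(t, b, pv, cv, pick, min_keep, base);
  bb.dfs(0, 0, 0);
  if (!R_FINITE(bb.best))
    return List::create(_["feasible"] = false);
  IntegerVector ch(bb.best_set.begin(), bb.best_set.end());
  return List::create(_["feasible"] = true,
                      _["objective"] = bb.best,
                      _["chosen"] = ch);
}
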