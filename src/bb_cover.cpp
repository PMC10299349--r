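#include <Rcpp.h>
#include <algorithm>
#include <chrono>
#include <vector>

using namespace Rcpp;

// Exact branch-and-bound for the weighted partial set multi-cover:
//   minimize    sum_g w[g] * z[g]
//   subject to  at least n_required cells c with sum_g z[g] * u[g][c] >= d
// with z binary and w >= 0. Genes must be passed sorted by ascending weight;
// the search dives include-first in that order, so the first leaf is the
// cheap-genes-first heuristic solution. Pruning combines
//  (a) a fractional-knapsack bound on the coverage units still needed by the
//      n_required easiest-to-finish coverable cells, and
//  (b) a cardinality bound: any covered cell expresses >= d selected genes,
//      so the panel holds >= d genes.
// Forced genes (nested expansion) are committed before the search starts.

namespace {

struct Problem {
  int n_cells, n_genes, d, n_required;
  int base_count = 0;                  // forced genes already in the panel
  std::vector<double> w;               // ascending
  std::vector<std::vector<int>> cells; // cells[g] = cell indices covered by g
  double node_limit, time_limit;
};

struct Search {
  const Problem* P;
  std::vector<int> depth;      // accumulated depth per cell
  std::vector<int> suffcov;    // suffix coverage count per cell (maintained)
  std::vector<char> selected;
  std::vector<char> best_sel;
  double cur_w = 0.0, best_w = R_PosInf;
  bool have_incumbent = false, truncated = false;
  double nodes = 0.0;
  std::chrono::steady_clock::time_point t0;
  std::vector<int> deficit_buf; // scratch

  bool out_of_budget() {
    if (nodes > P->node_limit) return true;
    if ((static_cast<long long>(nodes) & 1023) == 0) {
      double el = std::chrono::duration<double>(
          std::chrono::steady_clock::now() - t0).count();
      if (el > P->time_limit) return true;
    }
    return false;
  }

  // Lower bound on additional weight from genes idx.. given current depths.
  // Returns R_PosInf when infeasible from here. Also reports whether the
  // current selection is already feasible.
  double bound(int idx, bool& feasible_now) {
    const Problem& P_ = *P;
    int coverable = 0, covered = 0;
    deficit_buf.clear();
    for (int c = 0; c < P_.n_cells; ++c) {
      int def = P_.d - depth[c];
      if (def <= 0) { ++covered; ++coverable; continue; }
      if (depth[c] + suffcov[c] >= P_.d) { ++coverable; deficit_buf.push_back(def); }
    }
    feasible_now = covered >= P_.n_required;
    if (feasible_now) return 0.0;
    if (coverable < P_.n_required) return R_PosInf;
    int need_cells = P_.n_required - covered;
    std::partial_sort(deficit_buf.begin(), deficit_buf.begin() + need_cells,
                      deficit_buf.end());
    long long T = 0;
    for (int i = 0; i < need_cells; ++i) T += deficit_buf[i];
    // capacity of each remaining gene = #deficit coverable cells it touches
    std::vector<std::pair<double, int>> items; // (weight, cap)
    items.reserve(P_.n_genes - idx);
    for (int g = idx; g < P_.n_genes; ++g) {
      int cap = 0;
      for (int c : P_.cells[g])
        if (depth[c] < P_.d && depth[c] + suffcov[c] >= P_.d) ++cap;
      if (cap > 0) items.push_back({P_.w[g], cap});
    }
    std::sort(items.begin(), items.end(),
              [](const std::pair<double, int>& a,
                 const std::pair<double, int>& b) {
                return a.first * b.second < b.first * a.second;
              });
    double lb = 0.0;
    long long got = 0;
    for (auto& it : items) {
      if (got + it.second >= T) {
        lb += it.first * static_cast<double>(T - got) / it.second;
        got = T;
        break;
      }
      got += it.second;
      lb += it.first;
    }
    if (got < T) return R_PosInf;
    // cardinality bound: panel needs >= d genes in total
    int sel_count = P_.base_count;
    for (int g = 0; g < P_.n_genes; ++g) sel_count += selected[g];
    if (sel_count < P_.d) {
      double lb2 = 0.0;
      int need = std::min(P_.d - sel_count, P_.n_genes - idx);
      if (P_.d - sel_count > P_.n_genes - idx) return R_PosInf;
      for (int g = idx; g < idx + need; ++g) lb2 += P_.w[g];
      lb = std::max(lb, lb2);
    }
    return lb;
  }

  void dfs(int idx) {
    nodes += 1.0;
    if (out_of_budget()) { truncated = true; return; }
    bool feasible_now = false;
    double lb = bound(idx, feasible_now);
    if (feasible_now) {
      if (cur_w < best_w - 1e-12) {
        best_w = cur_w;
        best_sel = selected;
        have_incumbent = true;
      }
      return; // adding more genes cannot reduce the objective (w >= 0)
    }
    if (!R_finite(lb)) return;
    if (cur_w + lb >= best_w - 1e-9) return;
    if (idx >= P->n_genes) return;
    // include branch (only useful if the gene covers some deficit cell)
    bool useful = false;
    for (int c : P->cells[idx])
      if (depth[c] < P->d && depth[c] + suffcov[c] >= P->d) { useful = true; break; }
    for (int c : P->cells[idx]) --suffcov[c];
    if (useful) {
      selected[idx] = 1;
      cur_w += P->w[idx];
      for (int c : P->cells[idx]) ++depth[c];
      dfs(idx + 1);
      for (int c : P->cells[idx]) --depth[c];
      cur_w -= P->w[idx];
      selected[idx] = 0;
    }
    // exclude branch
    if (!truncated) dfs(idx + 1);
    for (int c : P->cells[idx]) ++suffcov[c];
  }
};

} // namespace

// [[Rcpp::export(name = ".bb_cover")]]
List bb_cover(IntegerMatrix u, NumericVector w, int d, int n_required,
              LogicalVector forced, double incumbent_obj,
              IntegerVector incumbent_sel, double node_limit,
              double time_limit) {
  // u: n_cells x n_genes 0/1; genes sorted ascending by weight by caller.
  Problem P;
  P.n_cells = u.nrow();
  P.n_genes = u.ncol();
  P.d = d;
  P.n_required = n_required;
  P.w = as<std::vector<double>>(w);
  P.node_limit = node_limit;
  P.time_limit = time_limit;
  P.cells.resize(P.n_genes);
  for (int g = 0; g < P.n_genes; ++g)
    for (int c = 0; c < P.n_cells; ++c)
      if (u(c, g)) P.cells[g].push_back(c);

  Search S;
  S.P = &P;
  S.depth.assign(P.n_cells, 0);
  S.suffcov.assign(P.n_cells, 0);
  S.selected.assign(P.n_genes, 0);
  S.t0 = std::chrono::steady_clock::now();

  // commit forced genes (nested expansion); they are not search variables
  double forced_w = 0.0;
  std::vector<int> free_genes;
  for (int g = 0; g < P.n_genes; ++g) {
    if (forced[g]) {
      forced_w += P.w[g];
      for (int c : P.cells[g]) ++S.depth[c];
    } else {
      free_genes.push_back(g);
    }
  }
  // re-index the free genes as the search space
  Problem Q;
  Q.n_cells = P.n_cells;
  Q.n_genes = static_cast<int>(free_genes.size());
  Q.d = d;
  Q.n_required = n_required;
  Q.node_limit = node_limit;
  Q.time_limit = time_limit;
  Q.base_count = static_cast<int>(P.n_genes - free_genes.size());
  for (int g : free_genes) {
    Q.w.push_back(P.w[g]);
    Q.cells.push_back(P.cells[g]);
  }
  S.P = &Q;
  S.selected.assign(Q.n_genes, 0);
  for (int g = 0; g < Q.n_genes; ++g)
    for (int c : Q.cells[g]) ++S.suffcov[c];
  S.cur_w = 0.0;

  if (R_finite(incumbent_obj)) {
    S.best_w = incumbent_obj - forced_w;
    S.have_incumbent = true;
    S.best_sel.assign(Q.n_genes, 0);
    // incumbent_sel refers to original gene indices (1-based)
    std::vector<char> inc(P.n_genes, 0);
    for (int i = 0; i < incumbent_sel.size(); ++i)
      inc[incumbent_sel[i] - 1] = 1;
    for (int j = 0; j < Q.n_genes; ++j) S.best_sel[j] = inc[free_genes[j]];
  }

  S.dfs(0);

  std::string status;
  std::vector<int> sel_out; // 1-based original indices
  for (int g = 0; g < P.n_genes; ++g) if (forced[g]) sel_out.push_back(g + 1);
  if (!S.have_incumbent) {
    status = S.truncated ? "gap_reported" : "infeasible";
  } else {
    status = S.truncated ? "gap_reported" : "optimal";
    for (int j = 0; j < Q.n_genes; ++j)
      if (S.best_sel[j]) sel_out.push_back(free_genes[j] + 1);
  }
  double obj = S.have_incumbent ? S.best_w + forced_w : R_PosInf;
  return List::create(_["status"] = status, _["objective"] = obj,
                      _["selected"] = wrap(sel_out), _["nodes"] = S.nodes);
}
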