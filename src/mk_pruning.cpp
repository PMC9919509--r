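// Felsenstein pruning for the k-state symmetric Mk model with a discrete
// rate mixture and the Lewis "variable" ascertainment correction.
//
// Transition probabilities have the closed form
//   P(same) = 1/k + (k-1)/k * exp(-k t / (k-1))
//   P(diff) = 1/k -   1/k * exp(-k t / (k-1))
// under the convention that branch lengths measure expected changes per
// character. Partials are rescaled at every internal node to avoid
// underflow on large trees.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static double logsumexp(const std::vector<double>& x) {
  double m = *std::max_element(x.begin(), x.end());
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (double v : x) s += std::exp(v - m);
  return m + std::log(s);
}

// one pruning pass for one character and one rate; tipp is k x ntip
// (column-major), constant_state >= 0 replaces tip partials by that basis
// vector (for ascertainment terms). Returns log P(pattern).
static double prune_one(const std::vector<int>& edge_order,
                        const IntegerMatrix& edge, const NumericVector& elen,
                        double rate, int ntip, int ntot, int k,
                        const double* tipp, int constant_state) {
  std::vector<double> part((size_t)ntot * k, 1.0);
  std::vector<double> logscale(ntot, 0.0);
  std::vector<bool> is_set(ntot, false);
  for (int i = 0; i < ntip; ++i) {
    for (int s = 0; s < k; ++s)
      part[(size_t)i * k + s] =
        constant_state >= 0 ? (s == constant_state ? 1.0 : 0.0)
                            : tipp[(size_t)i * k + s];
    is_set[i] = true;
  }
  const double km1 = k - 1.0;
  for (int idx : edge_order) {
    int par = edge(idx, 0) - 1, child = edge(idx, 1) - 1;
    double t = elen[idx] * rate;
    double e = std::exp(-k * t / km1);
    double ps = 1.0 / k + km1 / k * e;
    double pd = (1.0 - ps) / km1;
    double* pc = &part[(size_t)child * k];
    double sum = 0.0;
    for (int s = 0; s < k; ++s) sum += pc[s];
    double* pp = &part[(size_t)par * k];
    if (!is_set[par]) {
      for (int s = 0; s < k; ++s) pp[s] = 1.0;
      is_set[par] = true;
    }
    for (int s = 0; s < k; ++s)
      pp[s] *= pd * sum + (ps - pd) * pc[s];
    logscale[par] += logscale[child];
    double m = 0.0;
    for (int s = 0; s < k; ++s) m = std::max(m, pp[s]);
    if (m > 0.0 && (m < 1e-12 || m > 1e12)) {
      for (int s = 0; s < k; ++s) pp[s] /= m;
      logscale[par] += std::log(m);
    }
  }
  int root = ntip;  // 0-based node ntip == R node ntip+1
  double L = 0.0;
  for (int s = 0; s < k; ++s) L += part[(size_t)root * k + s] / k;
  if (L <= 0.0) return R_NegInf;
  return std::log(L) + logscale[root];
}

// [[Rcpp::export]]
List mk_loglik_cpp(IntegerMatrix edge, NumericVector elen, int ntip,
                   int nnode, List partials, IntegerVector kvec,
                   NumericVector rates, bool variable) {
  int ntot = ntip + nnode;
  int nedge = edge.nrow();
  int nchar = partials.size();

  // postorder: sort edges by completion order of the child node (iterative
  // DFS from the root, children pushed in edge order)
  std::vector<std::vector<int>> child_edges(ntot + 1);
  for (int i = 0; i < nedge; ++i) child_edges[edge(i, 0)].push_back(i);
  std::vector<int> post_index(ntot + 1, -1);
  {
    int counter = 0;
    std::vector<std::pair<int, size_t>> stack;
    stack.push_back({ntip + 1, 0});
    while (!stack.empty()) {
      auto& top = stack.back();
      int node = top.first;
      if (top.second < child_edges[node].size()) {
        int e = child_edges[node][top.second++];
        stack.push_back({edge(e, 1), 0});
      } else {
        post_index[node] = counter++;
        stack.pop_back();
      }
    }
  }
  std::vector<int> edge_order(nedge);
  for (int i = 0; i < nedge; ++i) edge_order[i] = i;
  std::sort(edge_order.begin(), edge_order.end(), [&](int a, int b) {
    return post_index[edge(a, 1)] < post_index[edge(b, 1)];
  });

  int R = rates.size();
  double logR = std::log((double)R);
  NumericVector per_char(nchar), log_pinv(nchar);
  double total = 0.0;
  for (int c = 0; c < nchar; ++c) {
    NumericMatrix tp = partials[c];
    int k = kvec[c];
    std::vector<double> lr(R), lc(R);
    for (int r = 0; r < R; ++r) {
      lr[r] = prune_one(edge_order, edge, elen, rates[r], ntip, ntot, k,
                        REAL(tp), -1);
      if (variable)
        lc[r] = prune_one(edge_order, edge, elen, rates[r], ntip, ntot, k,
                          REAL(tp), 0);
    }
    double ll = logsumexp(lr) - logR;
    double lp = R_NegInf;
    if (variable) {
      // by symmetry every constant pattern has the probability of all-zero
      lp = std::log((double)k) + logsumexp(lc) - logR;
      double pinv = std::exp(lp);
      ll = pinv < 1.0 ? ll - std::log1p(-pinv) : R_NegInf;
    }
    per_char[c] = ll;
    log_pinv[c] = lp;
    total += ll;
  }
  return List::create(_["total"] = total, _["per_char"] = per_char,
                      _["log_pinv"] = log_pinv);
}
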