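// Connected-component labeling of suprathreshold points on a channels x
// time grid, under spatial (montage) adjacency and temporal contiguity,
// with sign consistency.  Cluster mass is the sum of |t| over members.
// Used by the spatiotemporal and temporal cluster-based permutation tests;
// the permutation loop calls max_cluster_mass once per sign-flip draw.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Grid {
  const double *t;
  int nch, nt;
  double thr;
  const std::vector<std::vector<int>> *adj;

  inline int sgn(int idx) const {
    if (t[idx] > thr) return 1;
    if (t[idx] < -thr) return -1;
    return 0;
  }
};

// Flood-fill from seed; marks labels, returns mass.
double flood(const Grid &g, int seed, int id, std::vector<int> &label,
             std::vector<int> &stack) {
  const int s = g.sgn(seed);
  double mass = 0.0;
  stack.clear();
  stack.push_back(seed);
  label[seed] = id;
  while (!stack.empty()) {
    int idx = stack.back();
    stack.pop_back();
    mass += std::abs(g.t[idx]);
    int ch = idx % g.nch, ti = idx / g.nch;
    // temporal neighbors, same channel
    if (ti > 0) {
      int j = idx - g.nch;
      if (label[j] == 0 && g.sgn(j) == s) { label[j] = id; stack.push_back(j); }
    }
    if (ti + 1 < g.nt) {
      int j = idx + g.nch;
      if (label[j] == 0 && g.sgn(j) == s) { label[j] = id; stack.push_back(j); }
    }
    // spatial neighbors, same timepoint
    const std::vector<int> &nb = (*g.adj)[ch];
    for (size_t k = 0; k < nb.size(); ++k) {
      int j = nb[k] + g.nch * ti;
      if (label[j] == 0 && g.sgn(j) == s) { label[j] = id; stack.push_back(j); }
    }
  }
  return mass;
}

std::vector<std::vector<int>> adjToVec(const List &adj) {
  std::vector<std::vector<int>> out(adj.size());
  for (int i = 0; i < adj.size(); ++i) {
    IntegerVector v = adj[i];
    out[i].assign(v.begin(), v.end());
  }
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".clLabel")]]
List clLabel(NumericVector tvec, int nch, int nt, double thr, List adj) {
  Grid g{tvec.begin(), nch, nt, thr, nullptr};
  std::vector<std::vector<int>> a = adjToVec(adj);
  g.adj = &a;
  std::vector<int> label(nch * nt, 0), stack;
  std::vector<double> masses;
  std::vector<int> signs;
  int id = 0;
  for (int idx = 0; idx < nch * nt; ++idx) {
    if (label[idx] == 0 && g.sgn(idx) != 0) {
      ++id;
      signs.push_back(g.sgn(idx));
      masses.push_back(flood(g, idx, id, label, stack));
    }
  }
  IntegerMatrix lab(nch, nt);
  std::copy(label.begin(), label.end(), lab.begin());
  return List::create(_["labels"] = lab, _["masses"] = wrap(masses),
                      _["signs"] = wrap(signs));
}

// Maximum cluster mass over both signs for a batch of t-maps (one per row
// of `tmat`, each a flattened channels x time grid).
// [[Rcpp::export(name = ".clMaxMassBatch")]]
NumericVector clMaxMassBatch(NumericMatrix tmat, int nch, int nt, double thr,
                             List adj) {
  std::vector<std::vector<int>> a = adjToVec(adj);
  int nperm = tmat.nrow();
  NumericVector out(nperm);
  std::vector<double> row(nch * nt);
  std::vector<int> label, stack;
  for (int p = 0; p < nperm; ++p) {
    for (int j = 0; j < nch * nt; ++j) row[j] = tmat(p, j);
    Grid g{row.data(), nch, nt, thr, &a};
    label.assign(nch * nt, 0);
    double best = 0.0;
    int id = 0;
    for (int idx = 0; idx < nch * nt; ++idx) {
      if (label[idx] == 0 && g.sgn(idx) != 0) {
        double m = flood(g, idx, ++id, label, stack);
        if (m > best) best = m;
      }
    }
    out[p] = best;
  }
  return out;
}
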