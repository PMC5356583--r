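#include <Rcpp.h>
#include <vector>
#include <random>
#include <cmath>
using namespace Rcpp;

// BDeu local marginal likelihood for one family (target + parent set) on a
// 3-state discrete matrix (genes in rows, samples in columns, values 0..2).
static double family_score(const IntegerMatrix& st, int target,
                           const std::vector<int>& parents, double ess) {
  const int n = st.ncol();
  const int p = (int) parents.size();
  int q = 1;
  for (int i = 0; i < p; ++i) q *= 3;
  std::vector<int> counts((size_t) q * 3, 0);
  for (int s = 0; s < n; ++s) {
    int cfg = 0, mult = 1;
    for (int i = 0; i < p; ++i) { cfg += st(parents[i], s) * mult; mult *= 3; }
    counts[(size_t) cfg * 3 + st(target, s)]++;
  }
  const double aj = ess / q, ajk = ess / (q * 3.0);
  double sc = 0.0;
  for (int j = 0; j < q; ++j) {
    const int N0 = counts[(size_t) j * 3], N1 = counts[(size_t) j * 3 + 1],
              N2 = counts[(size_t) j * 3 + 2];
    const int Nj = N0 + N1 + N2;
    if (Nj == 0) continue;
    sc += std::lgamma(aj) - std::lgamma(aj + Nj);
    const int Njk[3] = {N0, N1, N2};
    for (int k = 0; k < 3; ++k)
      if (Njk[k] > 0) sc += std::lgamma(ajk + Njk[k]) - std::lgamma(ajk);
  }
  return sc;
}

// [[Rcpp::export]]
double bdeu_family_score_cpp(IntegerMatrix states, int target,
                             IntegerVector parents, double ess) {
  std::vector<int> par(parents.size());
  for (int i = 0; i < parents.size(); ++i) par[i] = parents[i] - 1;
  return family_score(states, target - 1, par, ess);
}

struct Graph {
  int n;
  std::vector<std::vector<int>> parents, children;
  std::vector<std::pair<int,int>> edges;   // (regulator, target)

  explicit Graph(int n_) : n(n_), parents(n_), children(n_) {}

  bool has_edge(int i, int j) const {
    for (int p : parents[j]) if (p == i) return true;
    return false;
  }
  void add_edge(int i, int j) {
    parents[j].push_back(i);
    children[i].push_back(j);
    edges.emplace_back(i, j);
  }
  void remove_from(std::vector<int>& v, int x) {
    for (size_t k = 0; k < v.size(); ++k)
      if (v[k] == x) { v[k] = v.back(); v.pop_back(); return; }
  }
  void delete_edge(int i, int j) {
    remove_from(parents[j], i);
    remove_from(children[i], j);
    for (size_t k = 0; k < edges.size(); ++k)
      if (edges[k].first == i && edges[k].second == j) {
        edges[k] = edges.back(); edges.pop_back(); return;
      }
  }
  // is there a directed path from `from` to `to`?
  bool path_exists(int from, int to) const {
    if (from == to) return true;
    std::vector<char> seen(n, 0);
    std::vector<int> stack{from};
    seen[from] = 1;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      for (int v : children[u]) {
        if (v == to) return true;
        if (!seen[v]) { seen[v] = 1; stack.push_back(v); }
      }
    }
    return false;
  }
};

// Simulated-annealing structure search over add/delete/reverse moves with a
// geometric temperature schedule; returns the best structure visited.
// prior(i, j) is the log structure-prior increment for edge i -> j.
// [[Rcpp::export]]
List anneal_search_cpp(IntegerMatrix states, NumericMatrix prior,
                       int max_parents, int n_steps,
                       double t0, double t_end, double ess,
                       int seed, int trace_every) {
  const int n = states.nrow();
  Graph g(n);
  std::vector<double> fam(n);        // family score incl. incoming-edge priors
  for (int j = 0; j < n; ++j) fam[j] = family_score(states, j, g.parents[j], ess);
  double total = 0.0;
  for (int j = 0; j < n; ++j) total += fam[j];

  double best = total;
  std::vector<std::pair<int,int>> best_edges;
  std::mt19937_64 rng((uint64_t) seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  auto rint = [&](int m) { return (int) (rng() % (uint64_t) m); };

  auto fam_with = [&](int j, const std::vector<int>& par) {
    double sc = family_score(states, j, par, ess);
    for (int p : par) sc += prior(p, j);
    return sc;
  };

  const int n_trace = (n_steps + trace_every - 1) / trace_every;
  NumericVector trace(n_trace);
  const double ratio = (t0 > 0 && t_end > 0) ? t_end / t0 : 1.0;

  for (int step = 0; step < n_steps; ++step) {
    const double T = t0 * std::pow(ratio, n_steps > 1 ? (double) step / (n_steps - 1) : 0.0);
    const int move = rint(3);
    double delta = 0.0;
    bool legal = false;
    int mi = -1, mj = -1;
    double new_fam_j = 0.0, new_fam_i = 0.0;

    if (move == 0) {                       // add i -> j
      mi = rint(n); mj = rint(n);
      if (mi != mj && !g.has_edge(mi, mj) &&
          (int) g.parents[mj].size() < max_parents && !g.path_exists(mj, mi)) {
        std::vector<int> par = g.parents[mj];
        par.push_back(mi);
        new_fam_j = fam_with(mj, par);
        delta = new_fam_j - fam[mj];
        legal = true;
      }
    } else if (move == 1 && !g.edges.empty()) {   // delete i -> j
      const auto e = g.edges[rint((int) g.edges.size())];
      mi = e.first; mj = e.second;
      std::vector<int> par = g.parents[mj];
      for (size_t k = 0; k < par.size(); ++k)
        if (par[k] == mi) { par[k] = par.back(); par.pop_back(); break; }
      new_fam_j = fam_with(mj, par);
      delta = new_fam_j - fam[mj];
      legal = true;
    } else if (move == 2 && !g.edges.empty()) {   // reverse i -> j to j -> i
      const auto e = g.edges[rint((int) g.edges.size())];
      mi = e.first; mj = e.second;
      if ((int) g.parents[mi].size() < max_parents) {
        g.delete_edge(mi, mj);
        const bool cyc = g.path_exists(mi, mj);   // alternative path would close a cycle
        g.add_edge(mi, mj);
        if (!cyc) {
          std::vector<int> par_j = g.parents[mj];
          for (size_t k = 0; k < par_j.size(); ++k)
            if (par_j[k] == mi) { par_j[k] = par_j.back(); par_j.pop_back(); break; }
          std::vector<int> par_i = g.parents[mi];
          par_i.push_back(mj);
          new_fam_j = fam_with(mj, par_j);
          new_fam_i = fam_with(mi, par_i);
          delta = (new_fam_j - fam[mj]) + (new_fam_i - fam[mi]);
          legal = true;
        }
      }
    }

    if (legal && (delta > 0 || (T > 0 && unif(rng) < std::exp(delta / T)))) {
      if (move == 0) {
        g.add_edge(mi, mj); fam[mj] = new_fam_j;
      } else if (move == 1) {
        g.delete_edge(mi, mj); fam[mj] = new_fam_j;
      } else {
        g.delete_edge(mi, mj); g.add_edge(mj, mi);
        fam[mj] = new_fam_j; fam[mi] = new_fam_i;
      }
      total += delta;
      if (total > best) { best = total; best_edges = g.edges; }
    }
    if (step % trace_every == 0) trace[step / trace_every] = best;
  }

  IntegerMatrix em((int) best_edges.size(), 2);
  for (size_t k = 0; k < best_edges.size(); ++k) {
    em(k, 0) = best_edges[k].first + 1;
    em(k, 1) = best_edges[k].second + 1;
  }
  return List::create(_["edges"] = em, _["score"] = best, _["trace"] = trace);
}
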