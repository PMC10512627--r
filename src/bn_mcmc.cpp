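// Discrete (3-state) Bayesian network scoring and single-edge structure
// MCMC.  The score is the BIC of the multinomial family model plus a
// decomposable structure prior: -kappa per edge, +lambda per edge whose
// source is eQTL-anchored and whose target is not.  Genes with a cis-eQTL
// may additionally carry their genotype (0/1/2) as a fixed instrument
// parent: this breaks Markov equivalence by likelihood, so edge
// orientation propagates outward from anchored genes.

#include <Rcpp.h>
#include <random>
#include <queue>
using namespace Rcpp;

// log-likelihood of node given parent configuration (+ optional fixed
// genotype instrument row `ginst` in `geno`; -1 = none)
static double family_loglik(const IntegerMatrix& S, int node,
                            const std::vector<int>& parents, int n,
                            const IntegerMatrix& geno, int ginst) {
  int np = parents.size();
  int ncfg = 1;
  for (int j = 0; j < np; j++) ncfg *= 3;
  if (ginst >= 0) ncfg *= 3;
  std::vector<int> cnt(ncfg * 3, 0);
  for (int s = 0; s < n; s++) {
    int cfg = 0, mul = 1;
    for (int j = 0; j < np; j++) { cfg += S(parents[j], s) * mul; mul *= 3; }
    if (ginst >= 0) cfg += geno(ginst, s) * mul;
    cnt[cfg * 3 + S(node, s)]++;
  }
  double ll = 0.0;
  for (int c = 0; c < ncfg; c++) {
    int nj = cnt[c * 3] + cnt[c * 3 + 1] + cnt[c * 3 + 2];
    if (nj == 0) continue;
    for (int k = 0; k < 3; k++) {
      int v = cnt[c * 3 + k];
      if (v > 0) ll += v * std::log((double)v / nj);
    }
  }
  return ll;
}

static double family_score(const IntegerMatrix& S, int node,
                           const std::vector<int>& parents,
                           const LogicalVector& anchored,
                           double kappa, double lambda,
                           const IntegerMatrix& geno, int ginst) {
  int n = S.ncol();
  double ll = family_loglik(S, node, parents, n, geno, ginst);
  double d = 2.0 * std::pow(3.0, (double)parents.size() + (ginst >= 0));
  double prior = -kappa * (double)parents.size();
  if (!anchored[node])
    for (int p : parents) if (anchored[p]) prior += lambda;
  return ll - 0.5 * d * std::log((double)n) + prior;
}

// [[Rcpp::export]]
double bn_family_score_cpp(IntegerMatrix states, int node,
                           IntegerVector parents, LogicalVector anchored,
                           double kappa, double lambda,
                           IntegerMatrix geno, int ginst) {
  std::vector<int> pv(parents.begin(), parents.end());
  return family_score(states, node, pv, anchored, kappa, lambda,
                      geno, ginst);
}

// pairwise mutual information (nats) between discretized gene rows
// [[Rcpp::export]]
NumericMatrix bn_mi_cpp(IntegerMatrix states) {
  int V = states.nrow(), n = states.ncol();
  NumericMatrix mi(V, V);
  for (int i = 0; i < V; i++) {
    for (int j = i + 1; j < V; j++) {
      int cnt[9] = {0};
      int ri[3] = {0}, rj[3] = {0};
      for (int s = 0; s < n; s++) {
        int a = states(i, s), b = states(j, s);
        cnt[a * 3 + b]++; ri[a]++; rj[b]++;
      }
      double m = 0.0;
      for (int a = 0; a < 3; a++)
        for (int b = 0; b < 3; b++) {
          int c = cnt[a * 3 + b];
          if (c > 0)
            m += (double)c / n *
              std::log((double)c * n / ((double)ri[a] * rj[b]));
        }
      mi(i, j) = m; mi(j, i) = m;
    }
  }
  return mi;
}

// is there a directed path from -> to (BFS over child lists)?
static bool path_exists(const std::vector<std::vector<int>>& children,
                        int from, int to, int V) {
  if (from == to) return true;
  std::vector<char> seen(V, 0);
  std::queue<int> q;
  q.push(from); seen[from] = 1;
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (int w : children[u]) {
      if (w == to) return true;
      if (!seen[w]) { seen[w] = 1; q.push(w); }
    }
  }
  return false;
}

static void erase_val(std::vector<int>& v, int x) {
  for (size_t i = 0; i < v.size(); i++)
    if (v[i] == x) { v.erase(v.begin() + i); return; }
}

// One annealed Metropolis-Hastings chain over DAGs.  Proposal: draw an
// ordered node pair (u, v) uniformly; if the edge u->v is absent, propose
// adding it; if present, propose (coin flip) deleting or reversing it.
// Invalid moves (cycle, parent cap, antiparallel edge) reject in place.
// The Hastings correction is 1/2 for an add, 2 for a delete, 1 for a
// reversal.  The acceptance temperature decays geometrically from temp0 to
// temp_end over the first 60% of the sweeps and then stays at temp_end, so
// each chain settles into a high-scoring structure (consensus across
// chains then measures reconstruction stability).
// [[Rcpp::export]]
IntegerMatrix bn_mcmc_chain_cpp(IntegerMatrix states, LogicalVector anchored,
                                int sweeps, int max_parents,
                                double kappa, double lambda, int seed,
                                IntegerMatrix geno, IntegerVector ginst,
                                IntegerMatrix init_edges,
                                double temp0 = 2.0, double temp_end = 0.5) {
  int V = states.nrow();
  std::mt19937 gen((unsigned)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::uniform_int_distribution<int> pick(0, V - 1);

  std::vector<std::vector<int>> parents(V), children(V);
  std::vector<std::vector<char>> edge(V, std::vector<char>(V, 0));

  // warm start (e.g. a Chow-Liu tree); rows are 1-based (u, v) edges,
  // applied only while they keep the graph a DAG within the parent cap
  for (int r = 0; r < init_edges.nrow(); r++) {
    int u = init_edges(r, 0) - 1, v = init_edges(r, 1) - 1;
    if (u < 0 || v < 0 || u >= V || v >= V || u == v) continue;
    if (edge[u][v] || edge[v][u]) continue;
    if ((int)parents[v].size() >= max_parents) continue;
    if (path_exists(children, v, u, V)) continue;
    parents[v].push_back(u);
    children[u].push_back(v);
    edge[u][v] = 1;
  }

  std::vector<double> fscore(V);
  for (int i = 0; i < V; i++)
    fscore[i] = family_score(states, i, parents[i], anchored, kappa, lambda,
                             geno, ginst[i]);

  int t_anneal = (int)(0.6 * sweeps);
  if (t_anneal < 1) t_anneal = 1;
  double decay = std::pow(temp_end / temp0, 1.0 / t_anneal);

  double temp = temp0;
  for (int it = 0; it < sweeps; it++) {
    if (it < t_anneal) temp = temp0 * std::pow(decay, it);
    else temp = temp_end;
    int u = pick(gen);
    int v = pick(gen);
    if (u == v) continue;
    if (!edge[u][v]) {
      // propose add u -> v
      if (edge[v][u]) continue;
      if ((int)parents[v].size() >= max_parents) continue;
      if (path_exists(children, v, u, V)) continue;  // would close a cycle
      std::vector<int> pv = parents[v];
      pv.push_back(u);
      double ns = family_score(states, v, pv, anchored, kappa, lambda,
                               geno, ginst[v]);
      double loga = (ns - fscore[v]) / temp + std::log(0.5);
      if (loga >= 0 || unif(gen) < std::exp(loga)) {
        parents[v] = pv;
        children[u].push_back(v);
        edge[u][v] = 1;
        fscore[v] = ns;
      }
    } else {
      if (unif(gen) < 0.5) {
        // propose delete u -> v
        std::vector<int> pv = parents[v];
        erase_val(pv, u);
        double ns = family_score(states, v, pv, anchored, kappa, lambda,
                                 geno, ginst[v]);
        double loga = (ns - fscore[v]) / temp + std::log(2.0);
        if (loga >= 0 || unif(gen) < std::exp(loga)) {
          parents[v] = pv;
          erase_val(children[u], v);
          edge[u][v] = 0;
          fscore[v] = ns;
        }
      } else {
        // propose reverse u -> v  =>  v -> u
        if ((int)parents[u].size() >= max_parents) continue;
        // temporarily drop u -> v, then v -> u must not close a cycle
        erase_val(children[u], v);
        bool cyc = path_exists(children, u, v, V);
        children[u].push_back(v);
        if (cyc) continue;
        std::vector<int> pv = parents[v]; erase_val(pv, u);
        std::vector<int> pu = parents[u]; pu.push_back(v);
        double nsv = family_score(states, v, pv, anchored, kappa, lambda,
                                  geno, ginst[v]);
        double nsu = family_score(states, u, pu, anchored, kappa, lambda,
                                  geno, ginst[u]);
        double loga = ((nsv + nsu) - (fscore[v] + fscore[u])) / temp;
        if (loga >= 0 || unif(gen) < std::exp(loga)) {
          parents[v] = pv; parents[u] = pu;
          erase_val(children[u], v);
          children[v].push_back(u);
          edge[u][v] = 0; edge[v][u] = 1;
          fscore[v] = nsv; fscore[u] = nsu;
        }
      }
    }
  }

  int ne = 0;
  for (int i = 0; i < V; i++) ne += (int)parents[i].size();
  IntegerMatrix out(ne, 2);
  int r = 0;
  for (int v = 0; v < V; v++)
    for (int u : parents[v]) {
      out(r, 0) = u + 1;  // 1-based for R
      out(r, 1) = v + 1;
      r++;
    }
  return out;
}
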