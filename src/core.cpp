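#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// State order everywhere: 0 = U, 1 = F, 2 = S1, 3 = S2.
// Assignment vectors v in {1,2}^n are indexed 0..2^n-1 with bit (g-1) set
// iff genome g's slot-1 track maps to parental subgenome 2.

static inline void tip_conditional(int obs, int a, double* out) {
  // obs: 1 duplicated, 2 single_in_p1, 3 single_in_p2; a = v_g - 1
  out[0] = out[1] = out[2] = out[3] = 0.0;
  if (obs == 1) { out[0] = 1.0; out[1] = 1.0; }
  else if (obs == 2) { if (a == 0) out[2] = 1.0; else out[3] = 1.0; }
  else { if (a == 0) out[3] = 1.0; else out[2] = 1.0; }
}

// Emission likelihoods for every assignment vector, one row per unique
// observation pattern. Pruning keeps, for every node, partial likelihoods
// indexed by the assignment sub-vector of the tips below it, so the whole
// 2^n family of assignments is computed in one postorder sweep.
//
// patterns: npat x n observation codes; edge: E x 2 (1-based node ids,
// postorder: every child edge precedes its parent's edge); P: 4 x 4 x E
// column-major transition matrices (row = parent state); tip_genome: genome
// column (1-based) for tip node ids 1..n_tips.
// [[Rcpp::export]]
NumericMatrix cpp_pillar_emissions(IntegerMatrix patterns, IntegerMatrix edge,
                                   NumericVector P, IntegerVector tip_genome,
                                   int n_nodes, int root) {
  const int npat = patterns.nrow(), n = patterns.ncol();
  const int E = edge.nrow(), S = 1 << n, ntips = tip_genome.size();
  NumericMatrix out(npat, S);
  std::vector<int> kk(n_nodes + 1);
  std::vector< std::vector<int> > gens(n_nodes + 1);
  std::vector< std::vector<double> > L(n_nodes + 1);

  for (int p = 0; p < npat; ++p) {
    for (int u = 1; u <= n_nodes; ++u) {
      kk[u] = 0; gens[u].clear(); L[u].assign(4, 1.0);
    }
    std::vector<bool> tip_ready(ntips + 1, false);
    for (int e = 0; e < E; ++e) {
      int par = edge(e, 0), ch = edge(e, 1);
      if (ch <= ntips && !tip_ready[ch]) {
        int g = tip_genome[ch - 1];
        int obs = patterns(p, g - 1);
        L[ch].assign(8, 0.0);
        double tmp[4];
        for (int a = 0; a < 2; ++a) {
          tip_conditional(obs, a, tmp);
          for (int s = 0; s < 4; ++s) L[ch][a * 4 + s] = tmp[s];
        }
        kk[ch] = 1; gens[ch].assign(1, g); tip_ready[ch] = true;
      }
      const int kc = kk[ch], pc = 1 << kc;
      const double* Pe = &P[(size_t)e * 16];
      std::vector<double> M((size_t)pc * 4);
      for (int q = 0; q < pc; ++q)
        for (int sp = 0; sp < 4; ++sp) {
          double acc = 0.0;
          for (int sc = 0; sc < 4; ++sc) acc += Pe[sp + 4 * sc] * L[ch][q * 4 + sc];
          M[q * 4 + sp] = acc;
        }
      const int kp = kk[par], pp = 1 << kp;
      std::vector<double> newL((size_t)pp * pc * 4);
      for (int qc = 0; qc < pc; ++qc)
        for (int qp = 0; qp < pp; ++qp)
          for (int s = 0; s < 4; ++s)
            newL[((size_t)qc * pp + qp) * 4 + s] = L[par][qp * 4 + s] * M[qc * 4 + s];
      L[par].swap(newL);
      kk[par] = kp + kc;
      for (size_t j = 0; j < gens[ch].size(); ++j) gens[par].push_back(gens[ch][j]);
    }
    // root state is U with probability 1 (every locus starts duplicated)
    const int kr = kk[root];
    for (int q = 0; q < (1 << kr); ++q) {
      int vi = 0;
      for (int j = 0; j < kr; ++j)
        if ((q >> j) & 1) vi |= 1 << (gens[root][j] - 1);
      out(p, vi) = L[root][q * 4 + 0];
    }
  }
  return out;
}

// P(parent = U, child = S1 / S2 / F | pillar data, assignment v) for every
// edge, observation pattern and assignment vector, by an inside-outside pass
// per (pattern, v). Returns a flat vector laid out as
// [npat, S, E, 3] (types: S1, S2, F); zero where the assignment has zero
// likelihood.
// [[Rcpp::export]]
NumericVector cpp_branch_loss_cond(IntegerMatrix patterns, IntegerMatrix edge,
                                   NumericVector P, IntegerVector tip_genome,
                                   int n_nodes, int root) {
  const int npat = patterns.nrow(), n = patterns.ncol();
  const int E = edge.nrow(), S = 1 << n, ntips = tip_genome.size();
  NumericVector out((R_xlen_t)npat * S * E * 3);
  const int type_state[3] = {2, 3, 1};  // S1, S2, F

  // child-edge lists per node
  std::vector< std::vector<int> > child_edges(n_nodes + 1);
  for (int e = 0; e < E; ++e) child_edges[edge(e, 0)].push_back(e);

  std::vector< std::vector<double> > inside(n_nodes + 1, std::vector<double>(4));
  std::vector< std::vector<double> > outn(n_nodes + 1, std::vector<double>(4));
  std::vector< std::vector<double> > msg(E, std::vector<double>(4));

  for (int p = 0; p < npat; ++p) {
    for (int v = 0; v < S; ++v) {
      // inside (postorder)
      for (int u = 1; u <= n_nodes; ++u) inside[u].assign(4, 1.0);
      for (int t = 1; t <= ntips; ++t) {
        int g = tip_genome[t - 1];
        tip_conditional(patterns(p, g - 1), (v >> (g - 1)) & 1, &inside[t][0]);
      }
      for (int e = 0; e < E; ++e) {
        int par = edge(e, 0), ch = edge(e, 1);
        const double* Pe = &P[(size_t)e * 16];
        for (int sp = 0; sp < 4; ++sp) {
          double acc = 0.0;
          for (int sc = 0; sc < 4; ++sc) acc += Pe[sp + 4 * sc] * inside[ch][sc];
          msg[e][sp] = acc;
        }
        for (int sp = 0; sp < 4; ++sp) inside[par][sp] *= msg[e][sp];
      }
      double Lv = inside[root][0];
      if (!(Lv > 0.0)) continue;
      // outside (preorder = reversed postorder), root pinned to U
      for (int u = 1; u <= n_nodes; ++u) outn[u].assign(4, 0.0);
      outn[root][0] = 1.0;
      for (int e = E - 1; e >= 0; --e) {
        int par = edge(e, 0), ch = edge(e, 1);
        const double* Pe = &P[(size_t)e * 16];
        double excl[4];
        for (int sp = 0; sp < 4; ++sp) {
          double acc = outn[par][sp];
          const std::vector<int>& ces = child_edges[par];
          for (size_t j = 0; j < ces.size(); ++j)
            if (ces[j] != e) acc *= msg[ces[j]][sp];
          excl[sp] = acc;
        }
        for (int sc = 0; sc < 4; ++sc) {
          double acc = 0.0;
          for (int sp = 0; sp < 4; ++sp) acc += excl[sp] * Pe[sp + 4 * sc];
          outn[ch][sc] = acc;
        }
        for (int t = 0; t < 3; ++t) {
          int sc = type_state[t];
          double joint = excl[0] * Pe[0 + 4 * sc] * inside[ch][sc];
          out[(R_xlen_t)p + (R_xlen_t)npat * (v + (R_xlen_t)S * (e + (R_xlen_t)E * t))] =
            joint / Lv;
        }
      }
    }
  }
  return out;
}

static inline void apply_flip_kernel(std::vector<double>& f, int S, int n,
                                     const double* flip_row, int stride) {
  for (int g = 0; g < n; ++g) {
    double t = flip_row[(size_t)g * stride];
    if (t == 0.0) continue;
    int bit = 1 << g;
    for (int idx = 0; idx < S; ++idx)
      if (!(idx & bit)) {
        double x = f[idx], y = f[idx | bit];
        f[idx] = (1 - t) * x + t * y;
        f[idx | bit] = t * x + (1 - t) * y;
      }
  }
}

// Scaled forward (and optionally backward/posterior) pass of the HMM over
// assignment vectors. emis: m x S linear emission likelihoods (caller scales
// rows; returned loglik excludes those scales). flip: (m-1) x n per-genome
// flip probabilities at each junction. The flip kernel factorises over
// genomes and is symmetric, so the same sweep serves both directions.
// [[Rcpp::export]]
List cpp_hmm(NumericMatrix emis, NumericMatrix flip, bool want_posterior) {
  const int m = emis.nrow(), S = emis.ncol();
  int n = 0; while ((1 << n) < S) ++n;
  std::vector<double> f(S), b(S), tmp(S);
  NumericMatrix Fm(want_posterior ? m : 1, want_posterior ? S : 1);
  NumericMatrix post(want_posterior ? m : 1, want_posterior ? S : 1);
  double loglik = 0.0;
  bool dead = false;

  for (int j = 0; j < S; ++j) f[j] = emis(0, j) / S;
  for (int i = 0; i < m; ++i) {
    if (i > 0) {
      apply_flip_kernel(f, S, n, &flip(i - 1, 0), m - 1);
      for (int j = 0; j < S; ++j) f[j] *= emis(i, j);
    }
    double norm = 0.0;
    for (int j = 0; j < S; ++j) norm += f[j];
    if (!(norm > 0.0)) { dead = true; break; }
    for (int j = 0; j < S; ++j) f[j] /= norm;
    loglik += std::log(norm);
    if (want_posterior) for (int j = 0; j < S; ++j) Fm(i, j) = f[j];
  }
  if (dead)
    return List::create(_["loglik"] = R_NegInf, _["posterior"] = R_NilValue);
  if (!want_posterior)
    return List::create(_["loglik"] = loglik, _["posterior"] = R_NilValue);

  for (int j = 0; j < S; ++j) b[j] = 1.0;
  for (int i = m - 1; i >= 0; --i) {
    if (i < m - 1) {
      for (int j = 0; j < S; ++j) tmp[j] = b[j] * emis(i + 1, j);
      apply_flip_kernel(tmp, S, n, &flip(i, 0), m - 1);
      double norm = 0.0;
      for (int j = 0; j < S; ++j) norm += tmp[j];
      for (int j = 0; j < S; ++j) b[j] = tmp[j] / norm;
    }
    double norm = 0.0;
    for (int j = 0; j < S; ++j) { post(i, j) = Fm(i, j) * b[j]; norm += post(i, j); }
    for (int j = 0; j < S; ++j) post(i, j) /= norm;
  }
  return List::create(_["loglik"] = loglik, _["posterior"] = post);
}
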