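// Greedy hill-climbing engine for all-continuous (Gaussian) networks,
// operating on the crossproduct matrix of the data so that local scores are
// independent of the sample size in cost.  The R layer handles mixed
// discrete/continuous data with a generic implementation; this engine is the
// fast path used inside bootstrap averaging and per-individual imputation.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// In-place Cholesky solve of A x = b for a k x k SPD matrix (column-major).
// Returns false when the matrix is numerically singular.
static bool chol_solve(std::vector<double>& A, std::vector<double>& b, int k) {
  std::vector<double> diag0(k);
  for (int j = 0; j < k; ++j) diag0[j] = A[j + k * j];
  for (int j = 0; j < k; ++j) {
    double d = A[j + k * j];
    for (int t = 0; t < j; ++t) d -= A[j + k * t] * A[j + k * t];
    double tol = 1e-10 * std::max(1.0, std::fabs(diag0[j]));
    if (d <= tol) return false;
    d = std::sqrt(d);
    A[j + k * j] = d;
    for (int i = j + 1; i < k; ++i) {
      double s = A[i + k * j];
      for (int t = 0; t < j; ++t) s -= A[i + k * t] * A[j + k * t];
      A[i + k * j] = s / d;
    }
  }
  for (int i = 0; i < k; ++i) {
    double s = b[i];
    for (int t = 0; t < i; ++t) s -= A[i + k * t] * b[t];
    b[i] = s / A[i + k * i];
  }
  for (int i = k - 1; i >= 0; --i) {
    double s = b[i];
    for (int t = i + 1; t < k; ++t) s -= A[t + k * i] * b[t];
    b[i] = s / A[i + k * i];
  }
  return true;
}

// Maximised Gaussian log-likelihood score of `node` given `parents`,
// computed from the crossproduct matrix C of cbind(1, X) ((p+1) x (p+1),
// intercept first).  pen = 0 (loglik), 1 (AIC) or log(n)/2 (BIC); the
// parameter count is |parents| + 2 (coefficients + intercept + variance).
// Returns NA for a singular design or a zero residual variance (degenerate
// fit: the candidate parent set is inadmissible).
static double gauss_local(const double* C, int pc, int n, int node,
                          const std::vector<int>& par, double pen) {
  int np = (int)par.size(), k = np + 1;
  std::vector<double> A(k * k), b(k), b0(k);
  std::vector<int> idx(k);
  idx[0] = 0;
  for (int i = 0; i < np; ++i) idx[i + 1] = par[i] + 1;
  int y = node + 1;
  for (int j = 0; j < k; ++j) {
    for (int i = 0; i < k; ++i) A[i + k * j] = C[idx[i] + pc * idx[j]];
    b[j] = C[idx[j] + pc * y];
    b0[j] = b[j];
  }
  double yty = C[y + pc * y];
  if (!chol_solve(A, b, k)) return NA_REAL;
  double rss = yty;
  for (int i = 0; i < k; ++i) rss -= b[i] * b0[i];
  if (!(rss > 1e-12 * std::max(1.0, yty))) return NA_REAL;
  double sigma2 = rss / n;
  double ll = -0.5 * n * (std::log(2.0 * M_PI * sigma2) + 1.0);
  return ll - pen * (np + 2.0);
}

// [[Rcpp::export]]
double cpp_gauss_local(NumericMatrix C, int n, int node, IntegerVector parents,
                       double pen) {
  std::vector<int> par(parents.begin(), parents.end());
  return gauss_local(REAL(C), C.nrow(), n, node - 1, par, pen);
}

namespace {

struct HC {
  int p, n, pc;
  const double* C;
  double pen, tol;
  const int* allowed;    // p x p, 1 if edge i->j may exist
  const int* mustpair;   // p x p symmetric, 1 if pair must stay connected
  const double* lp;      // p x p log prior weights (0 when unflagged)
  std::vector<int> amat;
  std::vector<double> ls, addD, delD, revD;
  std::vector<unsigned char> excl;
  int maxit;

  HC(int p_, int n_, const double* C_, int pc_, double pen_,
     const int* allowed_, const int* mustpair_, const double* lp_, int maxit_)
    : p(p_), n(n_), pc(pc_), C(C_), pen(pen_), tol(1e-9),
      allowed(allowed_), mustpair(mustpair_), lp(lp_),
      amat(p_ * p_, 0), ls(p_), addD(p_ * p_), delD(p_ * p_),
      revD(p_ * p_), excl(3 * p_ * p_), maxit(maxit_) {}

  inline int  edge(int i, int j) const { return amat[i + p * j]; }
  inline double prior(int i, int j) const { return lp[i + p * j]; }

  std::vector<int> parents(int j) const {
    std::vector<int> out;
    for (int i = 0; i < p; ++i) if (edge(i, j)) out.push_back(i);
    return out;
  }

  double score_with(int j, std::vector<int> par) const {
    return gauss_local(C, pc, n, j, par, pen);
  }

  bool has_path(int from, int to) const {
    if (from == to) return true;
    std::vector<unsigned char> seen(p, 0);
    std::vector<int> stack(1, from);
    seen[from] = 1;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      for (int w = 0; w < p; ++w)
        if (edge(v, w) && !seen[w]) {
          if (w == to) return true;
          seen[w] = 1;
          stack.push_back(w);
        }
    }
    return false;
  }

  // recompute ls[j] and every cached delta that depends on pa(j)
  void refresh(int j) {
    ls[j] = score_with(j, parents(j));
    std::vector<int> pa = parents(j);
    for (int i = 0; i < p; ++i) {
      if (i == j) continue;
      double na = NA_REAL;
      // addition i -> j
      if (!edge(i, j) && !edge(j, i) && allowed[i + p * j]) {
        std::vector<int> pa2 = pa; pa2.push_back(i);
        double s = score_with(j, pa2);
        addD[i + p * j] = (ISNAN(s) || ISNAN(ls[j])) ? na
          : s - ls[j] + prior(i, j);
      } else addD[i + p * j] = na;
      // deletion / reversal of existing edge i -> j
      if (edge(i, j)) {
        std::vector<int> pa2;
        for (int t : pa) if (t != i) pa2.push_back(t);
        double s = score_with(j, pa2);
        double dj = (ISNAN(s) || ISNAN(ls[j])) ? na
          : s - ls[j] - prior(i, j);
        delD[i + p * j] = mustpair[i + p * j] ? na : dj;
        if (allowed[j + p * i] && !ISNAN(dj)) {
          std::vector<int> pai = parents(i); pai.push_back(j);
          double si = score_with(i, pai);
          revD[i + p * j] = (ISNAN(si) || ISNAN(ls[i])) ? na
            : dj + si - ls[i] + prior(j, i);
        } else revD[i + p * j] = na;
      } else { delD[i + p * j] = na; revD[i + p * j] = na; }
    }
    // reversal deltas of edges out of j depend on pa(j) as well
    for (int k2 = 0; k2 < p; ++k2) {
      if (!edge(j, k2)) continue;
      if (!allowed[k2 + p * j]) { revD[j + p * k2] = NA_REAL; continue; }
      std::vector<int> pak;
      for (int t = 0; t < p; ++t) if (edge(t, k2) && t != j) pak.push_back(t);
      double sk = score_with(k2, pak);
      double dk = (ISNAN(sk) || ISNAN(ls[k2])) ? NA_REAL
        : sk - ls[k2] - prior(j, k2);
      if (ISNAN(dk)) { revD[j + p * k2] = NA_REAL; continue; }
      std::vector<int> paj = pa; paj.push_back(k2);
      double sj = score_with(j, paj);
      revD[j + p * k2] = (ISNAN(sj) || ISNAN(ls[j])) ? NA_REAL
        : dk + sj - ls[j] + prior(k2, j);
    }
  }

  void set_graph(const int* start) {
    std::copy(start, start + p * p, amat.begin());
    for (int j = 0; j < p; ++j) refresh(j);
  }

  double total() const {
    double s = 0;
    for (int j = 0; j < p; ++j) {
      if (ISNAN(ls[j])) return NA_REAL;
      s += ls[j];
    }
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j)
        if (edge(i, j)) s += prior(i, j);
    return s;
  }

  // one full hill climb from the current graph; returns final score
  double climb() {
    for (int iter = 0; iter < maxit; ++iter) {
      std::fill(excl.begin(), excl.end(), 0);
      bool applied = false;
      for (;;) {
        double best = tol;
        int bi = -1, bj = -1, bt = -1;
        // fixed (from, to, move-type) scan order for deterministic ties
        for (int i = 0; i < p; ++i)
          for (int j = 0; j < p; ++j) {
            if (i == j) continue;
            for (int t = 0; t < 3; ++t) {
              if (excl[t + 3 * (i + p * j)]) continue;
              double d = (t == 0) ? addD[i + p * j]
                       : (t == 1) ? delD[i + p * j]
                                  : revD[i + p * j];
              // first-in-order wins among deltas within tol of each other,
              // suppressing floating-point order effects
              bool better = (bi < 0) ? (d > best) : (d > best + tol);
              if (!ISNAN(d) && better) { best = d; bi = i; bj = j; bt = t; }
            }
          }
        if (bi < 0) return total();   // local maximum
        // acyclicity check on the selected move only
        bool ok = true;
        if (bt == 0) ok = !has_path(bj, bi);
        else if (bt == 2) {
          amat[bi + p * bj] = 0;
          ok = !has_path(bi, bj);
          amat[bi + p * bj] = 1;
        }
        if (!ok) { excl[bt + 3 * (bi + p * bj)] = 1; continue; }
        if (bt == 0) { amat[bi + p * bj] = 1; refresh(bj); }
        else if (bt == 1) { amat[bi + p * bj] = 0; refresh(bj); }
        else { amat[bi + p * bj] = 0; amat[bj + p * bi] = 1;
               refresh(bi); refresh(bj); }
        applied = true;
        break;
      }
      if (!applied) break;
    }
    return total();
  }

  // random constraint-respecting DAG layered over the mandatory edges
  void random_graph(const int* base, double q) {
    std::copy(base, base + p * p, amat.begin());
    std::vector<int> perm(p), rank(p);
    for (int i = 0; i < p; ++i) perm[i] = i;
    for (int i = p - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    for (int i = 0; i < p; ++i) rank[perm[i]] = i;
    for (int u = 0; u < p; ++u)
      for (int v = u + 1; v < p; ++v) {
        if (edge(u, v) || edge(v, u)) continue;
        if (unif_rand() >= q) continue;
        int a = (rank[u] < rank[v]) ? u : v;
        int b = (a == u) ? v : u;
        if (!allowed[a + p * b]) continue;
        if (lp[a + p * b] == R_NegInf) continue;
        if (has_path(b, a)) continue;
        amat[a + p * b] = 1;
      }
  }

  // apply `nmoves` uniformly chosen valid single-arc moves
  void jitter(int nmoves) {
    for (int m = 0; m < nmoves; ++m) {
      std::vector<int> mi, mj, mt;
      for (int i = 0; i < p; ++i)
        for (int j = 0; j < p; ++j) {
          if (i == j) continue;
          if (!edge(i, j) && !edge(j, i) && allowed[i + p * j] &&
              lp[i + p * j] != R_NegInf && !has_path(j, i)) {
            mi.push_back(i); mj.push_back(j); mt.push_back(0);
          }
          if (edge(i, j)) {
            if (!mustpair[i + p * j]) {
              mi.push_back(i); mj.push_back(j); mt.push_back(1);
            }
            if (allowed[j + p * i] && lp[j + p * i] != R_NegInf) {
              amat[i + p * j] = 0;
              bool ok = !has_path(i, j);
              amat[i + p * j] = 1;
              if (ok) { mi.push_back(i); mj.push_back(j); mt.push_back(2); }
            }
          }
        }
      if (mi.empty()) return;
      int k = (int)std::floor(unif_rand() * mi.size());
      if (k >= (int)mi.size()) k = (int)mi.size() - 1;
      int i = mi[k], j = mj[k], t = mt[k];
      if (t == 0) amat[i + p * j] = 1;
      else if (t == 1) amat[i + p * j] = 0;
      else { amat[i + p * j] = 0; amat[j + p * i] = 1; }
    }
  }
};

} // namespace

// Hill climbing with random and jitter restarts for Gaussian networks.
// C: crossproduct of cbind(1, X); start: starting adjacency (must contain the
// whitelist edges); allowed/mustpair/logprior encode the constraints.
// [[Rcpp::export]]
List cpp_hc_gauss(NumericMatrix C, int n, double pen, IntegerMatrix allowed,
                  IntegerMatrix mustpair, NumericMatrix logprior,
                  IntegerMatrix start, int random_restarts,
                  int jitter_restarts, int jitter_moves, double restart_q,
                  int maxit) {
  int p = start.nrow();
  HC hc(p, n, REAL(C), C.nrow(), pen, INTEGER(allowed), INTEGER(mustpair),
        REAL(logprior), maxit);
  hc.set_graph(INTEGER(start));
  double best_score = hc.climb();
  std::vector<int> best_amat = hc.amat;
  const double tol = 1e-9;
  bool best_na = ISNAN(best_score);
  for (int r = 0; r < random_restarts; ++r) {
    hc.random_graph(INTEGER(start), restart_q);
    std::vector<int> g = hc.amat;
    hc.set_graph(g.data());
    double s = hc.climb();
    if (!ISNAN(s) && (best_na || s > best_score + tol)) {
      best_score = s; best_amat = hc.amat; best_na = false;
    }
  }
  for (int r = 0; r < jitter_restarts; ++r) {
    if (best_na) break;
    hc.amat = best_amat;
    hc.jitter(jitter_moves);
    std::vector<int> g = hc.amat;
    hc.set_graph(g.data());
    double s = hc.climb();
    if (!ISNAN(s) && s > best_score + tol) {
      best_score = s; best_amat = hc.amat;
    }
  }
  IntegerMatrix out(p, p);
  std::copy(best_amat.begin(), best_amat.end(), INTEGER(out));
  return List::create(_["amat"] = out, _["score"] = best_score);
}
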