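// Core numerics for the z-score event-sequence model: expected-trajectory
// construction, per-visit stage-marginalised log-likelihood, and the
// remove/reinsert coordinate-ascent sequence optimizer. Everything here is
// called through thin R wrappers; stages are 0..E, event ids and sequence
// entries are 1-based to match the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// piecewise-linear expected z for each feature at stages 0..E:
// control points (0,0), (p_r, z_r) per threshold event, (E, z_max) unless
// the feature's last event sits at position E
static arma::mat traj_matrix(const std::vector<int>& S,
                             const std::vector<int>& evFeat,
                             const std::vector<double>& evZ,
                             const std::vector<double>& zmax, int F) {
  const int E = (int)S.size();
  std::vector<int> pos(E);
  for (int p = 0; p < E; ++p) pos[S[p] - 1] = p + 1;
  arma::mat G(F, E + 1);
  std::vector<std::pair<double, double>> pts;
  for (int i = 0; i < F; ++i) {
    pts.clear();
    pts.push_back(std::make_pair(0.0, 0.0));
    std::vector<std::pair<double, double>> mine;
    for (int e = 0; e < E; ++e)
      if (evFeat[e] == i + 1)
        mine.push_back(std::make_pair((double)pos[e], evZ[e]));
    std::sort(mine.begin(), mine.end());
    for (size_t m = 0; m < mine.size(); ++m) pts.push_back(mine[m]);
    if (pts.back().first < (double)E)
      pts.push_back(std::make_pair((double)E, zmax[i]));
    size_t seg = 0;
    for (int k = 0; k <= E; ++k) {
      while (seg + 2 < pts.size() && pts[seg + 1].first < (double)k) ++seg;
      const double x0 = pts[seg].first, y0 = pts[seg].second;
      const double x1 = pts[seg + 1].first, y1 = pts[seg + 1].second;
      G(i, k) = (k <= x0) ? y0
              : ((k >= x1) ? y1 : y0 + (k - x0) * (y1 - y0) / (x1 - x0));
    }
  }
  return G;
}

// per-visit log of the stage-marginalised likelihood under a uniform
// stage prior: log( (1/(E+1)) sum_k prod_i N(z_vi; g_ik, sigma_i) )
static arma::vec logmean_from_G(const arma::mat& Zs, const arma::vec& zz,
                                const arma::mat& G, const arma::vec& sigma,
                                double lconst) {
  arma::mat Gs = G.each_col() / sigma;
  arma::rowvec gg = 0.5 * arma::sum(arma::square(Gs), 0);
  arma::mat M = Zs * Gs;          // N x (E+1)
  M.each_row() -= gg;
  const double logE1 = std::log((double)G.n_cols);
  arma::vec mx = arma::max(M, 1);
  M.each_col() -= mx;
  return (lconst - logE1) - 0.5 * zz + mx + arma::log(arma::sum(arma::exp(M), 1));
}

// [[Rcpp::export]]
arma::mat cpp_traj(IntegerVector S, IntegerVector evFeat, NumericVector evZ,
                   NumericVector zmax, int F) {
  return traj_matrix(as<std::vector<int>>(S), as<std::vector<int>>(evFeat),
                     as<std::vector<double>>(evZ),
                     as<std::vector<double>>(zmax), F);
}

// [[Rcpp::export]]
arma::vec cpp_visit_logmean(const arma::mat& Z, IntegerVector S,
                            IntegerVector evFeat, NumericVector evZ,
                            NumericVector zmax, NumericVector sigma) {
  const int F = (int)Z.n_cols;
  arma::vec sig = as<arma::vec>(sigma);
  arma::mat Zs = Z.each_row() / sig.t();
  arma::vec zz = arma::sum(arma::square(Zs), 1);
  const double lconst = -arma::accu(arma::log(sig)) -
    0.5 * F * std::log(2.0 * M_PI);
  arma::mat G = traj_matrix(as<std::vector<int>>(S),
                            as<std::vector<int>>(evFeat),
                            as<std::vector<double>>(evZ),
                            as<std::vector<double>>(zmax), F);
  return logmean_from_G(Zs, zz, G, sig, lconst);
}

// weighted objective up to candidate-independent constants: for each
// visit, max_k + truncated log-sum-exp of the stage scores M(v,k) =
// (Zs Gs)(v,k) - gg(k); terms more than 34 log-units below the row
// maximum are dropped (beyond double resolution of the sum)
static double obj_fast(const arma::mat& Zs, const arma::vec& w,
                       const arma::mat& G, const arma::vec& sigma) {
  arma::mat Gs = G.each_col() / sigma;
  arma::rowvec gg = 0.5 * arma::sum(arma::square(Gs), 0);
  arma::mat M = Zs * Gs;
  M.each_row() -= gg;
  const arma::uword N = M.n_rows, E1 = M.n_cols;
  arma::vec mx = arma::max(M, 1);
  arma::vec s(N, arma::fill::zeros);
  for (arma::uword k = 0; k < E1; ++k) {
    const double* col = M.colptr(k);
    for (arma::uword v = 0; v < N; ++v) {
      const double d = col[v] - mx[v];
      if (d > -34.0) s[v] += std::exp(d);
    }
  }
  return arma::dot(w, mx + arma::log(s));
}

// weighted coordinate ascent: repeatedly remove each event and reinsert it
// at its best admissible position (within-feature threshold order is a hard
// constraint) until no move improves the weighted log-likelihood
// [[Rcpp::export]]
List cpp_optimize(const arma::mat& Z, IntegerVector S0, IntegerVector evFeat,
                  NumericVector evZ, NumericVector zmax, NumericVector sigma,
                  NumericVector w, int max_sweeps) {
  const int F = (int)Z.n_cols;
  const int E = S0.size();
  std::vector<int> S = as<std::vector<int>>(S0);
  std::vector<int> feat = as<std::vector<int>>(evFeat);
  std::vector<double> zv = as<std::vector<double>>(evZ);
  std::vector<double> zm = as<std::vector<double>>(zmax);
  arma::vec sig = as<arma::vec>(sigma);
  arma::vec wv = as<arma::vec>(w);
  arma::mat Zs = Z.each_row() / sig.t();
  arma::vec zz = arma::sum(arma::square(Zs), 1);
  const double lconst = -arma::accu(arma::log(sig)) -
    0.5 * F * std::log(2.0 * M_PI);
  // candidate-independent part of the weighted log-likelihood
  const double base = arma::accu(wv) * (lconst - std::log((double)(E + 1))) -
    0.5 * arma::dot(wv, zz);

  const double obj0 = obj_fast(Zs, wv, traj_matrix(S, feat, zv, zm, F), sig);
  double cur = obj0;
  int sweeps = 0;
  bool improved = true;
  std::vector<int> reduced(E - 1), cand(E);
  while (improved && sweeps < max_sweeps) {
    improved = false;
    ++sweeps;
    for (int e = 1; e <= E; ++e) {
      // drop event e
      int at = -1;
      for (int p = 0, q = 0; p < E; ++p) {
        if (S[p] == e) { at = p; continue; }
        reduced[q++] = S[p];
      }
      // admissible insertion range given same-feature threshold order
      int lo = 0, hi = E - 1;
      for (int q = 0; q < E - 1; ++q) {
        if (feat[reduced[q] - 1] != feat[e - 1]) continue;
        if (zv[reduced[q] - 1] < zv[e - 1]) lo = q + 1;
        else if (zv[reduced[q] - 1] > zv[e - 1] && q < hi) { hi = q; break; }
      }
      double best = cur;
      int best_j = -1;
      for (int j = lo; j <= hi; ++j) {
        for (int q = 0; q < j; ++q) cand[q] = reduced[q];
        cand[j] = e;
        for (int q = j; q < E - 1; ++q) cand[q + 1] = reduced[q];
        if (j == at) continue;  // unchanged sequence
        const double obj = obj_fast(Zs, wv, traj_matrix(cand, feat, zv, zm, F),
                                    sig);
        if (obj > best + 1e-10) { best = obj; best_j = j; }
      }
      if (best_j >= 0) {
        for (int q = 0; q < best_j; ++q) S[q] = reduced[q];
        S[best_j] = e;
        for (int q = best_j; q < E - 1; ++q) S[q + 1] = reduced[q];
        cur = best;
        improved = true;
      }
    }
  }
  return List::create(_["sequence"] = wrap(S), _["objective"] = cur + base,
                      _["sweeps"] = sweeps, _["initial"] = obj0 + base);
}
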