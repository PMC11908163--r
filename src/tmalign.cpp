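// TM-score refinement for a fixed residue correspondence: iterative Kabsch
// re-superposition on shrinking close-pair subsets, seeded from several
// deterministic contiguous fragments. Mirrors the R-level definitions; kept
// in C++ because all-vs-all TM matrices call this in a tight loop.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Rigid transform (R, t) minimizing RMSD of R*p + t onto q over the rows in
// idx. Returns false if degenerate.
static bool kabsch_sub(const mat &P, const mat &Q, const uvec &idx,
                       mat &R, rowvec &t) {
  mat Ps = P.rows(idx), Qs = Q.rows(idx);
  rowvec pbar = mean(Ps, 0), qbar = mean(Qs, 0);
  Ps.each_row() -= pbar;
  Qs.each_row() -= qbar;
  mat H = Ps.t() * Qs; // 3x3
  mat U, V;
  vec s;
  if (!svd(U, s, V, H)) return false;
  double d = det(V * U.t());
  mat D = eye(3, 3);
  D(2, 2) = (d < 0) ? -1.0 : 1.0;
  R = V * D * U.t();
  t = qbar - pbar * R.t();
  return true;
}

// Weighted variant over all rows.
static bool kabsch_weighted(const mat &P, const mat &Q, const vec &w,
                            mat &R, rowvec &t) {
  double W = accu(w);
  if (W <= 0) return false;
  rowvec pbar = (w.t() * P) / W, qbar = (w.t() * Q) / W;
  mat Ps = P.each_row() - pbar;
  mat Qs = Q.each_row() - qbar;
  mat H = (Ps.each_col() % w).t() * Qs;
  mat U, V;
  vec s;
  if (!svd(U, s, V, H)) return false;
  double d = det(V * U.t());
  mat D = eye(3, 3);
  D(2, 2) = (d < 0) ? -1.0 : 1.0;
  R = V * D * U.t();
  t = qbar - pbar * R.t();
  return true;
}

static vec dists2(const mat &P, const mat &Q, const mat &R, const rowvec &t) {
  mat Pt = P * R.t();
  Pt.each_row() += t;
  return sum(square(Pt - Q), 1);
}

static double tm_from_d2(const vec &d2, double d0, int Lnorm) {
  return accu(1.0 / (1.0 + d2 / (d0 * d0))) / Lnorm;
}

// One refinement run from an initial superposition on rows `init_idx`:
// the shrinking-cutoff subset schedule, followed by an iteratively
// reweighted Kabsch polish with weights w_i = 1/(1 + d_i^2/d0^2)^2 (the
// gradient weights of the TM objective, whose fixed point is a stationary
// point of the TM-score itself).
static double refine_from(const mat &P, const mat &Q, double d0, int Lnorm,
                          const uvec &init_idx, int n_iter) {
  int n = P.n_rows;
  mat R;
  rowvec t;
  if (!kabsch_sub(P, Q, init_idx, R, t)) return 0.0;
  vec d2 = dists2(P, Q, R, t);
  double best = tm_from_d2(d2, d0, Lnorm);
  vec best_d2 = d2;
  double cut_hi = std::max(d0, 4.5);
  for (int it = 1; it <= n_iter; ++it) {
    double cutoff = cut_hi - (cut_hi - d0) * (it - 1) / std::max(1, n_iter - 1);
    uvec keep = find(d2 < cutoff * cutoff);
    if (keep.n_elem < 3) {
      keep = sort_index(d2);
      keep = keep.head(std::min(3, n));
    }
    if (!kabsch_sub(P, Q, keep, R, t)) break;
    d2 = dists2(P, Q, R, t);
    double s = tm_from_d2(d2, d0, Lnorm);
    if (s > best) { best = s; best_d2 = d2; }
  }
  d2 = best_d2;
  double d02 = d0 * d0;
  for (int it = 0; it < 40; ++it) {
    vec w = 1.0 / square(1.0 + d2 / d02);
    if (!kabsch_weighted(P, Q, w, R, t)) break;
    d2 = dists2(P, Q, R, t);
    double s = tm_from_d2(d2, d0, Lnorm);
    if (s > best + 1e-12) best = s; else break;
  }
  return best;
}

// Deterministic fragment seeds: the full range plus contiguous windows of
// length n/2 and n/4 slid at stride ~n/8 — gapless-threading-style starts
// that let the refinement escape the basin of the all-pair superposition.
static std::vector<uvec> seed_ranges_cpp(int n) {
  std::vector<uvec> out;
  out.push_back(regspace<uvec>(0, n - 1));
  for (int len : {n / 2, n / 4}) {
    if (len < 4) continue;
    int stride = std::max(3, n / 8);
    for (int off = 0; off + len <= n; off += stride)
      out.push_back(regspace<uvec>(off, off + len - 1));
    if ((n - len) % stride != 0)
      out.push_back(regspace<uvec>(n - len, n - 1));
  }
  return out;
}

// IRLS polish from an explicit initial rotation (centroid-aligned).
static double irls_from_rotation(const mat &P, const mat &Q, const mat &R0,
                                 double d0, int Lnorm) {
  rowvec pbar = mean(P, 0), qbar = mean(Q, 0);
  mat R = R0;
  rowvec t = qbar - pbar * R.t();
  vec d2 = dists2(P, Q, R, t);
  double best = tm_from_d2(d2, d0, Lnorm);
  double d02 = d0 * d0;
  for (int it = 0; it < 60; ++it) {
    vec w = 1.0 / square(1.0 + d2 / d02);
    if (!kabsch_weighted(P, Q, w, R, t)) break;
    d2 = dists2(P, Q, R, t);
    double s = tm_from_d2(d2, d0, Lnorm);
    if (s > best + 1e-12) best = s; else break;
  }
  return best;
}

// The 24 proper rotations of the octahedral group (signed axis permutations
// with determinant +1), used as coarse global starts.
static const std::vector<mat> &octahedral_rotations() {
  static std::vector<mat> rots;
  if (rots.empty()) {
    int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
    for (auto &pm : perms)
      for (int sx = -1; sx <= 1; sx += 2)
        for (int sy = -1; sy <= 1; sy += 2)
          for (int sz = -1; sz <= 1; sz += 2) {
            mat R(3, 3, fill::zeros);
            R(0, pm[0]) = sx; R(1, pm[1]) = sy; R(2, pm[2]) = sz;
            if (det(R) > 0.5) rots.push_back(R);
          }
  }
  return rots;
}

// [[Rcpp::export]]
double tm_refine_cpp(const arma::mat &P, const arma::mat &Q, double d0,
                     int Lnorm, int n_iter) {
  double best = 0.0;
  for (const uvec &idx : seed_ranges_cpp(P.n_rows))
    best = std::max(best, refine_from(P, Q, d0, Lnorm, idx, n_iter));
  // weakly similar pairs can have the optimal superposition in a basin no
  // contiguous fragment reaches: sweep coarse global rotation starts
  if (best < 0.6)
    for (const mat &R0 : octahedral_rotations())
      best = std::max(best, irls_from_rotation(P, Q, R0, d0, Lnorm));
  return best;
}
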