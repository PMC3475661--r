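#include <Rcpp.h>
using namespace Rcpp;

// Mean-matched subset sampler for the rank-space slope test.
//
// A sample qualifies when the RMSD between its mean (x, y) ranks and the
// reference subset's mean ranks is at most `tol`:
//   RMSD(S) = sqrt( ((mx(S)-tx)^2 + (my(S)-ty)^2) / 2 ).
// Naive rejection is intractable when the reference subset is off-centre
// (e.g. the TF set's low expression), so each sample is produced by greedy
// descent from a uniform subset into the tolerance ball, followed by
// tolerance-preserving randomizing swaps for decorrelation. All randomness
// comes from R's RNG, so results are reproducible under set.seed().

static inline int rand_below(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static inline double sq_rmsd(double mx, double my, double tx, double ty) {
  const double dx = mx - tx, dy = my - ty;
  return 0.5 * (dx * dx + dy * dy);
}

// [[Rcpp::export]]
IntegerMatrix cpp_sample_matched_swap(NumericVector x, NumericVector y,
                                      double target_mx, double target_my,
                                      int m, double tol, int n_samples,
                                      int k_randomize, int max_greedy,
                                      int max_randomize_proposals) {
  const int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  if (m < 1 || m >= n) stop("subset size must lie in [1, n-1]");
  if (tol <= 0) stop("tolerance must be positive");

  const double tol2 = tol * tol;
  IntegerMatrix out(n_samples, m);
  // perm[0..m-1] are current members, perm[m..n-1] the outsiders
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;

  for (int s = 0; s < n_samples; ++s) {
    // fresh uniform m-subset via partial Fisher-Yates
    for (int t = 0; t < m; ++t) {
      int j = t + rand_below(n - t);
      std::swap(perm[t], perm[j]);
    }
    double sx = 0.0, sy = 0.0;
    for (int t = 0; t < m; ++t) { sx += x[perm[t]]; sy += y[perm[t]]; }
    double mx = sx / m, my = sy / m;
    double d2 = sq_rmsd(mx, my, target_mx, target_my);

    // greedy descent: accept only swaps that reduce the squared RMSD
    int tries = 0;
    while (d2 > tol2) {
      if (++tries > max_greedy)
        stop("matched swap sampler failed to reach the RMSD tolerance");
      const int i = rand_below(m);
      const int j = m + rand_below(n - m);
      const double nmx = mx + (x[perm[j]] - x[perm[i]]) / m;
      const double nmy = my + (y[perm[j]] - y[perm[i]]) / m;
      const double nd2 = sq_rmsd(nmx, nmy, target_mx, target_my);
      if (nd2 < d2) {
        std::swap(perm[i], perm[j]);
        mx = nmx; my = nmy; d2 = nd2;
      }
    }

    // randomizing phase: symmetric swap proposals, accepted iff the sample
    // stays inside the tolerance ball
    int accepted = 0, proposals = 0;
    while (accepted < k_randomize && proposals < max_randomize_proposals) {
      ++proposals;
      const int i = rand_below(m);
      const int j = m + rand_below(n - m);
      const double nmx = mx + (x[perm[j]] - x[perm[i]]) / m;
      const double nmy = my + (y[perm[j]] - y[perm[i]]) / m;
      const double nd2 = sq_rmsd(nmx, nmy, target_mx, target_my);
      if (nd2 <= tol2) {
        std::swap(perm[i], perm[j]);
        mx = nmx; my = nmy; d2 = nd2;
        ++accepted;
      }
    }

    for (int t = 0; t < m; ++t) out(s, t) = perm[t] + 1;
  }
  return out;
}

// Least-squares slope of y on x per row of index matrix (1-based indices).
// [[Rcpp::export]]
NumericVector cpp_subset_slopes(NumericVector x, NumericVector y,
                                IntegerMatrix idx) {
  const int ns = idx.nrow(), m = idx.ncol();
  NumericVector slopes(ns);
  for (int s = 0; s < ns; ++s) {
    double sx = 0, sy = 0, sxx = 0, sxy = 0;
    for (int t = 0; t < m; ++t) {
      const double xv = x[idx(s, t) - 1], yv = y[idx(s, t) - 1];
      sx += xv; sy += yv; sxx += xv * xv; sxy += xv * yv;
    }
    const double vx = sxx - sx * sx / m;
    slopes[s] = (vx > 0) ? (sxy - sx * sy / m) / vx : NA_REAL;
  }
  return slopes;
}
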