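#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Artificially-centered hit-and-run core.
//
// Walks the flux polytope {v : Sv = 0, lb <= v <= ub}. Each step picks a
// direction from a randomly chosen warmup point to the running center of
// all visited points, finds the feasible segment from the bound crossings,
// and jumps to a uniform point on it. Every `proj_period` recorded samples
// the state is re-projected onto the affine solution set of Sv = 0
// (v -> xp + P (v - xp)) to cancel accumulated drift. Uses R's RNG, so
// set.seed() in R makes runs reproducible.
//
// warmup: n x W matrix of feasible starting points (FVA vertices pulled
// toward their centroid). P: n x n projector onto the null space of S over
// the free coordinates (zero rows/cols for fixed ones); xp: a particular
// feasible point.
// [[Rcpp::export]]
NumericMatrix achr_core(NumericMatrix warmup, NumericVector lb,
                        NumericVector ub, NumericVector start,
                        NumericVector center0, double center_count0,
                        int n_keep, int thin, NumericMatrix P,
                        NumericVector xp, int proj_period, double dir_tol,
                        double inset) {
  const int n = warmup.nrow();
  const int W = warmup.ncol();
  NumericMatrix out(n_keep, n);
  std::vector<double> x(start.begin(), start.end());
  std::vector<double> center(center0.begin(), center0.end());
  std::vector<double> d(n), tmp(n);
  double cnt = center_count0;
  int kept = 0, step_in_sample = 0, fails = 0, empty_segments = 0;

  while (kept < n_keep) {
    // direction: random stored point minus the running center
    int u = (int)std::floor(unif_rand() * W);
    if (u == W) u = W - 1;
    double nrm = 0.0;
    for (int i = 0; i < n; ++i) {
      d[i] = warmup(i, u) - center[i];
      nrm += d[i] * d[i];
    }
    nrm = std::sqrt(nrm);
    if (nrm < dir_tol) {
      if (++fails >= 100)
        stop("degenerate polytope: 100 consecutive zero-norm directions");
      continue;
    }
    fails = 0;
    for (int i = 0; i < n; ++i) d[i] /= nrm;

    // feasible segment [tmin, tmax] from the bound crossings
    double tmin = -R_PosInf, tmax = R_PosInf;
    for (int i = 0; i < n; ++i) {
      if (std::fabs(d[i]) < dir_tol) continue;
      double lo = (lb[i] - x[i]) / d[i];
      double hi = (ub[i] - x[i]) / d[i];
      if (d[i] > 0) {
        if (lo > tmin) tmin = lo;
        if (hi < tmax) tmax = hi;
      } else {
        if (hi > tmin) tmin = hi;
        if (lo < tmax) tmax = lo;
      }
    }
    if (!(tmax > tmin) || !R_finite(tmin) || !R_finite(tmax)) {
      // a chain wedged in a corner by roundoff recovers by restarting
      // from a feasible warmup point
      if (++empty_segments >= 1000) {
        for (int i = 0; i < n; ++i) x[i] = warmup(i, u);
        empty_segments = 0;
      }
      continue;
    }
    empty_segments = 0;
    double width = tmax - tmin;
    double t = tmin + unif_rand() * width;
    // ties at the bounds resolved toward the interior
    double eps = inset * std::max(width, 1.0);
    if (t < tmin + eps) t = tmin + eps;
    if (t > tmax - eps) t = tmax - eps;

    for (int i = 0; i < n; ++i) x[i] += t * d[i];
    // running center over every visited point
    cnt += 1.0;
    for (int i = 0; i < n; ++i)
      center[i] += (x[i] - center[i]) / cnt;

    if (++step_in_sample >= thin) {
      step_in_sample = 0;
      for (int i = 0; i < n; ++i) out(kept, i) = x[i];
      ++kept;
      if (proj_period > 0 && kept % proj_period == 0) {
        // re-project the state AND the running center onto the affine
        // solution set of Sv = 0. The center must be projected too:
        // off-subspace error stored there feeds back into every direction
        // and grows geometrically. Residual bound excursions after
        // projection are O(1e-12) and the next accepted step moves back
        // inside, so no clamping (clamping would push the state off the
        // subspace and can wedge it in an infeasible corner).
        for (int i = 0; i < n; ++i) tmp[i] = x[i] - xp[i];
        for (int i = 0; i < n; ++i) {
          double s = 0.0;
          for (int j = 0; j < n; ++j) s += P(i, j) * tmp[j];
          x[i] = xp[i] + s;
        }
        for (int i = 0; i < n; ++i) tmp[i] = center[i] - xp[i];
        for (int i = 0; i < n; ++i) {
          double s = 0.0;
          for (int j = 0; j < n; ++j) s += P(i, j) * tmp[j];
          center[i] = xp[i] + s;
        }
      }
    }
  }
  return out;
}
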