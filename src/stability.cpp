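#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// State points are stored one per COLUMN (dims x n): a point is contiguous
// in memory, which keeps the all-points scans of Wolf's algorithm cache
// friendly.
static inline double col_dist(const NumericMatrix &pts, int i, int j) {
  const int d = pts.nrow();
  const double *a = &pts(0, i), *b = &pts(0, j);
  double s = 0.0;
  for (int c = 0; c < d; ++c) {
    double t = a[c] - b[c];
    s += t * t;
  }
  return std::sqrt(s);
}

// Trace distances between a reference trajectory segment and a set of
// neighbour segments: out(s, i) = || pts[, ref+s] - pts[, nb_i+s] ||.
// Indices are 0-based; the caller guarantees ref+horizon and nb+horizon are
// in range.
// [[Rcpp::export]]
NumericMatrix cpp_trace_distances(const NumericMatrix &pts,
                                  int ref,
                                  const IntegerVector &nb,
                                  int horizon) {
  const int nnb = nb.size();
  NumericMatrix out(horizon + 1, nnb);
  for (int i = 0; i < nnb; ++i) {
    int b = nb[i];
    for (int s = 0; s <= horizon; ++s) {
      out(s, i) = col_dist(pts, ref + s, b + s);
    }
  }
  return out;
}

// Distances from one point to a candidate set (0-based column indices).
// [[Rcpp::export]]
NumericVector cpp_point_distances(const NumericMatrix &pts,
                                  int ref,
                                  const IntegerVector &cand) {
  const int n = cand.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = col_dist(pts, ref, cand[i]);
  return out;
}

// Wolf's trajectory-tracking estimate of the largest Lyapunov exponent.
//
// pts:     embedded trajectory, one state point per column
// dt:      time between consecutive points (s)
// evolve:  evolution time between replacement attempts, in samples
// theiler: minimum temporal separation (samples) between fiducial and
//          neighbour
// dmin, dmax: replacement search annulus
// max_angle:  maximum replacement angle (radians)
//
// Accumulates log(L'/L) at each evolution step and divides by elapsed time.
// [[Rcpp::export]]
List cpp_wolf(const NumericMatrix &pts,
              double dt,
              int evolve,
              int theiler,
              double dmin,
              double dmax,
              double max_angle) {
  const int n = pts.ncol();
  const int d = pts.nrow();
  if (n < 2 * evolve + theiler + 2) {
    return List::create(_["lambda"] = NA_REAL, _["n_steps"] = 0);
  }

  int cur = 0;
  const int limit = n - evolve;  // both segments must evolve in range

  // nearest point to `fid` outside the Theiler window with distance above
  // the noise floor
  auto find_nearest = [&](int fid) {
    int best = -1;
    double bestd = R_PosInf;
    for (int j = 0; j < limit; ++j) {
      if (std::abs(j - fid) <= theiler) continue;
      double dist = col_dist(pts, fid, j);
      if (dist > dmin && dist < bestd) {
        bestd = dist;
        best = j;
      }
    }
    return best;
  };

  int nb = find_nearest(cur);
  if (nb < 0) return List::create(_["lambda"] = NA_REAL, _["n_steps"] = 0);

  double total_log = 0.0;
  double total_time = 0.0;
  int steps = 0;

  while (cur + evolve < limit) {
    if (nb + evolve >= n) {            // retained neighbour ran out of data
      nb = find_nearest(cur);
      if (nb < 0) break;
    }
    double L = col_dist(pts, cur, nb);
    cur += evolve;
    nb += evolve;
    double Lp = col_dist(pts, cur, nb);
    if (L > dmin && Lp > 0.0) {
      total_log += std::log(Lp / L);
      total_time += evolve * dt;
      ++steps;
    }

    // replacement: a closer neighbour preserving orientation (smallest
    // angle w.r.t. the current separation vector) within [dmin, dmax]
    double best_ang = R_PosInf, best_ang_dist = R_PosInf;
    int best_ang_idx = -1;
    double best_dist = R_PosInf;
    int best_dist_idx = -1;

    const double *pc = &pts(0, cur), *pn = &pts(0, nb);
    double sep_norm = col_dist(pts, cur, nb);
    for (int j = 0; j < limit; ++j) {
      if (std::abs(j - cur) <= theiler) continue;
      double dist = col_dist(pts, cur, j);
      if (dist <= dmin || dist >= dmax) continue;
      if (dist < best_dist) {
        best_dist = dist;
        best_dist_idx = j;
      }
      if (sep_norm > 0.0) {
        const double *pj = &pts(0, j);
        double dot = 0.0;
        for (int c = 0; c < d; ++c) dot += (pj[c] - pc[c]) * (pn[c] - pc[c]);
        double ca = dot / (dist * sep_norm);
        if (ca > 1.0) ca = 1.0;
        if (ca < -1.0) ca = -1.0;
        double ang = std::acos(ca);
        if (ang <= max_angle && (ang < best_ang ||
            (ang == best_ang && dist < best_ang_dist))) {
          best_ang = ang;
          best_ang_dist = dist;
          best_ang_idx = j;
        }
      }
    }
    if (best_ang_idx >= 0) {
      nb = best_ang_idx;
    } else if (best_dist_idx >= 0) {
      nb = best_dist_idx;
    }
    // else: keep evolving the current neighbour
  }

  double lambda = (total_time > 0.0) ? total_log / total_time : NA_REAL;
  return List::create(_["lambda"] = lambda, _["n_steps"] = steps);
}
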