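#include <Rcpp.h>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

// Best-of-restarts Lloyd k-means with Hamerly distance bounds.
//
// X: n x p data matrix; seed_idx: n_starts x k matrix of 1-based row indices
// used as the initial centroids of each run. Each run iterates
// assignment/centroid updates to a fixed point (at most max_iter sweeps),
// using one upper and one lower distance bound per point to skip most
// distance computations (Hamerly's acceleration; the fixed point reached is
// a Lloyd fixed point). An emptied cluster is re-seeded with the point
// farthest from the centroid of the largest cluster (never a point that is
// itself a singleton cluster). Returns the assignment of the minimum
// within-deviance run.

static inline double dist_pt(const double *a, const double *b, int p) {
  double dd = 0.0;
  for (int d = 0; d < p; ++d) {
    const double t = a[d] - b[d];
    dd += t * t;
  }
  return std::sqrt(dd);
}

// [[Rcpp::export]]
List ht_kmeans_best(NumericMatrix X, IntegerMatrix seed_idx, int max_iter) {
  const int n = X.nrow(), p = X.ncol();
  const int n_starts = seed_idx.nrow(), k = seed_idx.ncol();
  std::vector<double> xv(static_cast<size_t>(n) * p);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < p; ++d) xv[static_cast<size_t>(i) * p + d] = X(i, d);

  std::vector<double> centers(k * p), newc(k * p), csum(k * p), ctr(p);
  std::vector<double> ub(n), lb(n), shift(k), sclose(k);
  std::vector<int> cl(n), best_cl(n), sizes(k);
  double best_within = R_PosInf;
  int best_start = -1;

  for (int s = 0; s < n_starts; ++s) {
    for (int j = 0; j < k; ++j) {
      const int r = seed_idx(s, j) - 1;
      for (int d = 0; d < p; ++d)
        centers[j * p + d] = xv[static_cast<size_t>(r) * p + d];
    }
    // initial full assignment with both bounds
    std::fill(csum.begin(), csum.end(), 0.0);
    std::fill(sizes.begin(), sizes.end(), 0);
    for (int i = 0; i < n; ++i) {
      const double *xi = &xv[static_cast<size_t>(i) * p];
      double d1 = DBL_MAX, d2 = DBL_MAX;
      int bj = 0;
      for (int j = 0; j < k; ++j) {
        const double d = dist_pt(xi, &centers[static_cast<size_t>(j) * p], p);
        if (d < d1) { d2 = d1; d1 = d; bj = j; }
        else if (d < d2) { d2 = d; }
      }
      cl[i] = bj; ub[i] = d1; lb[i] = d2;
      sizes[bj]++;
      for (int d = 0; d < p; ++d) csum[bj * p + d] += xi[d];
    }

    for (int it = 0; it < max_iter; ++it) {
      // empty clusters: re-seed with the farthest point from the largest
      // cluster's centroid, then force a full rescan of the bounds
      bool rebuilt = false;
      for (;;) {
        int empty = -1;
        for (int j = 0; j < k; ++j) if (sizes[j] == 0) { empty = j; break; }
        if (empty < 0) break;
        int big = 0;
        for (int j = 1; j < k; ++j) if (sizes[j] > sizes[big]) big = j;
        for (int d = 0; d < p; ++d) ctr[d] = csum[big * p + d] / sizes[big];
        double fard = -1.0;
        int far = -1;
        for (int i = 0; i < n; ++i) {
          if (sizes[cl[i]] == 1) continue;
          const double d = dist_pt(&xv[static_cast<size_t>(i) * p], ctr.data(), p);
          if (d > fard) { fard = d; far = i; }
        }
        const double *xf = &xv[static_cast<size_t>(far) * p];
        sizes[cl[far]]--;
        for (int d = 0; d < p; ++d) csum[cl[far] * p + d] -= xf[d];
        cl[far] = empty;
        sizes[empty] = 1;
        for (int d = 0; d < p; ++d) csum[empty * p + d] = xf[d];
        rebuilt = true;
      }
      // centroid update, recording how far each centroid moved
      double max_shift = 0.0;
      for (int j = 0; j < k; ++j) {
        for (int d = 0; d < p; ++d) newc[j * p + d] = csum[j * p + d] / sizes[j];
        shift[j] = dist_pt(&centers[static_cast<size_t>(j) * p],
                           &newc[static_cast<size_t>(j) * p], p);
        if (shift[j] > max_shift) max_shift = shift[j];
      }
      std::copy(newc.begin(), newc.end(), centers.begin());
      if (rebuilt) {
        for (int i = 0; i < n; ++i) { ub[i] = DBL_MAX; lb[i] = -DBL_MAX; }
      } else {
        if (max_shift == 0.0 && it > 0) break;
        for (int i = 0; i < n; ++i) {
          ub[i] += shift[cl[i]];
          lb[i] -= max_shift;
        }
      }
      // half the distance from each centroid to its nearest other centroid
      for (int j = 0; j < k; ++j) {
        double m = DBL_MAX;
        for (int j2 = 0; j2 < k; ++j2) {
          if (j2 == j) continue;
          const double d = dist_pt(&centers[static_cast<size_t>(j) * p],
                                   &centers[static_cast<size_t>(j2) * p], p);
          if (d < m) m = d;
        }
        sclose[j] = 0.5 * m;
      }
      int changed = 0;
      for (int i = 0; i < n; ++i) {
        const double m = std::max(sclose[cl[i]], lb[i]);
        if (ub[i] <= m) continue;
        const double *xi = &xv[static_cast<size_t>(i) * p];
        double d1 = dist_pt(xi, &centers[static_cast<size_t>(cl[i]) * p], p);
        ub[i] = d1;
        if (d1 <= m) continue;
        double d2 = DBL_MAX;
        int bj = cl[i];
        for (int j = 0; j < k; ++j) {
          if (j == cl[i]) continue;
          const double d = dist_pt(xi, &centers[static_cast<size_t>(j) * p], p);
          if (d < d1) { d2 = d1; d1 = d; bj = j; }
          else if (d < d2) { d2 = d; }
        }
        lb[i] = d2;
        if (bj != cl[i]) {
          sizes[cl[i]]--;
          sizes[bj]++;
          for (int d = 0; d < p; ++d) {
            csum[cl[i] * p + d] -= xi[d];
            csum[bj * p + d] += xi[d];
          }
          cl[i] = bj;
          ub[i] = d1;
          changed++;
        }
      }
      if (changed == 0 && !rebuilt) break;
    }
    // exact within-deviance about the centroids implied by the assignment
    std::fill(csum.begin(), csum.end(), 0.0);
    std::fill(sizes.begin(), sizes.end(), 0);
    for (int i = 0; i < n; ++i) {
      sizes[cl[i]]++;
      for (int d = 0; d < p; ++d)
        csum[cl[i] * p + d] += xv[static_cast<size_t>(i) * p + d];
    }
    double within = 0.0;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < p; ++d) {
        const double t = xv[static_cast<size_t>(i) * p + d] -
          csum[cl[i] * p + d] / sizes[cl[i]];
        within += t * t;
      }
    if (within < best_within) {
      best_within = within;
      best_cl = cl;
      best_start = s;
    }
  }
  return List::create(_["assignments"] = IntegerVector(best_cl.begin(), best_cl.end()),
                      _["within"] = best_within,
                      _["best_start"] = best_start + 1);
}
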