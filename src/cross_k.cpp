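#include <Rcpp.h>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Fraction of the circumference of the circle centred at (x, y) with radius t
// that lies inside the rectangle [x0, x1] x [y0, y1].  The rectangle is the
// intersection of four half-planes, so the excluded arc is the union of (at
// most four) arcs, one per edge; arcs of opposite edges never overlap (each
// half-angle is <= pi/2) and adjacent arcs overlap exactly when the circle
// reaches past the shared corner, so inclusion-exclusion with the four corner
// terms is exact for every t.
static double circle_inside_fraction(double x, double y, double t,
                                     double x0, double x1,
                                     double y0, double y1) {
  const double dl = x - x0, dr = x1 - x, dd = y - y0, du = y1 - y;
  const double al = dl < t ? std::acos(dl / t) : 0.0;
  const double ar = dr < t ? std::acos(dr / t) : 0.0;
  const double ad = dd < t ? std::acos(dd / t) : 0.0;
  const double au = du < t ? std::acos(du / t) : 0.0;
  double exterior = 2.0 * (al + ar + ad + au);
  exterior -= std::max(0.0, al + ad - M_PI_2);
  exterior -= std::max(0.0, ad + ar - M_PI_2);
  exterior -= std::max(0.0, ar + au - M_PI_2);
  exterior -= std::max(0.0, au + al - M_PI_2);
  return 1.0 - exterior / (2.0 * M_PI);
}

// Weighted cumulative pair counts for the cross-type K estimator.
// For every ordered pair (a in pattern i, b in pattern j) with d(a,b) <= max
// radius, accumulate the edge-correction weight into the smallest radius bin
// with radii[k] >= d; the cumulative sum over bins gives
// sum_{a,b} 1[d <= r] e(a, b) per radius.  correction: 0 = none,
// 1 = translation, 2 = isotropic (Ripley; circle centred on the i-point).
// When self is true the two patterns are the same vector and identical
// indices (zero-distance self matches) are skipped.
// [[Rcpp::export]]
NumericVector cross_pair_counts(NumericVector xi, NumericVector yi,
                                NumericVector xj, NumericVector yj,
                                NumericVector radii,
                                double x0, double x1, double y0, double y1,
                                int correction, bool self) {
  const int ni = xi.size(), nj = xj.size(), nr = radii.size();
  NumericVector bins(nr);
  const double rmax = radii[nr - 1];
  const double wx = x1 - x0, wy = y1 - y0;
  const double area = wx * wy;
  for (int a = 0; a < ni; ++a) {
    const double xa = xi[a], ya = yi[a];
    for (int b = 0; b < nj; ++b) {
      if (self && a == b) continue;
      const double dx = xj[b] - xa, dy = yj[b] - ya;
      const double d = std::sqrt(dx * dx + dy * dy);
      if (d > rmax) continue;
      double w = 1.0;
      if (correction == 1) {
        w = area / ((wx - std::fabs(dx)) * (wy - std::fabs(dy)));
      } else if (correction == 2 && d > 0.0) {
        const double f = circle_inside_fraction(xa, ya, d, x0, x1, y0, y1);
        if (f > 0.0) w = 1.0 / f;
      }
      // first bin with radii[k] >= d
      const int k = std::lower_bound(radii.begin(), radii.end(), d) -
        radii.begin();
      if (k < nr) bins[k] += w;
    }
  }
  for (int k = 1; k < nr; ++k) bins[k] += bins[k - 1];
  return bins;
}

// Unnormalized disc-kernel density of a point pattern, evaluated at the
// centres of an nx x ny pixel grid over [x0, x1] x [y0, y1]: the count of
// points within `radius` of each pixel centre.  Column-major with x varying
// over rows (matrix[ix, iy]).
// [[Rcpp::export]]
NumericMatrix disc_kernel_counts(NumericVector x, NumericVector y,
                                 double radius, int nx, int ny,
                                 double x0, double x1,
                                 double y0, double y1) {
  NumericMatrix out(nx, ny);
  const int n = x.size();
  if (n == 0) return out;
  const double px = (x1 - x0) / nx, py = (y1 - y0) / ny;
  const double r2 = radius * radius;
  for (int p = 0; p < n; ++p) {
    // restrict to the pixel-index window the disc can touch
    const int ix_lo = std::max(0, (int)std::floor((x[p] - radius - x0) / px) - 1);
    const int ix_hi = std::min(nx - 1, (int)std::ceil((x[p] + radius - x0) / px));
    const int iy_lo = std::max(0, (int)std::floor((y[p] - radius - y0) / py) - 1);
    const int iy_hi = std::min(ny - 1, (int)std::ceil((y[p] + radius - y0) / py));
    for (int iy = iy_lo; iy <= iy_hi; ++iy) {
      const double cy = y0 + (iy + 0.5) * py;
      const double dy = cy - y[p];
      for (int ix = ix_lo; ix <= ix_hi; ++ix) {
        const double cx = x0 + (ix + 0.5) * px;
        const double dx = cx - x[p];
        if (dx * dx + dy * dy <= r2) out(ix, iy) += 1.0;
      }
    }
  }
  return out;
}
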