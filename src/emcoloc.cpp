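#include <Rcpp.h>
using namespace Rcpp;

// Enumerate all (j, q) cross-label pairs with r_lo <= d < r_hi.
// Indices are 1-based, ordered by (j, q). Distances are returned for audit.
// [[Rcpp::export]]
List cross_pairs_cpp(NumericVector xa, NumericVector ya,
                     NumericVector xb, NumericVector yb,
                     double rlo, double rhi) {
  const int na = xa.size(), nb = xb.size();
  const double lo2 = rlo * rlo, hi2 = rhi * rhi;
  std::vector<int> ia, ib;
  std::vector<double> dd;
  for (int j = 0; j < na; ++j) {
    const double xj = xa[j], yj = ya[j];
    for (int q = 0; q < nb; ++q) {
      const double dx = xj - xb[q], dy = yj - yb[q];
      const double d2 = dx * dx + dy * dy;
      if (d2 >= lo2 && d2 < hi2) {
        ia.push_back(j + 1);
        ib.push_back(q + 1);
        dd.push_back(std::sqrt(d2));
      }
    }
  }
  return List::create(_["a"] = wrap(ia), _["b"] = wrap(ib), _["d"] = wrap(dd));
}

// Per-A neighbour counts sum_q I(r_lo <= d(A_j, B_q) < r_hi).
// [[Rcpp::export]]
IntegerVector neighbour_counts_cpp(NumericVector xa, NumericVector ya,
                                   NumericVector xb, NumericVector yb,
                                   double rlo, double rhi) {
  const int na = xa.size(), nb = xb.size();
  const double lo2 = rlo * rlo, hi2 = rhi * rhi;
  IntegerVector out(na);
  for (int j = 0; j < na; ++j) {
    const double xj = xa[j], yj = ya[j];
    int c = 0;
    for (int q = 0; q < nb; ++q) {
      const double dx = xj - xb[q], dy = yj - yb[q];
      const double d2 = dx * dx + dy * dy;
      if (d2 >= lo2 && d2 < hi2) ++c;
    }
    out[j] = c;
  }
  return out;
}

// Histogram of cross-label pair distances into uniform bins
// [0, bw), [bw, 2bw), ... (n_bins bins); distances >= n_bins*bw ignored.
// [[Rcpp::export]]
IntegerVector cross_bin_counts_cpp(NumericVector xa, NumericVector ya,
                                   NumericVector xb, NumericVector yb,
                                   double bw, int n_bins) {
  const int na = xa.size(), nb = xb.size();
  const double rmax = bw * n_bins, rmax2 = rmax * rmax;
  IntegerVector out(n_bins);
  for (int j = 0; j < na; ++j) {
    const double xj = xa[j], yj = ya[j];
    for (int q = 0; q < nb; ++q) {
      const double dx = xj - xb[q], dy = yj - yb[q];
      const double d2 = dx * dx + dy * dy;
      if (d2 < rmax2) {
        int bin = (int)(std::sqrt(d2) / bw);
        if (bin >= n_bins) bin = n_bins - 1;  // guard fp rounding at the edge
        ++out[bin];
      }
    }
  }
  return out;
}

// As cross_bin_counts_cpp but each pair contributes invw(j, bin), the
// reciprocal edge-correction weight of the A particle for that bin's annulus.
// [[Rcpp::export]]
NumericVector cross_bin_counts_weighted_cpp(NumericVector xa, NumericVector ya,
                                            NumericVector xb, NumericVector yb,
                                            double bw, int n_bins,
                                            NumericMatrix invw) {
  const int na = xa.size(), nb = xb.size();
  const double rmax = bw * n_bins, rmax2 = rmax * rmax;
  NumericVector out(n_bins);
  for (int j = 0; j < na; ++j) {
    const double xj = xa[j], yj = ya[j];
    for (int q = 0; q < nb; ++q) {
      const double dx = xj - xb[q], dy = yj - yb[q];
      const double d2 = dx * dx + dy * dy;
      if (d2 < rmax2) {
        int bin = (int)(std::sqrt(d2) / bw);
        if (bin >= n_bins) bin = n_bins - 1;
        out[bin] += invw(j, bin);
      }
    }
  }
  return out;
}

static inline double chord_antideriv(double x, double r) {
  // antiderivative of sqrt(r^2 - x^2)
  double t = x / r;
  if (t > 1.0) t = 1.0;
  if (t < -1.0) t = -1.0;
  double s2 = r * r - x * x;
  double s = s2 > 0 ? std::sqrt(s2) : 0.0;
  return 0.5 * (x * s + r * r * std::asin(t));
}

// Exact area of disc(centre origin, radius r) intersected with the axis
// box [x1,x2] x [y1,y2].  Piecewise integration with breakpoints where the
// circle crosses the horizontal box edges.
static double disc_box_area(double x1, double x2, double y1, double y2,
                            double r) {
  if (r <= 0 || x1 >= x2 || y1 >= y2) return 0.0;
  double lo = std::max(x1, -r), hi = std::min(x2, r);
  if (lo >= hi) return 0.0;
  std::vector<double> bp;
  bp.push_back(lo);
  bp.push_back(hi);
  for (double y : {y1, y2}) {
    if (std::fabs(y) < r) {
      double c = std::sqrt(r * r - y * y);
      if (-c > lo && -c < hi) bp.push_back(-c);
      if (c > lo && c < hi) bp.push_back(c);
    }
  }
  std::sort(bp.begin(), bp.end());
  double area = 0.0;
  for (size_t i = 0; i + 1 < bp.size(); ++i) {
    const double a = bp[i], b = bp[i + 1];
    if (b - a <= 0) continue;
    const double m = 0.5 * (a + b);
    const double s = std::sqrt(std::max(0.0, r * r - m * m));
    const double top = std::min(y2, s), bot = std::max(y1, -s);
    if (top <= bot) continue;
    double seg = 0.0;
    if (top == y2) seg += y2 * (b - a);
    else seg += chord_antideriv(b, r) - chord_antideriv(a, r);
    if (bot == y1) seg -= y1 * (b - a);
    else seg += chord_antideriv(b, r) - chord_antideriv(a, r);
    area += seg;
  }
  return area;
}

// Area of the disc of radius r centred at (px, py) clipped to the window
// [0, w] x [0, h].  Vectorised over points; r scalar.
// [[Rcpp::export]]
NumericVector disc_rect_area_cpp(NumericVector px, NumericVector py,
                                 double r, double w, double h) {
  const int n = px.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = disc_box_area(-px[i], w - px[i], -py[i], h - py[i], r);
  return out;
}
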