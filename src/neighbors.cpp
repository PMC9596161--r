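#include <Rcpp.h>
using namespace Rcpp;

// Uniform grid over the unit square with cell size >= r, so that all
// neighbours within r of a point lie in the 3x3 cell block around it.
struct Grid {
  int nx;
  double cell;
  std::vector<std::vector<int>> bins;

  Grid(const NumericVector& x, const NumericVector& y, double r) {
    nx = (int)std::floor(1.0 / std::max(r, 1e-9));
    if (nx < 1) nx = 1;
    if (nx > 512) nx = 512;
    cell = 1.0 / nx;
    bins.assign((size_t)nx * nx, {});
    for (int i = 0; i < x.size(); ++i) {
      bins[index(x[i], y[i])].push_back(i);
    }
  }

  int clampi(int v) const { return v < 0 ? 0 : (v >= nx ? nx - 1 : v); }

  size_t index(double px, double py) const {
    int ix = clampi((int)(px / cell));
    int iy = clampi((int)(py / cell));
    return (size_t)iy * nx + ix;
  }
};

// Kernel-weighted neighbour sum within radius r for each query point.
// kernel 0: flat (weight w per neighbour); kernel 1: linear decay
// w * (1 - d/r). self_idx gives, for each query, its 0-based index in the
// source set (so a point never counts itself); pass an empty vector when
// the sets are disjoint.
// [[Rcpp::export]]
NumericVector cpp_radius_sum(NumericVector sx, NumericVector sy,
                             NumericVector w, NumericVector qx,
                             NumericVector qy, double r, int kernel,
                             IntegerVector self_idx) {
  Grid g(sx, sy, r);
  int nq = qx.size();
  NumericVector out(nq);
  double r2 = r * r;
  bool unit_w = (w.size() == 1 && w[0] == 1.0);
  bool has_self = self_idx.size() == nq;
  for (int q = 0; q < nq; ++q) {
    int self = has_self ? self_idx[q] : -1;
    double px = qx[q], py = qy[q], acc = 0.0;
    int cx = g.clampi((int)(px / g.cell));
    int cy = g.clampi((int)(py / g.cell));
    for (int dy = -1; dy <= 1; ++dy) {
      int iy = cy + dy;
      if (iy < 0 || iy >= g.nx) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int ix = cx + dx;
        if (ix < 0 || ix >= g.nx) continue;
        const std::vector<int>& bin = g.bins[(size_t)iy * g.nx + ix];
        for (int j : bin) {
          if (j == self) continue;
          double ddx = sx[j] - px, ddy = sy[j] - py;
          double d2 = ddx * ddx + ddy * ddy;
          if (d2 > r2) continue;
          double wj = unit_w ? 1.0 : w[j];
          if (kernel == 1) {
            acc += wj * (1.0 - std::sqrt(d2) / r);
          } else {
            acc += wj;
          }
        }
      }
    }
    out[q] = acc;
  }
  return out;
}

// For each query (female) position, a uniformly chosen index (1-based)
// among source (male) points within radius r, or 0 when the circle is
// empty. Uses R's RNG (reservoir sampling), so results are reproducible
// under set.seed().
// [[Rcpp::export]]
IntegerVector cpp_pick_within(NumericVector mx, NumericVector my,
                              NumericVector fx, NumericVector fy,
                              double r) {
  Grid g(mx, my, r);
  int nf = fx.size();
  IntegerVector out(nf);
  double r2 = r * r;
  for (int q = 0; q < nf; ++q) {
    double px = fx[q], py = fy[q];
    int cx = g.clampi((int)(px / g.cell));
    int cy = g.clampi((int)(py / g.cell));
    int count = 0, chosen = -1;
    for (int dy = -1; dy <= 1; ++dy) {
      int iy = cy + dy;
      if (iy < 0 || iy >= g.nx) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int ix = cx + dx;
        if (ix < 0 || ix >= g.nx) continue;
        const std::vector<int>& bin = g.bins[(size_t)iy * g.nx + ix];
        for (int j : bin) {
          double ddx = mx[j] - px, ddy = my[j] - py;
          if (ddx * ddx + ddy * ddy > r2) continue;
          ++count;
          if (count == 1 || unif_rand() * count < 1.0) chosen = j;
        }
      }
    }
    out[q] = (count > 0) ? chosen + 1 : 0;
  }
  return out;
}
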