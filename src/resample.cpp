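#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sample of a column-major (x fastest) volume at 0-based fractional
// coordinates; voxels outside the grid contribute zero.
static inline double trilinear(const double *v, int nx, int ny, int nz,
                               double x, double y, double z) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double acc = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    int zz = z0 + dz;
    if (zz < 0 || zz >= nz) continue;
    double wz = dz ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    for (int dy = 0; dy <= 1; ++dy) {
      int yy = y0 + dy;
      if (yy < 0 || yy >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      double wzy = wz * wy;
      for (int dx = 0; dx <= 1; ++dx) {
        int xx = x0 + dx;
        if (xx < 0 || xx >= nx) continue;
        double wx = dx ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        acc += wzy * wx * v[(size_t)xx + (size_t)nx * ((size_t)yy + (size_t)ny * zz)];
      }
    }
  }
  return acc;
}

// out(x) = vol(A (x - c_out) + c_in + t), all coordinates 0-based voxels.
// A is 3x3 (column-major from R), c_out/c_in/t length-3.
// [[Rcpp::export(name = ".resample_affine")]]
NumericVector resample_affine(NumericVector vol, IntegerVector dim_in,
                              IntegerVector dim_out, NumericMatrix A,
                              NumericVector c_out, NumericVector c_in,
                              NumericVector t) {
  int nx = dim_in[0], ny = dim_in[1], nz = dim_in[2];
  int mx = dim_out[0], my = dim_out[1], mz = dim_out[2];
  NumericVector out((size_t)mx * my * mz);
  const double *v = vol.begin();
  double *o = out.begin();
  double a11 = A(0, 0), a12 = A(0, 1), a13 = A(0, 2);
  double a21 = A(1, 0), a22 = A(1, 1), a23 = A(1, 2);
  double a31 = A(2, 0), a32 = A(2, 1), a33 = A(2, 2);
  double bx = c_in[0] + t[0], by = c_in[1] + t[1], bz = c_in[2] + t[2];
  size_t idx = 0;
  for (int k = 0; k < mz; ++k) {
    double dz = k - c_out[2];
    for (int j = 0; j < my; ++j) {
      double dy = j - c_out[1];
      double px0 = a12 * dy + a13 * dz + bx;
      double py0 = a22 * dy + a23 * dz + by;
      double pz0 = a32 * dy + a33 * dz + bz;
      for (int i = 0; i < mx; ++i, ++idx) {
        double dx = i - c_out[0];
        o[idx] = trilinear(v, nx, ny, nz,
                           a11 * dx + px0, a21 * dx + py0, a31 * dx + pz0);
      }
    }
  }
  return out;
}

// Accumulate a rotated motif into a target volume:
//   target(x) += motif(Rinv (x - p) + c_m)
// p is the (fractional, 0-based) placement position in the target grid,
// c_m the motif centre. Only the bounding region of the rotated motif is
// visited. Returns the number of motif voxels that fell outside the target.
// [[Rcpp::export(name = ".add_motif")]]
int add_motif(NumericVector target, IntegerVector dim_t, NumericVector motif,
              IntegerVector dim_m, NumericMatrix Rinv, NumericVector p,
              NumericVector c_m) {
  int nx = dim_t[0], ny = dim_t[1], nz = dim_t[2];
  int mx = dim_m[0], my = dim_m[1], mz = dim_m[2];
  double *tg = target.begin();
  const double *mo = motif.begin();
  // sampling bound: the rotated motif support; the clip report below uses
  // the per-axis half-extent (motif corners are usually empty, so the
  // diagonal would over-report clipping)
  double rad = 0.5 * std::sqrt((double)mx * mx + (double)my * my + (double)mz * mz) + 1.0;
  double rad_clip = 0.5 * std::max(std::max(mx, my), mz) + 1.0;
  int clipped = 0;
  int x0 = std::max(0, (int)std::floor(p[0] - rad));
  int x1 = std::min(nx - 1, (int)std::ceil(p[0] + rad));
  int y0 = std::max(0, (int)std::floor(p[1] - rad));
  int y1 = std::min(ny - 1, (int)std::ceil(p[1] + rad));
  int z0 = std::max(0, (int)std::floor(p[2] - rad));
  int z1 = std::min(nz - 1, (int)std::ceil(p[2] + rad));
  if (x0 > x1 || y0 > y1 || z0 > z1) return 1;
  double a11 = Rinv(0, 0), a12 = Rinv(0, 1), a13 = Rinv(0, 2);
  double a21 = Rinv(1, 0), a22 = Rinv(1, 1), a23 = Rinv(1, 2);
  double a31 = Rinv(2, 0), a32 = Rinv(2, 1), a33 = Rinv(2, 2);
  for (int k = z0; k <= z1; ++k) {
    double dz = k - p[2];
    for (int j = y0; j <= y1; ++j) {
      double dy = j - p[1];
      double px0 = a12 * dy + a13 * dz + c_m[0];
      double py0 = a22 * dy + a23 * dz + c_m[1];
      double pz0 = a32 * dy + a33 * dz + c_m[2];
      for (int i = x0; i <= x1; ++i) {
        double dx = i - p[0];
        double val = trilinear(mo, mx, my, mz,
                               a11 * dx + px0, a21 * dx + py0, a31 * dx + pz0);
        if (val != 0.0)
          tg[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)] += val;
      }
    }
  }
  if (p[0] - rad_clip < 0 || p[0] + rad_clip > nx - 1 ||
      p[1] - rad_clip < 0 || p[1] + rad_clip > ny - 1 ||
      p[2] - rad_clip < 0 || p[2] + rad_clip > nz - 1)
    clipped = 1;
  return clipped;
}
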