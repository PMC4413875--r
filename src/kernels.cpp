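#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Volumes are R arrays with dim = c(nz, ny, nx): element (iz, iy, ix) sits at
// iz + nz * (iy + ny * ix).  All rotation matrices passed from R act on (x, y, z)
// column vectors; coordinates are 0-based voxel indices.

static inline double trilinear(const double *v, int nz, int ny, int nx,
                               double z, double y, double x) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double acc = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    int zi = z0 + dz;
    if (zi < 0 || zi >= nz) continue;
    double wz = dz ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    for (int dy = 0; dy <= 1; ++dy) {
      int yi = y0 + dy;
      if (yi < 0 || yi >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      for (int dx = 0; dx <= 1; ++dx) {
        int xi = x0 + dx;
        if (xi < 0 || xi >= nx) continue;
        double wx = dx ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        acc += wz * wy * wx * v[zi + (R_xlen_t)nz * (yi + (R_xlen_t)ny * xi)];
      }
    }
  }
  return acc;
}

// out(p) = vol(A %*% p + b) for p = (x, y, z) of each output voxel; zero outside.
// [[Rcpp::export]]
NumericVector cpp_affine_sample(NumericVector vol, IntegerVector dim_in,
                                IntegerVector dim_out, NumericMatrix A,
                                NumericVector b) {
  int nz = dim_in[0], ny = dim_in[1], nx = dim_in[2];
  int oz = dim_out[0], oy = dim_out[1], ox = dim_out[2];
  NumericVector out((R_xlen_t)oz * oy * ox);
  const double *v = vol.begin();
  double *o = out.begin();
  double a11 = A(0, 0), a12 = A(0, 1), a13 = A(0, 2);
  double a21 = A(1, 0), a22 = A(1, 1), a23 = A(1, 2);
  double a31 = A(2, 0), a32 = A(2, 1), a33 = A(2, 2);
  for (int ix = 0; ix < ox; ++ix) {
    for (int iy = 0; iy < oy; ++iy) {
      double sx0 = a11 * ix + a12 * iy + b[0];
      double sy0 = a21 * ix + a22 * iy + b[1];
      double sz0 = a31 * ix + a32 * iy + b[2];
      R_xlen_t base = (R_xlen_t)oz * (iy + (R_xlen_t)oy * ix);
      for (int iz = 0; iz < oz; ++iz) {
        double sx = sx0 + a13 * iz, sy = sy0 + a23 * iz, sz = sz0 + a33 * iz;
        if (sx <= -1.0 || sx >= nx || sy <= -1.0 || sy >= ny ||
            sz <= -1.0 || sz >= nz) continue;
        o[base + iz] = trilinear(v, nz, ny, nx, sz, sy, sx);
      }
    }
  }
  out.attr("dim") = dim_out;
  return out;
}

// Additive paste of `block` into `target` (modified in place) with the block's
// voxel (0,0,0) landing at integer target offset (off_z, off_y, off_x).
// [[Rcpp::export]]
void cpp_paste_add(NumericVector target, IntegerVector dim_t,
                   NumericVector block, IntegerVector dim_b,
                   IntegerVector offset) {
  int tz = dim_t[0], ty = dim_t[1], tx = dim_t[2];
  int bz = dim_b[0], by = dim_b[1], bx = dim_b[2];
  int oz = offset[0], oy = offset[1], ox = offset[2];
  double *t = target.begin();
  const double *b = block.begin();
  for (int ix = 0; ix < bx; ++ix) {
    int txi = ix + ox;
    if (txi < 0 || txi >= tx) continue;
    for (int iy = 0; iy < by; ++iy) {
      int tyi = iy + oy;
      if (tyi < 0 || tyi >= ty) continue;
      for (int iz = 0; iz < bz; ++iz) {
        int tzi = iz + oz;
        if (tzi < 0 || tzi >= tz) continue;
        t[tzi + (R_xlen_t)tz * (tyi + (R_xlen_t)ty * txi)] +=
          b[iz + (R_xlen_t)bz * (iy + (R_xlen_t)by * ix)];
      }
    }
  }
}

// Line-integral projections of a volume for a single-axis tilt series about y.
// For tilt angle theta the beam runs along the output z axis; an output pixel
// (x', y) integrates vol along z' with source coordinates rotated about the
// volume centre.  Returns array (nx, ny, n_angles).
// [[Rcpp::export]]
NumericVector cpp_project_tilt(NumericVector vol, IntegerVector dim,
                               NumericVector angles_deg) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int na = angles_deg.size();
  NumericVector out((R_xlen_t)nx * ny * na);
  const double *v = vol.begin();
  double *o = out.begin();
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  int half = (int)std::ceil(std::sqrt((double)nx * nx + (double)nz * nz) / 2.0) + 1;
  for (int ia = 0; ia < na; ++ia) {
    double th = angles_deg[ia] * M_PI / 180.0;
    double c = std::cos(th), s = std::sin(th);
    for (int iy = 0; iy < ny; ++iy) {
      for (int ixp = 0; ixp < nx; ++ixp) {
        double u = ixp - cx;
        double acc = 0.0;
        for (int w = -half; w <= half; ++w) {
          double sx = cx + c * u + s * w;
          if (sx <= -1.0 || sx >= nx) continue;
          double sz = cz - s * u + c * w;
          if (sz <= -1.0 || sz >= nz) continue;
          acc += trilinear(v, nz, ny, nx, sz, (double)iy, sx);
        }
        o[ixp + (R_xlen_t)nx * (iy + (R_xlen_t)ny * ia)] = acc;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, na);
  return out;
}

// Back-projection of (ramp-filtered) images into a (nz, ny, nx) volume.
// images: array (nx, ny, n_angles); linear interpolation along the detector x'.
// [[Rcpp::export]]
NumericVector cpp_backproject_tilt(NumericVector images, IntegerVector dim_img,
                                   NumericVector angles_deg, IntegerVector dim_out) {
  int nx = dim_img[0], ny = dim_img[1], na = dim_img[2];
  int oz = dim_out[0], oy = dim_out[1], ox = dim_out[2];
  NumericVector out((R_xlen_t)oz * oy * ox);
  const double *im = images.begin();
  double *o = out.begin();
  double cx = (ox - 1) / 2.0, cz = (oz - 1) / 2.0;
  double cdx = (nx - 1) / 2.0;
  for (int ia = 0; ia < na; ++ia) {
    double th = angles_deg[ia] * M_PI / 180.0;
    double c = std::cos(th), s = std::sin(th);
    const double *img = im + (R_xlen_t)nx * ny * ia;
    for (int ix = 0; ix < ox; ++ix) {
      for (int iz = 0; iz < oz; ++iz) {
        // detector coordinate of this (x, z) column
        double u = c * (ix - cx) - s * (iz - cz) + cdx;
        if (u <= -1.0 || u >= nx) continue;
        int u0 = (int)std::floor(u);
        double fu = u - u0;
        for (int iy = 0; iy < oy; ++iy) {
          double val = 0.0;
          if (u0 >= 0) val += (1.0 - fu) * img[u0 + (R_xlen_t)nx * iy];
          if (u0 + 1 < nx) val += fu * img[u0 + 1 + (R_xlen_t)nx * iy];
          o[iz + (R_xlen_t)oz * (iy + (R_xlen_t)oy * ix)] += val;
        }
      }
    }
  }
  out.attr("dim") = dim_out;
  return out;
}
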