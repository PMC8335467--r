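#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double BIG = 1e20;

// 1D squared Euclidean distance transform (Felzenszwalb & Huttenlocher)
// on samples at physical positions i*s, i = 0..n-1.
static void dt1d(const double* f, double* d, int n, double s,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    double inter;
    for (;;) {
      double xv = v[k] * s;
      inter = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (inter <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = inter;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
}

// Exact Euclidean distance (mm) from every voxel centre to the mask set;
// 0 inside the mask. Anisotropic spacing supported.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n) stop("mask length does not match dim");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : BIG;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along axis 1 (stride 1)
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      double* line = &out[(R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1];
      for (int i = 0; i < n1; ++i) f[i] = line[i];
      dt1d(f.data(), d.data(), n1, spacing[0], v, z);
      for (int i = 0; i < n1; ++i) line[i] = d[i];
    }
  // axis 2 (stride n1)
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      double* base = &out[(R_xlen_t)k * n1 * n2 + i];
      for (int j = 0; j < n2; ++j) f[j] = base[(R_xlen_t)j * n1];
      dt1d(f.data(), d.data(), n2, spacing[1], v, z);
      for (int j = 0; j < n2; ++j) base[(R_xlen_t)j * n1] = d[j];
    }
  // axis 3 (stride n1*n2)
  const R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      double* base = &out[(R_xlen_t)j * n1 + i];
      for (int k = 0; k < n3; ++k) f[k] = base[(R_xlen_t)k * s3];
      dt1d(f.data(), d.data(), n3, spacing[2], v, z);
      for (int k = 0; k < n3; ++k) base[(R_xlen_t)k * s3] = d[k];
    }
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}

static void conv1d(std::vector<double>& buf, const std::vector<double>& ker,
                   std::vector<double>& tmp) {
  const int n = (int)buf.size();
  const int r = ((int)ker.size() - 1) / 2;
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int t = -r; t <= r; ++t) {
      int idx = i + t;
      if (idx < 0) idx = -idx - 1;          // reflect
      if (idx >= n) idx = 2 * n - idx - 1;
      acc += buf[idx] * ker[t + r];
    }
    tmp[i] = acc;
  }
  buf.swap(tmp);
}

// Separable Gaussian smoothing with physical sigma (mm), reflective borders.
// [[Rcpp::export(name = ".gauss3d")]]
NumericVector gauss3d_cpp(NumericVector x, IntegerVector dim,
                          NumericVector spacing, double sigma) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (x.size() != n) stop("array length does not match dim");
  NumericVector out = clone(x);
  if (sigma <= 0) return out;

  for (int ax = 0; ax < 3; ++ax) {
    double s = spacing[ax];
    int r = (int)std::ceil(3.0 * sigma / s);
    if (r < 1) r = 1;
    std::vector<double> ker(2 * r + 1);
    double sum = 0.0;
    for (int t = -r; t <= r; ++t) {
      double u = t * s / sigma;
      ker[t + r] = std::exp(-0.5 * u * u);
      sum += ker[t + r];
    }
    for (double& kv : ker) kv /= sum;

    int nline = (ax == 0) ? n1 : (ax == 1 ? n2 : n3);
    std::vector<double> buf(nline), tmp(nline);
    if (ax == 0) {
      for (int k = 0; k < n3; ++k)
        for (int j = 0; j < n2; ++j) {
          double* line = &out[(R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1];
          for (int i = 0; i < n1; ++i) buf[i] = line[i];
          conv1d(buf, ker, tmp);
          for (int i = 0; i < n1; ++i) line[i] = buf[i];
        }
    } else if (ax == 1) {
      for (int k = 0; k < n3; ++k)
        for (int i = 0; i < n1; ++i) {
          double* base = &out[(R_xlen_t)k * n1 * n2 + i];
          for (int j = 0; j < n2; ++j) buf[j] = base[(R_xlen_t)j * n1];
          conv1d(buf, ker, tmp);
          for (int j = 0; j < n2; ++j) base[(R_xlen_t)j * n1] = buf[j];
        }
    } else {
      const R_xlen_t s3 = (R_xlen_t)n1 * n2;
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          double* base = &out[(R_xlen_t)j * n1 + i];
          for (int k = 0; k < n3; ++k) buf[k] = base[(R_xlen_t)k * s3];
          conv1d(buf, ker, tmp);
          for (int k = 0; k < n3; ++k) base[(R_xlen_t)k * s3] = buf[k];
        }
    }
  }
  return out;
}

// Trilinear resampling of a scalar grid under a rigid transform.
// Forward map: target = R (source - c) + c + t  =>  source = R^T (target - t - c) + c.
// rot is a row-major 3x3 rotation matrix (identity for translation-only),
// c the rotation centre (mm), t the translation (mm). Outside -> 0.
// [[Rcpp::export(name = ".resample_rigid")]]
NumericVector resample_rigid_cpp(NumericVector values, IntegerVector dim,
                                 NumericVector spacing, NumericVector origin,
                                 NumericVector trans, NumericVector rot,
                                 NumericVector centre) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (values.size() != n) stop("array length does not match dim");
  NumericVector out(n);
  const double* V = values.begin();
  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;

  for (int k = 0; k < n3; ++k) {
    double z = origin[2] + k * spacing[2];
    for (int j = 0; j < n2; ++j) {
      double y = origin[1] + j * spacing[1];
      for (int i = 0; i < n1; ++i) {
        double x = origin[0] + i * spacing[0];
        double px = x - trans[0] - centre[0];
        double py = y - trans[1] - centre[1];
        double pz = z - trans[2] - centre[2];
        // apply R^T (rot is row-major forward rotation)
        double sx = rot[0] * px + rot[3] * py + rot[6] * pz + centre[0];
        double sy = rot[1] * px + rot[4] * py + rot[7] * pz + centre[1];
        double sz = rot[2] * px + rot[5] * py + rot[8] * pz + centre[2];
        double fi = (sx - origin[0]) / spacing[0];
        double fj = (sy - origin[1]) / spacing[1];
        double fk = (sz - origin[2]) / spacing[2];
        int i0 = (int)std::floor(fi), j0 = (int)std::floor(fj),
            k0 = (int)std::floor(fk);
        double out_v = 0.0;
        if (i0 >= -1 && i0 <= n1 - 1 && j0 >= -1 && j0 <= n2 - 1 &&
            k0 >= -1 && k0 <= n3 - 1) {
          double wi = fi - i0, wj = fj - j0, wk = fk - k0;
          for (int dk = 0; dk <= 1; ++dk) {
            int kk = k0 + dk;
            if (kk < 0 || kk >= n3) continue;
            double wz = dk ? wk : 1.0 - wk;
            for (int dj = 0; dj <= 1; ++dj) {
              int jj = j0 + dj;
              if (jj < 0 || jj >= n2) continue;
              double wy = dj ? wj : 1.0 - wj;
              for (int di = 0; di <= 1; ++di) {
                int ii = i0 + di;
                if (ii < 0 || ii >= n1) continue;
                double wx = di ? wi : 1.0 - wi;
                out_v += wx * wy * wz * V[(R_xlen_t)kk * s3 + (R_xlen_t)jj * s2 + ii];
              }
            }
          }
        }
        out[(R_xlen_t)k * s3 + (R_xlen_t)j * s2 + i] = out_v;
      }
    }
  }
  return out;
}
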