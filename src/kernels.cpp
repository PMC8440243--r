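// Low-level 3D array kernels: convolution (forward and both backward passes),
// max pooling, fixed trilinear 2x upsampling, trilinear sampling at arbitrary
// coordinates, separable Gaussian blur and binary box dilation.
//
// Array layout follows R column-major order with dimensions (X, Y, Z, C):
//   index(x, y, z, c) = x + X*(y + Y*(z + Z*c)).
// Convolution weights have dimensions (k1, k2, k3, Cin, Cout).
#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline R_xlen_t idx4(int x, int y, int z, int c, int X, int Y, int Z) {
  return x + (R_xlen_t)X * (y + (R_xlen_t)Y * (z + (R_xlen_t)Z * c));
}

static inline int out_dim(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// [[Rcpp::export(name = ".cpp_conv3d_fwd")]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector kdim,
                             NumericVector bias, int stride, int pad) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Ci = xdim[3];
  const int K1 = kdim[0], K2 = kdim[1], K3 = kdim[2], Co = kdim[4];
  if (kdim[3] != Ci) stop("input channels do not match kernel");
  const int OX = out_dim(X, K1, stride, pad);
  const int OY = out_dim(Y, K2, stride, pad);
  const int OZ = out_dim(Z, K3, stride, pad);
  if (OX < 1 || OY < 1 || OZ < 1) stop("input too small for kernel");
  NumericVector out((R_xlen_t)OX * OY * OZ * Co);
  const double *px = x.begin(), *pw = w.begin();
  double *po = out.begin();

  for (int co = 0; co < Co; ++co) {
    const double b = bias[co];
    for (int oz = 0; oz < OZ; ++oz) {
      const int z0 = oz * stride - pad;
      for (int oy = 0; oy < OY; ++oy) {
        const int y0 = oy * stride - pad;
        for (int ox = 0; ox < OX; ++ox) {
          const int x0 = ox * stride - pad;
          double acc = b;
          for (int ci = 0; ci < Ci; ++ci) {
            for (int kz = 0; kz < K3; ++kz) {
              const int iz = z0 + kz;
              if (iz < 0 || iz >= Z) continue;
              for (int ky = 0; ky < K2; ++ky) {
                const int iy = y0 + ky;
                if (iy < 0 || iy >= Y) continue;
                const R_xlen_t xbase = idx4(0, iy, iz, ci, X, Y, Z);
                const R_xlen_t wbase = (R_xlen_t)K1 * (ky + (R_xlen_t)K2 * (kz + (R_xlen_t)K3 * (ci + (R_xlen_t)Ci * co)));
                const int klo = std::max(0, -x0), khi = std::min(K1, X - x0);
                for (int kx = klo; kx < khi; ++kx)
                  acc += px[xbase + x0 + kx] * pw[wbase + kx];
              }
            }
          }
          po[idx4(ox, oy, oz, co, OX, OY, OZ)] = acc;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(OX, OY, OZ, Co);
  return out;
}

// Gradient w.r.t. the convolution input; also serves as the forward pass of
// the stride-2 transposed convolution (xdim is then the *output* grid).
// [[Rcpp::export(name = ".cpp_conv3d_bwd_input")]]
NumericVector cpp_conv3d_bwd_input(NumericVector dy, IntegerVector ydim,
                                   NumericVector w, IntegerVector kdim,
                                   IntegerVector xdim, int stride, int pad) {
  const int OX = ydim[0], OY = ydim[1], OZ = ydim[2], Co = ydim[3];
  const int K1 = kdim[0], K2 = kdim[1], K3 = kdim[2], Ci = kdim[3];
  if (kdim[4] != Co) stop("channel mismatch in conv backward");
  const int X = xdim[0], Y = xdim[1], Z = xdim[2];
  NumericVector dx((R_xlen_t)X * Y * Z * Ci);
  const double *pdy = dy.begin(), *pw = w.begin();
  double *pdx = dx.begin();

  for (int co = 0; co < Co; ++co) {
    for (int ci = 0; ci < Ci; ++ci) {
      for (int oz = 0; oz < OZ; ++oz) {
        const int z0 = oz * stride - pad;
        for (int oy = 0; oy < OY; ++oy) {
          const int y0 = oy * stride - pad;
          for (int ox = 0; ox < OX; ++ox) {
            const int x0 = ox * stride - pad;
            const double g = pdy[idx4(ox, oy, oz, co, OX, OY, OZ)];
            if (g == 0.0) continue;
            for (int kz = 0; kz < K3; ++kz) {
              const int iz = z0 + kz;
              if (iz < 0 || iz >= Z) continue;
              for (int ky = 0; ky < K2; ++ky) {
                const int iy = y0 + ky;
                if (iy < 0 || iy >= Y) continue;
                const R_xlen_t xbase = idx4(0, iy, iz, ci, X, Y, Z);
                const R_xlen_t wbase = (R_xlen_t)K1 * (ky + (R_xlen_t)K2 * (kz + (R_xlen_t)K3 * (ci + (R_xlen_t)Ci * co)));
                const int klo = std::max(0, -x0), khi = std::min(K1, X - x0);
                for (int kx = klo; kx < khi; ++kx)
                  pdx[xbase + x0 + kx] += g * pw[wbase + kx];
              }
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(X, Y, Z, Ci);
  return dx;
}

// [[Rcpp::export(name = ".cpp_conv3d_bwd_weight")]]
NumericVector cpp_conv3d_bwd_weight(NumericVector x, IntegerVector xdim,
                                    NumericVector dy, IntegerVector ydim,
                                    IntegerVector kdim, int stride, int pad) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Ci = xdim[3];
  const int OX = ydim[0], OY = ydim[1], OZ = ydim[2], Co = ydim[3];
  const int K1 = kdim[0], K2 = kdim[1], K3 = kdim[2];
  NumericVector dw((R_xlen_t)K1 * K2 * K3 * Ci * Co);
  const double *px = x.begin(), *pdy = dy.begin();
  double *pdw = dw.begin();

  for (int co = 0; co < Co; ++co) {
    for (int ci = 0; ci < Ci; ++ci) {
      for (int kz = 0; kz < K3; ++kz) {
        for (int ky = 0; ky < K2; ++ky) {
          for (int kx = 0; kx < K1; ++kx) {
            double acc = 0.0;
            for (int oz = 0; oz < OZ; ++oz) {
              const int iz = oz * stride - pad + kz;
              if (iz < 0 || iz >= Z) continue;
              for (int oy = 0; oy < OY; ++oy) {
                const int iy = oy * stride - pad + ky;
                if (iy < 0 || iy >= Y) continue;
                const R_xlen_t xbase = idx4(0, iy, iz, ci, X, Y, Z);
                const R_xlen_t ybase = idx4(0, oy, oz, co, OX, OY, OZ);
                for (int ox = 0; ox < OX; ++ox) {
                  const int ix = ox * stride - pad + kx;
                  if (ix < 0 || ix >= X) continue;
                  acc += px[xbase + ix] * pdy[ybase + ox];
                }
              }
            }
            pdw[kx + (R_xlen_t)K1 * (ky + (R_xlen_t)K2 * (kz + (R_xlen_t)K3 * (ci + (R_xlen_t)Ci * co)))] = acc;
          }
        }
      }
    }
  }
  dw.attr("dim") = IntegerVector::create(K1, K2, K3, Ci, Co);
  return dw;
}

// 2x2x2 max pooling with stride 2; returns pooled values and argmax indices.
// [[Rcpp::export(name = ".cpp_maxpool3d_fwd")]]
List cpp_maxpool3d_fwd(NumericVector x, IntegerVector xdim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  if (X % 2 || Y % 2 || Z % 2) stop("max pooling requires even spatial dims");
  const int OX = X / 2, OY = Y / 2, OZ = Z / 2;
  NumericVector out((R_xlen_t)OX * OY * OZ * C);
  NumericVector arg((R_xlen_t)OX * OY * OZ * C);  // double holds indices exactly
  const double *px = x.begin();
  double *po = out.begin(), *pa = arg.begin();
  for (int c = 0; c < C; ++c)
    for (int oz = 0; oz < OZ; ++oz)
      for (int oy = 0; oy < OY; ++oy)
        for (int ox = 0; ox < OX; ++ox) {
          double best = -INFINITY; R_xlen_t bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy_ = 0; dy_ < 2; ++dy_)
              for (int dx_ = 0; dx_ < 2; ++dx_) {
                R_xlen_t i = idx4(2 * ox + dx_, 2 * oy + dy_, 2 * oz + dz, c, X, Y, Z);
                if (px[i] > best) { best = px[i]; bi = i; }
              }
          R_xlen_t o = idx4(ox, oy, oz, c, OX, OY, OZ);
          po[o] = best; pa[o] = (double)bi;
        }
  out.attr("dim") = IntegerVector::create(OX, OY, OZ, C);
  return List::create(_["value"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".cpp_maxpool3d_bwd")]]
NumericVector cpp_maxpool3d_bwd(NumericVector dy, NumericVector arg, IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  double *pdx = dx.begin();
  const double *pdy = dy.begin(), *pa = arg.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) pdx[(R_xlen_t)pa[i]] += pdy[i];
  dx.attr("dim") = xdim;
  return dx;
}

// Per-axis weights for cell-centered trilinear 2x upsampling: output node i
// samples input coordinate (i + 0.5)/2 - 0.5, clamped to the border.
static void up2_weights(int n, std::vector<int>& i0, std::vector<double>& w0) {
  i0.resize(2 * n); w0.resize(2 * n);
  for (int i = 0; i < 2 * n; ++i) {
    double u = (i + 0.5) / 2.0 - 0.5;
    if (u < 0) u = 0;
    if (u > n - 1) u = n - 1;
    int f = (int)std::floor(u);
    if (f > n - 2) f = n - 2;
    if (n == 1) { f = 0; }
    i0[i] = f;
    w0[i] = 1.0 - (u - f);
  }
}

// [[Rcpp::export(name = ".cpp_upsample2x_fwd")]]
NumericVector cpp_upsample2x_fwd(NumericVector x, IntegerVector xdim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int OX = 2 * X, OY = 2 * Y, OZ = 2 * Z;
  std::vector<int> ix, iy, iz; std::vector<double> wx, wy, wz;
  up2_weights(X, ix, wx); up2_weights(Y, iy, wy); up2_weights(Z, iz, wz);
  NumericVector out((R_xlen_t)OX * OY * OZ * C);
  const double *px = x.begin(); double *po = out.begin();
  for (int c = 0; c < C; ++c)
    for (int oz = 0; oz < OZ; ++oz)
      for (int oy = 0; oy < OY; ++oy)
        for (int ox = 0; ox < OX; ++ox) {
          const int x0 = ix[ox], y0 = iy[oy], z0 = iz[oz];
          const int x1 = std::min(x0 + 1, X - 1), y1 = std::min(y0 + 1, Y - 1), z1 = std::min(z0 + 1, Z - 1);
          const double ax = wx[ox], ay = wy[oy], az = wz[oz];
          double v =
            az * (ay * (ax * px[idx4(x0, y0, z0, c, X, Y, Z)] + (1 - ax) * px[idx4(x1, y0, z0, c, X, Y, Z)]) +
                  (1 - ay) * (ax * px[idx4(x0, y1, z0, c, X, Y, Z)] + (1 - ax) * px[idx4(x1, y1, z0, c, X, Y, Z)])) +
            (1 - az) * (ay * (ax * px[idx4(x0, y0, z1, c, X, Y, Z)] + (1 - ax) * px[idx4(x1, y0, z1, c, X, Y, Z)]) +
                        (1 - ay) * (ax * px[idx4(x0, y1, z1, c, X, Y, Z)] + (1 - ax) * px[idx4(x1, y1, z1, c, X, Y, Z)]));
          po[idx4(ox, oy, oz, c, OX, OY, OZ)] = v;
        }
  out.attr("dim") = IntegerVector::create(OX, OY, OZ, C);
  return out;
}

// [[Rcpp::export(name = ".cpp_upsample2x_bwd")]]
NumericVector cpp_upsample2x_bwd(NumericVector dy, IntegerVector xdim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int OX = 2 * X, OY = 2 * Y, OZ = 2 * Z;
  std::vector<int> ix, iy, iz; std::vector<double> wx, wy, wz;
  up2_weights(X, ix, wx); up2_weights(Y, iy, wy); up2_weights(Z, iz, wz);
  NumericVector dx((R_xlen_t)X * Y * Z * C);
  const double *pdy = dy.begin(); double *pdx = dx.begin();
  for (int c = 0; c < C; ++c)
    for (int oz = 0; oz < OZ; ++oz)
      for (int oy = 0; oy < OY; ++oy)
        for (int ox = 0; ox < OX; ++ox) {
          const double g = pdy[idx4(ox, oy, oz, c, OX, OY, OZ)];
          if (g == 0.0) continue;
          const int x0 = ix[ox], y0 = iy[oy], z0 = iz[oz];
          const int x1 = std::min(x0 + 1, X - 1), y1 = std::min(y0 + 1, Y - 1), z1 = std::min(z0 + 1, Z - 1);
          const double ax = wx[ox], ay = wy[oy], az = wz[oz];
          pdx[idx4(x0, y0, z0, c, X, Y, Z)] += g * az * ay * ax;
          pdx[idx4(x1, y0, z0, c, X, Y, Z)] += g * az * ay * (1 - ax);
          pdx[idx4(x0, y1, z0, c, X, Y, Z)] += g * az * (1 - ay) * ax;
          pdx[idx4(x1, y1, z0, c, X, Y, Z)] += g * az * (1 - ay) * (1 - ax);
          pdx[idx4(x0, y0, z1, c, X, Y, Z)] += g * (1 - az) * ay * ax;
          pdx[idx4(x1, y0, z1, c, X, Y, Z)] += g * (1 - az) * ay * (1 - ax);
          pdx[idx4(x0, y1, z1, c, X, Y, Z)] += g * (1 - az) * (1 - ay) * ax;
          pdx[idx4(x1, y1, z1, c, X, Y, Z)] += g * (1 - az) * (1 - ay) * (1 - ax);
        }
  dx.attr("dim") = xdim;
  return dx;
}

// Trilinear sampling of a single-channel volume at arbitrary voxel
// coordinates (node-centered: coordinate u lies on grid node u). Coordinates
// are clamped to the volume border.
// [[Rcpp::export(name = ".cpp_sample_trilinear")]]
NumericVector cpp_sample_trilinear(NumericVector vol, IntegerVector vdim,
                                   NumericVector cx, NumericVector cy, NumericVector cz) {
  const int X = vdim[0], Y = vdim[1], Z = vdim[2];
  const R_xlen_t n = cx.size();
  NumericVector out(n);
  const double *pv = vol.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double u = cx[i], v = cy[i], w = cz[i];
    if (u < 0) u = 0; if (u > X - 1) u = X - 1;
    if (v < 0) v = 0; if (v > Y - 1) v = Y - 1;
    if (w < 0) w = 0; if (w > Z - 1) w = Z - 1;
    int x0 = (int)std::floor(u), y0 = (int)std::floor(v), z0 = (int)std::floor(w);
    if (x0 > X - 2) x0 = std::max(0, X - 2);
    if (y0 > Y - 2) y0 = std::max(0, Y - 2);
    if (z0 > Z - 2) z0 = std::max(0, Z - 2);
    const int x1 = std::min(x0 + 1, X - 1), y1 = std::min(y0 + 1, Y - 1), z1 = std::min(z0 + 1, Z - 1);
    const double ax = 1.0 - (u - x0), ay = 1.0 - (v - y0), az = 1.0 - (w - z0);
    out[i] =
      az * (ay * (ax * pv[idx4(x0, y0, z0, 0, X, Y, Z)] + (1 - ax) * pv[idx4(x1, y0, z0, 0, X, Y, Z)]) +
            (1 - ay) * (ax * pv[idx4(x0, y1, z0, 0, X, Y, Z)] + (1 - ax) * pv[idx4(x1, y1, z0, 0, X, Y, Z)])) +
      (1 - az) * (ay * (ax * pv[idx4(x0, y0, z1, 0, X, Y, Z)] + (1 - ax) * pv[idx4(x1, y0, z1, 0, X, Y, Z)]) +
                  (1 - ay) * (ax * pv[idx4(x0, y1, z1, 0, X, Y, Z)] + (1 - ax) * pv[idx4(x1, y1, z1, 0, X, Y, Z)]));
  }
  return out;
}

// Separable Gaussian blur with per-axis sigma in voxels; kernels truncated at
// 3 sigma and renormalized at the borders (flux-preserving for interior).
static void blur_axis(std::vector<double>& a, int X, int Y, int Z, int axis, double sigma) {
  if (sigma <= 0) return;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  for (int i = -r; i <= r; ++i) k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
  const int dims[3] = {X, Y, Z};
  const int n = dims[axis];
  std::vector<double> buf(n);
  const R_xlen_t strides[3] = {1, (R_xlen_t)X, (R_xlen_t)X * Y};
  const R_xlen_t st = strides[axis];
  // iterate over all lines along `axis`
  const int d1 = dims[(axis + 1) % 3], d2 = dims[(axis + 2) % 3];
  const R_xlen_t s1 = strides[(axis + 1) % 3], s2 = strides[(axis + 2) % 3];
  for (int j2 = 0; j2 < d2; ++j2)
    for (int j1 = 0; j1 < d1; ++j1) {
      const R_xlen_t base = j1 * s1 + j2 * s2;
      for (int i = 0; i < n; ++i) {
        double acc = 0, wsum = 0;
        const int lo = std::max(-r, -i), hi = std::min(r, n - 1 - i);
        for (int d = lo; d <= hi; ++d) { acc += k[d + r] * a[base + (i + d) * st]; wsum += k[d + r]; }
        buf[i] = acc / wsum;
      }
      for (int i = 0; i < n; ++i) a[base + i * st] = buf[i];
    }
}

// [[Rcpp::export(name = ".cpp_gauss_blur3d")]]
NumericVector cpp_gauss_blur3d(NumericVector x, IntegerVector xdim, NumericVector sigma) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2];
  std::vector<double> a(x.begin(), x.end());
  blur_axis(a, X, Y, Z, 0, sigma[0]);
  blur_axis(a, X, Y, Z, 1, sigma[1]);
  blur_axis(a, X, Y, Z, 2, sigma[2]);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = IntegerVector::create(X, Y, Z);
  return out;
}

// Binary dilation with a box (Chebyshev ball) of radius r, via three
// separable 1D running-max passes.
// [[Rcpp::export(name = ".cpp_dilate_box")]]
NumericVector cpp_dilate_box(NumericVector x, IntegerVector xdim, int r) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2];
  std::vector<double> a(x.begin(), x.end());
  const int dims[3] = {X, Y, Z};
  const R_xlen_t strides[3] = {1, (R_xlen_t)X, (R_xlen_t)X * Y};
  for (int axis = 0; axis < 3; ++axis) {
    const int n = dims[axis];
    const R_xlen_t st = strides[axis];
    const int d1 = dims[(axis + 1) % 3], d2 = dims[(axis + 2) % 3];
    const R_xlen_t s1 = strides[(axis + 1) % 3], s2 = strides[(axis + 2) % 3];
    std::vector<double> buf(n);
    for (int j2 = 0; j2 < d2; ++j2)
      for (int j1 = 0; j1 < d1; ++j1) {
        const R_xlen_t base = j1 * s1 + j2 * s2;
        for (int i = 0; i < n; ++i) {
          double m = 0;
          const int lo = std::max(0, i - r), hi = std::min(n - 1, i + r);
          for (int d = lo; d <= hi; ++d) if (a[base + d * st] > m) m = a[base + d * st];
          buf[i] = m;
        }
        for (int i = 0; i < n; ++i) a[base + i * st] = buf[i];
      }
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = IntegerVector::create(X, Y, Z);
  return out;
}
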