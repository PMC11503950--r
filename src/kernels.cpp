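// Dense numeric kernels for the 3D U-Net: 3x3x3 convolution (via im2col +
// BLAS matmul), 2x2x2 max-pooling, and factor-2 trilinear upsampling, each
// with its adjoint for backpropagation.
//
// Array layout everywhere: column-major R arrays dim (nx, ny, nz, C, B).
// All maths in double precision; deterministic (no threading).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::uword vox(arma::uword x, arma::uword y, arma::uword z,
                              arma::uword nx, arma::uword ny) {
  return x + nx * (y + ny * z);
}

static IntegerVector dims5(const NumericVector& a) {
  IntegerVector d = a.attr("dim");
  if (d.size() != 5) stop("expected a 5-D array (nx, ny, nz, C, B)");
  return d;
}

// Direct 3x3x3 convolution with zero padding 1: per (ci, co, ky, kz) plane
// pair, a fused row stencil out[x] += w0*src[x-1] + w1*src[x] + w2*src[x+1].
static inline void row_stencil(double* dst, const double* src, arma::uword nx,
                               double w0, double w1, double w2) {
  dst[0] += w1 * src[0] + w2 * src[1];
  for (arma::uword x = 1; x + 1 < nx; ++x)
    dst[x] += w0 * src[x - 1] + w1 * src[x] + w2 * src[x + 1];
  dst[nx - 1] += w0 * src[nx - 2] + w1 * src[nx - 1];
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector bias) {
  IntegerVector dx = dims5(x);
  IntegerVector dw = w.attr("dim");
  if (dw.size() != 5 || dw[0] != 3 || dw[1] != 3 || dw[2] != 3)
    stop("kernel must be 3 x 3 x 3 x Cin x Cout");
  const arma::uword nx = dx[0], ny = dx[1], nz = dx[2];
  const arma::uword ci = dx[3], B = dx[4], co = dw[4];
  if ((arma::uword)dw[3] != ci) stop("kernel Cin mismatch");
  if ((arma::uword)bias.size() != co) stop("bias length mismatch");
  const arma::uword nvox = nx * ny * nz;

  NumericVector out(nvox * co * B);
  out.attr("dim") = IntegerVector::create(dx[0], dx[1], dx[2], (int)co, (int)B);
  const double* W = w.begin();
  for (arma::uword b = 0; b < B; ++b) {
    const double* xs = x.begin() + b * nvox * ci;
    double* ys = out.begin() + b * nvox * co;
    for (arma::uword c = 0; c < co; ++c) {
      double* yc = ys + c * nvox;
      std::fill(yc, yc + nvox, bias[c]);
      for (arma::uword ic = 0; ic < ci; ++ic) {
        const double* xc = xs + ic * nvox;
        const double* w27 = W + 27 * (ic + ci * c);
        for (int kz = 0; kz < 3; ++kz)
          for (int ky = 0; ky < 3; ++ky) {
            const double* w3 = w27 + 3 * ky + 9 * kz;
            const int oy = ky - 1, oz = kz - 1;
            for (arma::uword z = 0; z < nz; ++z) {
              const int sz = (int)z + oz;
              if (sz < 0 || sz >= (int)nz) continue;
              for (arma::uword y = 0; y < ny; ++y) {
                const int sy = (int)y + oy;
                if (sy < 0 || sy >= (int)ny) continue;
                row_stencil(yc + vox(0, y, z, nx, ny),
                            xc + vox(0, (arma::uword)sy, (arma::uword)sz, nx, ny),
                            nx, w3[0], w3[1], w3[2]);
              }
            }
          }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector dx_ = dims5(x);
  IntegerVector dw_ = w.attr("dim");
  const arma::uword nx = dx_[0], ny = dx_[1], nz = dx_[2];
  const arma::uword ci = dx_[3], B = dx_[4], co = dw_[4];
  const arma::uword nvox = nx * ny * nz;

  NumericVector dxv(x.size());
  dxv.attr("dim") = x.attr("dim");
  NumericVector dwv(w.size());
  dwv.attr("dim") = w.attr("dim");
  NumericVector dbv(co);
  const double* W = w.begin();
  double* dW = dwv.begin();

  for (arma::uword b = 0; b < B; ++b) {
    const double* xs = x.begin() + b * nvox * ci;
    const double* dys = dy.begin() + b * nvox * co;
    double* dxs = dxv.begin() + b * nvox * ci;
    for (arma::uword c = 0; c < co; ++c) {
      const double* gc = dys + c * nvox;
      // bias gradient
      double sb = 0;
      for (arma::uword v = 0; v < nvox; ++v) sb += gc[v];
      dbv[c] += sb;
      for (arma::uword ic = 0; ic < ci; ++ic) {
        const double* xc = xs + ic * nvox;
        double* dxc = dxs + ic * nvox;
        const double* w27 = W + 27 * (ic + ci * c);
        double* dw27 = dW + 27 * (ic + ci * c);
        for (int kz = 0; kz < 3; ++kz)
          for (int ky = 0; ky < 3; ++ky) {
            const double* w3 = w27 + 3 * ky + 9 * kz;
            double* dw3 = dw27 + 3 * ky + 9 * kz;
            const int oy = ky - 1, oz = kz - 1;
            double s0 = 0, s1 = 0, s2 = 0;
            for (arma::uword z = 0; z < nz; ++z) {
              const int sz = (int)z + oz;
              if (sz < 0 || sz >= (int)nz) continue;
              for (arma::uword y = 0; y < ny; ++y) {
                const int sy = (int)y + oy;
                if (sy < 0 || sy >= (int)ny) continue;
                const double* src = xc + vox(0, (arma::uword)sy, (arma::uword)sz, nx, ny);
                double* dsrc = dxc + vox(0, (arma::uword)sy, (arma::uword)sz, nx, ny);
                const double* grow = gc + vox(0, y, z, nx, ny);
                // weight gradient: correlate input row with output gradient
                s1 += src[0] * grow[0];
                s2 += src[1] * grow[0];
                for (arma::uword xx = 1; xx + 1 < nx; ++xx) {
                  s0 += src[xx - 1] * grow[xx];
                  s1 += src[xx] * grow[xx];
                  s2 += src[xx + 1] * grow[xx];
                }
                s0 += src[nx - 2] * grow[nx - 1];
                s1 += src[nx - 1] * grow[nx - 1];
                // data gradient: adjoint row stencil (scatter of grow into dsrc)
                const double w0 = w3[0], w1 = w3[1], w2 = w3[2];
                dsrc[0] += w1 * grow[0] + w0 * grow[1];
                for (arma::uword xx = 1; xx + 1 < nx; ++xx)
                  dsrc[xx] += w2 * grow[xx - 1] + w1 * grow[xx] + w0 * grow[xx + 1];
                dsrc[nx - 1] += w2 * grow[nx - 2] + w1 * grow[nx - 1];
              }
            }
            dw3[0] += s0; dw3[1] += s1; dw3[2] += s2;
          }
      }
    }
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export(name = ".maxpool3d_fwd")]]
List maxpool3d_fwd(NumericVector x) {
  IntegerVector d = dims5(x);
  const arma::uword nx = d[0], ny = d[1], nz = d[2], C = d[3], B = d[4];
  if (nx % 2 || ny % 2 || nz % 2) stop("spatial dims must be even for 2x2x2 pooling");
  const arma::uword ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const arma::uword nvox = nx * ny * nz, ovox = ox * oy * oz;

  NumericVector y(ovox * C * B);
  y.attr("dim") = IntegerVector::create((int)ox, (int)oy, (int)oz, (int)C, (int)B);
  IntegerVector idx(ovox * C * B);   // 0-based linear index into x

  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (arma::uword cb = 0; cb < C * B; ++cb) {
    const double* xs = xp + cb * nvox;
    for (arma::uword z = 0; z < oz; ++z)
      for (arma::uword yy = 0; yy < oy; ++yy)
        for (arma::uword xx = 0; xx < ox; ++xx) {
          double best = -std::numeric_limits<double>::infinity();
          arma::uword besti = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dyy = 0; dyy < 2; ++dyy)
              for (int dxx = 0; dxx < 2; ++dxx) {
                arma::uword li = vox(2 * xx + dxx, 2 * yy + dyy, 2 * z + dz, nx, ny);
                if (xs[li] > best) { best = xs[li]; besti = li; }
              }
          arma::uword o = vox(xx, yy, z, ox, oy) + cb * ovox;
          yp[o] = best;
          ip[o] = (int)(besti + cb * nvox);
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool3d_bwd")]]
NumericVector maxpool3d_bwd(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  arma::uword n = 1;
  for (int i = 0; i < xdim.size(); ++i) n *= (arma::uword)xdim[i];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) dxp[ip[i]] += dyp[i];
  return dx;
}

// Factor-2 trilinear upsampling, half-voxel-centre alignment:
// output voxel o samples input coordinate (o + 0.5)/2 - 0.5, edge-clamped.
static void up_axis(arma::uword o, arma::uword n, arma::uword& i0, arma::uword& i1,
                    double& w1) {
  double s = (o + 0.5) / 2.0 - 0.5;
  if (s <= 0) { i0 = i1 = 0; w1 = 0; return; }
  if (s >= n - 1) { i0 = i1 = n - 1; w1 = 0; return; }
  i0 = (arma::uword)std::floor(s);
  i1 = i0 + 1;
  w1 = s - i0;
}

// [[Rcpp::export(name = ".upsample3d_fwd")]]
NumericVector upsample3d_fwd(NumericVector x) {
  IntegerVector d = dims5(x);
  const arma::uword nx = d[0], ny = d[1], nz = d[2], C = d[3], B = d[4];
  const arma::uword ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  const arma::uword nvox = nx * ny * nz, ovox = ox * oy * oz;
  NumericVector y(ovox * C * B);
  y.attr("dim") = IntegerVector::create((int)ox, (int)oy, (int)oz, (int)C, (int)B);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (arma::uword cb = 0; cb < C * B; ++cb) {
    const double* xs = xp + cb * nvox;
    double* ys = yp + cb * ovox;
    for (arma::uword z = 0; z < oz; ++z) {
      arma::uword z0, z1; double wz;
      up_axis(z, nz, z0, z1, wz);
      for (arma::uword yy = 0; yy < oy; ++yy) {
        arma::uword y0, y1; double wy;
        up_axis(yy, ny, y0, y1, wy);
        for (arma::uword xx = 0; xx < ox; ++xx) {
          arma::uword x0, x1; double wx;
          up_axis(xx, nx, x0, x1, wx);
          double v =
            (1-wz)*((1-wy)*((1-wx)*xs[vox(x0,y0,z0,nx,ny)] + wx*xs[vox(x1,y0,z0,nx,ny)]) +
                       wy *((1-wx)*xs[vox(x0,y1,z0,nx,ny)] + wx*xs[vox(x1,y1,z0,nx,ny)])) +
               wz *((1-wy)*((1-wx)*xs[vox(x0,y0,z1,nx,ny)] + wx*xs[vox(x1,y0,z1,nx,ny)]) +
                       wy *((1-wx)*xs[vox(x0,y1,z1,nx,ny)] + wx*xs[vox(x1,y1,z1,nx,ny)]));
          ys[vox(xx, yy, z, ox, oy)] = v;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".upsample3d_bwd")]]
NumericVector upsample3d_bwd(NumericVector dy) {
  IntegerVector d = dims5(dy);
  const arma::uword ox = d[0], oy = d[1], oz = d[2], C = d[3], B = d[4];
  if (ox % 2 || oy % 2 || oz % 2) stop("upsampled dims must be even");
  const arma::uword nx = ox / 2, ny = oy / 2, nz = oz / 2;
  const arma::uword nvox = nx * ny * nz, ovox = ox * oy * oz;
  NumericVector dx(nvox * C * B);
  dx.attr("dim") = IntegerVector::create((int)nx, (int)ny, (int)nz, (int)C, (int)B);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (arma::uword cb = 0; cb < C * B; ++cb) {
    const double* ds = dyp + cb * ovox;
    double* xs = dxp + cb * nvox;
    for (arma::uword z = 0; z < oz; ++z) {
      arma::uword z0, z1; double wz;
      up_axis(z, nz, z0, z1, wz);
      for (arma::uword yy = 0; yy < oy; ++yy) {
        arma::uword y0, y1; double wy;
        up_axis(yy, ny, y0, y1, wy);
        for (arma::uword xx = 0; xx < ox; ++xx) {
          arma::uword x0, x1; double wx;
          up_axis(xx, nx, x0, x1, wx);
          const double g = ds[vox(xx, yy, z, ox, oy)];
          xs[vox(x0,y0,z0,nx,ny)] += g*(1-wz)*(1-wy)*(1-wx);
          xs[vox(x1,y0,z0,nx,ny)] += g*(1-wz)*(1-wy)*wx;
          xs[vox(x0,y1,z0,nx,ny)] += g*(1-wz)*wy*(1-wx);
          xs[vox(x1,y1,z0,nx,ny)] += g*(1-wz)*wy*wx;
          xs[vox(x0,y0,z1,nx,ny)] += g*wz*(1-wy)*(1-wx);
          xs[vox(x1,y0,z1,nx,ny)] += g*wz*(1-wy)*wx;
          xs[vox(x0,y1,z1,nx,ny)] += g*wz*wy*(1-wx);
          xs[vox(x1,y1,z1,nx,ny)] += g*wz*wy*wx;
        }
      }
    }
  }
  return dx;
}
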