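// Dense 3D convolution and max-pooling kernels (valid padding, dilation 1).
// Array layout is R column-major: activations (X, Y, Z, C, N), convolution
// weights (KX, KY, KZ, Cin, Cout). Output extents follow
// floor((I - K)/S) + 1, so every kernel window lies fully inside the input.
#include <Rcpp.h>
using namespace Rcpp;

static inline int out_extent(int I, int K, int S) { return (I - K) / S + 1; }

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector b, IntegerVector stride) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3], N = xd[4];
  const int KX = wd[0], KY = wd[1], KZ = wd[2], Ci = wd[3], Co = wd[4];
  const int SX = stride[0], SY = stride[1], SZ = stride[2];
  if (Ci != C) stop("conv3d: input channels (%d) do not match weights (%d)", C, Ci);
  if (KX > X || KY > Y || KZ > Z)
    stop("conv3d: kernel exceeds input extent");
  const int OX = out_extent(X, KX, SX);
  const int OY = out_extent(Y, KY, SY);
  const int OZ = out_extent(Z, KZ, SZ);

  NumericVector y((R_xlen_t)OX * OY * OZ * Co * N);
  const double *px = REAL(x), *pw = REAL(w), *pb = REAL(b);
  double *py = REAL(y);
  const R_xlen_t xs = (R_xlen_t)X * Y * Z;   // one input channel slice
  const R_xlen_t ys = (R_xlen_t)OX * OY * OZ; // one output channel slice

  for (int n = 0; n < N; ++n) {
    for (int oc = 0; oc < Co; ++oc) {
      double *yb = py + ys * (oc + (R_xlen_t)Co * n);
      const double bias = pb[oc];
      for (R_xlen_t i = 0; i < ys; ++i) yb[i] = bias;
      for (int ic = 0; ic < C; ++ic) {
        const double *xb = px + xs * (ic + (R_xlen_t)C * n);
        for (int kz = 0; kz < KZ; ++kz)
        for (int ky = 0; ky < KY; ++ky)
        for (int kx = 0; kx < KX; ++kx) {
          const double wv = pw[kx + KX * (ky + (R_xlen_t)KY *
                              (kz + (R_xlen_t)KZ * (ic + (R_xlen_t)C * oc)))];
          if (wv == 0.0) continue;
          for (int oz = 0; oz < OZ; ++oz) {
            const int iz = oz * SZ + kz;
            for (int oy = 0; oy < OY; ++oy) {
              const int iy = oy * SY + ky;
              const double *xr = xb + kx + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz);
              double *yr = yb + (R_xlen_t)OX * (oy + (R_xlen_t)OY * oz);
              if (SX == 1) {
                for (int ox = 0; ox < OX; ++ox) yr[ox] += wv * xr[ox];
              } else {
                for (int ox = 0; ox < OX; ++ox) yr[ox] += wv * xr[(R_xlen_t)ox * SX];
              }
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(OX, OY, OZ, Co, N);
  return y;
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    IntegerVector stride, bool want_gx) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3], N = xd[4];
  const int KX = wd[0], KY = wd[1], KZ = wd[2], Co = wd[4];
  const int SX = stride[0], SY = stride[1], SZ = stride[2];
  const int OX = out_extent(X, KX, SX);
  const int OY = out_extent(Y, KY, SY);
  const int OZ = out_extent(Z, KZ, SZ);

  NumericVector gx(want_gx ? x.size() : 0);
  NumericVector gw(w.size());
  NumericVector gb(Co);
  const double *px = REAL(x), *pw = REAL(w), *pg = REAL(gy);
  double *pgx = want_gx ? REAL(gx) : NULL;
  double *pgw = REAL(gw), *pgb = REAL(gb);
  const R_xlen_t xs = (R_xlen_t)X * Y * Z;
  const R_xlen_t ys = (R_xlen_t)OX * OY * OZ;

  for (int n = 0; n < N; ++n) {
    for (int oc = 0; oc < Co; ++oc) {
      const double *gb_slice = pg + ys * (oc + (R_xlen_t)Co * n);
      double acc = 0.0;
      for (R_xlen_t i = 0; i < ys; ++i) acc += gb_slice[i];
      pgb[oc] += acc;
      for (int ic = 0; ic < C; ++ic) {
        const double *xb = px + xs * (ic + (R_xlen_t)C * n);
        double *gxb = want_gx ? pgx + xs * (ic + (R_xlen_t)C * n) : NULL;
        for (int kz = 0; kz < KZ; ++kz)
        for (int ky = 0; ky < KY; ++ky)
        for (int kx = 0; kx < KX; ++kx) {
          const R_xlen_t wi = kx + KX * (ky + (R_xlen_t)KY *
                               (kz + (R_xlen_t)KZ * (ic + (R_xlen_t)C * oc)));
          const double wv = pw[wi];
          double gwacc = 0.0;
          for (int oz = 0; oz < OZ; ++oz) {
            const int iz = oz * SZ + kz;
            for (int oy = 0; oy < OY; ++oy) {
              const int iy = oy * SY + ky;
              const R_xlen_t xoff = kx + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz);
              const double *xr = xb + xoff;
              const double *gr = gb_slice + (R_xlen_t)OX * (oy + (R_xlen_t)OY * oz);
              if (want_gx) {
                double *gxr = gxb + xoff;
                if (SX == 1) {
                  for (int ox = 0; ox < OX; ++ox) {
                    const double g = gr[ox];
                    gxr[ox] += wv * g;
                    gwacc += xr[ox] * g;
                  }
                } else {
                  for (int ox = 0; ox < OX; ++ox) {
                    const double g = gr[ox];
                    gxr[(R_xlen_t)ox * SX] += wv * g;
                    gwacc += xr[(R_xlen_t)ox * SX] * g;
                  }
                }
              } else {
                if (SX == 1) {
                  for (int ox = 0; ox < OX; ++ox) gwacc += xr[ox] * gr[ox];
                } else {
                  for (int ox = 0; ox < OX; ++ox) gwacc += xr[(R_xlen_t)ox * SX] * gr[ox];
                }
              }
            }
          }
          pgw[wi] += gwacc;
        }
      }
    }
  }
  if (want_gx) gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List pool3d_fwd_cpp(NumericVector x, IntegerVector kernel, IntegerVector stride) {
  IntegerVector xd = x.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3], N = xd[4];
  const int KX = kernel[0], KY = kernel[1], KZ = kernel[2];
  const int SX = stride[0], SY = stride[1], SZ = stride[2];
  if (KX > X || KY > Y || KZ > Z) stop("maxpool3d: kernel exceeds input extent");
  const int OX = out_extent(X, KX, SX);
  const int OY = out_extent(Y, KY, SY);
  const int OZ = out_extent(Z, KZ, SZ);

  NumericVector y((R_xlen_t)OX * OY * OZ * C * N);
  IntegerVector idx(y.size()); // spatial argmax index within the (c, n) slice
  const double *px = REAL(x);
  double *py = REAL(y);
  int *pi = INTEGER(idx);
  const R_xlen_t xs = (R_xlen_t)X * Y * Z;
  R_xlen_t o = 0;
  for (R_xlen_t s = 0; s < (R_xlen_t)C * N; ++s) {
    const double *xb = px + xs * s;
    for (int oz = 0; oz < OZ; ++oz)
    for (int oy = 0; oy < OY; ++oy)
    for (int ox = 0; ox < OX; ++ox) {
      double best = R_NegInf;
      int besti = 0;
      for (int kz = 0; kz < KZ; ++kz) {
        const int iz = oz * SZ + kz;
        for (int ky = 0; ky < KY; ++ky) {
          const int iy = oy * SY + ky;
          for (int kx = 0; kx < KX; ++kx) {
            const int ix = ox * SX + kx;
            const int ii = ix + X * (iy + Y * iz);
            const double v = xb[ii];
            if (v > best) { best = v; besti = ii; }
          }
        }
      }
      py[o] = best;
      pi[o] = besti;
      ++o;
    }
  }
  IntegerVector od = IntegerVector::create(OX, OY, OZ, C, N);
  y.attr("dim") = od;
  idx.attr("dim") = od;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector pool3d_bwd_cpp(IntegerVector idx, NumericVector gy, IntegerVector xdim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3], N = xdim[4];
  NumericVector gx((R_xlen_t)X * Y * Z * C * N);
  const R_xlen_t xs = (R_xlen_t)X * Y * Z;
  const R_xlen_t per_slice = gy.size() / ((R_xlen_t)C * N);
  double *pgx = REAL(gx);
  const double *pg = REAL(gy);
  const int *pi = INTEGER(idx);
  R_xlen_t o = 0;
  for (R_xlen_t s = 0; s < (R_xlen_t)C * N; ++s) {
    double *gxb = pgx + xs * s;
    for (R_xlen_t k = 0; k < per_slice; ++k, ++o) gxb[pi[o]] += pg[o];
  }
  gx.attr("dim") = xdim;
  return gx;
}

// im2col: unfold all valid kernel windows into a (KX*KY*KZ*C, OX*OY*OZ*N)
// matrix whose row order matches the flattened weight array, so convolution
// becomes one GEMM against the (K, Cout) weight matrix.
// [[Rcpp::export]]
NumericMatrix im2col3d_cpp(NumericVector x, IntegerVector kernel,
                           IntegerVector stride) {
  IntegerVector xd = x.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3], N = xd[4];
  const int KX = kernel[0], KY = kernel[1], KZ = kernel[2];
  const int SX = stride[0], SY = stride[1], SZ = stride[2];
  const int OX = out_extent(X, KX, SX);
  const int OY = out_extent(Y, KY, SY);
  const int OZ = out_extent(Z, KZ, SZ);
  const R_xlen_t K = (R_xlen_t)KX * KY * KZ * C;
  const R_xlen_t M = (R_xlen_t)OX * OY * OZ * N;
  NumericMatrix out(no_init(K, M));
  const double *px = REAL(x);
  double *po = REAL(out);
  const R_xlen_t xs = (R_xlen_t)X * Y * Z;
  R_xlen_t col = 0;
  for (int n = 0; n < N; ++n)
  for (int oz = 0; oz < OZ; ++oz)
  for (int oy = 0; oy < OY; ++oy)
  for (int ox = 0; ox < OX; ++ox, ++col) {
    double *oc = po + K * col;
    R_xlen_t row = 0;
    for (int ic = 0; ic < C; ++ic) {
      const double *xb = px + xs * (ic + (R_xlen_t)C * n);
      for (int kz = 0; kz < KZ; ++kz) {
        const int iz = oz * SZ + kz;
        for (int ky = 0; ky < KY; ++ky) {
          const int iy = oy * SY + ky;
          const double *xr = xb + (R_xlen_t)ox * SX + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz);
          for (int kx = 0; kx < KX; ++kx) oc[row++] = xr[kx];
        }
      }
    }
  }
  return out;
}

// scatter-add the unfolded gradient back onto the input grid
// [[Rcpp::export]]
NumericVector col2im3d_cpp(NumericMatrix gcol, IntegerVector xdim,
                           IntegerVector kernel, IntegerVector stride) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3], N = xdim[4];
  const int KX = kernel[0], KY = kernel[1], KZ = kernel[2];
  const int SX = stride[0], SY = stride[1], SZ = stride[2];
  const int OX = out_extent(X, KX, SX);
  const int OY = out_extent(Y, KY, SY);
  const int OZ = out_extent(Z, KZ, SZ);
  const R_xlen_t K = (R_xlen_t)KX * KY * KZ * C;
  NumericVector gx((R_xlen_t)X * Y * Z * C * N);
  double *pgx = REAL(gx);
  const double *pg = REAL(gcol);
  const R_xlen_t xs = (R_xlen_t)X * Y * Z;
  R_xlen_t col = 0;
  for (int n = 0; n < N; ++n)
  for (int oz = 0; oz < OZ; ++oz)
  for (int oy = 0; oy < OY; ++oy)
  for (int ox = 0; ox < OX; ++ox, ++col) {
    const double *gc = pg + K * col;
    R_xlen_t row = 0;
    for (int ic = 0; ic < C; ++ic) {
      double *gb = pgx + xs * (ic + (R_xlen_t)C * n);
      for (int kz = 0; kz < KZ; ++kz) {
        const int iz = oz * SZ + kz;
        for (int ky = 0; ky < KY; ++ky) {
          const int iy = oy * SY + ky;
          double *gr = gb + (R_xlen_t)ox * SX + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz);
          for (int kx = 0; kx < KX; ++kx) gr[kx] += gc[row++];
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  return gx;
}
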