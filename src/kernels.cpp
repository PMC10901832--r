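// Numerical kernels: the truncated-record spectral forward model and the 3D
// convolution / pooling primitives used by the network layers.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <complex>
#include <cmath>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif

using namespace Rcpp;

typedef std::complex<double> cplx;

// Exact DFT of the truncated free-space record of a homogeneous medium.
//
// Per detector-wavenumber column (rows of Pf), the recorded field is the
// Riemann mode sum g(t) = (1/nzf) sum_m Pf(m) cos(c |k_m| t) over the finely
// sampled depth wavenumbers kzf (zero-padded spectrum of the compact p0, so
// periodic ghost copies lie beyond the record). Its nt-point DFT is computed
// in closed form with one-sided Dirichlet kernels
//   S(alpha) = sum_{j=0}^{nt-1} e^{i alpha j} = (1 - e^{i alpha nt})
//              / (1 - e^{i alpha}),
// giving D(l) = (1/(2 nzf)) sum_m Pf(m) [S(th_m - ph_l) + S(th_m + ph_l)]
// with th_m = c |k_m| dt and ph_l = 2 pi l / nt.
// [[Rcpp::export]]
ComplexMatrix fwd_record_dft_cpp(const ComplexMatrix& Pf,
                                 const NumericVector& k2perp,
                                 const NumericVector& kzf,
                                 double c0, double dt, int nt) {
  const int nxy = Pf.nrow();
  const int nzf = Pf.ncol();
  ComplexMatrix D(nxy, nt);
  std::vector<cplx> eph(nt);
  for (int l = 0; l < nt; ++l) {
    double ph = 2.0 * M_PI * l / nt;
    eph[l] = cplx(std::cos(ph), std::sin(ph));
  }
  const double tol = 1e-9;
  std::vector<cplx> acc(nt);
  for (int a = 0; a < nxy; ++a) {
    std::fill(acc.begin(), acc.end(), cplx(0.0, 0.0));
    for (int m = 0; m < nzf; ++m) {
      Rcomplex pf = Pf(a, m);
      if (pf.r == 0.0 && pf.i == 0.0) continue;
      cplx P(pf.r, pf.i);
      double th = c0 * std::sqrt(k2perp[a] + kzf[m] * kzf[m]) * dt;
      cplx eth(std::cos(th), std::sin(th));
      double thn = th * nt;
      cplx num = cplx(1.0, 0.0) - cplx(std::cos(thn), std::sin(thn));
      for (int l = 0; l < nt; ++l) {
        // S(th - ph_l): e^{i(th-ph)} = eth * conj(eph)
        cplx dminus = cplx(1.0, 0.0) - eth * std::conj(eph[l]);
        cplx Sm = (std::abs(dminus.real()) + std::abs(dminus.imag()) < tol)
                      ? cplx((double)nt, 0.0)
                      : num / dminus;
        // S(-(th + ph_l)) = conj(S(th + ph_l)) for real th, ph
        cplx dplus = cplx(1.0, 0.0) - eth * eph[l];
        cplx Sp = (std::abs(dplus.real()) + std::abs(dplus.imag()) < tol)
                      ? cplx((double)nt, 0.0)
                      : std::conj(num / dplus);
        acc[l] += P * (Sm + Sp);
      }
    }
    for (int l = 0; l < nt; ++l) {
      cplx v = acc[l] / (2.0 * nzf);
      D(a, l) = Rcomplex{v.real(), v.imag()};
    }
  }
  return D;
}

// ---- 3D convolution primitives ---------------------------------------------
// Tensors are flat numeric vectors in R's column-major layout with dims
// (nx, ny, nz, channels); kernels (kw, kw, kw, cin, cout) with odd kw and
// zero padding that preserves the spatial shape. Convolutions are evaluated
// per z-slice as im2col followed by a BLAS dgemm.

static inline int idx4(int x, int y, int z, int c, int nx, int ny, int nz) {
  return x + nx * (y + ny * (z + nz * c));
}

// fill the im2col buffer for output slice z: rows (x,y) in column-major
// order, columns (kx, ky, kz, ci)
static void im2col_slice(const double* px, int nx, int ny, int nz, int cin,
                         int kw, int z, double* col) {
  const int h = kw / 2;
  const int nxy = nx * ny;
  int cc = 0;
  for (int ci = 0; ci < cin; ++ci) {
    const double* xv = px + (size_t)nxy * nz * ci;
    for (int kz = 0; kz < kw; ++kz) {
      const int zz = z + kz - h;
      for (int ky = 0; ky < kw; ++ky) {
        for (int kx = 0; kx < kw; ++kx, ++cc) {
          double* dst = col + (size_t)cc * nxy;
          if (zz < 0 || zz >= nz) {
            std::fill(dst, dst + nxy, 0.0);
            continue;
          }
          const int ox = kx - h, oy = ky - h;
          for (int y = 0; y < ny; ++y) {
            const int yy = y + oy;
            double* drow = dst + (size_t)y * nx;
            if (yy < 0 || yy >= ny) {
              std::fill(drow, drow + nx, 0.0);
              continue;
            }
            const double* xrow = xv + (size_t)nx * (yy + (size_t)ny * zz);
            const int x0 = std::max(0, -ox), x1 = std::min(nx, nx - ox);
            for (int x = 0; x < x0; ++x) drow[x] = 0.0;
            for (int x = x0; x < x1; ++x) drow[x] = xrow[x + ox];
            for (int x = x1; x < nx; ++x) drow[x] = 0.0;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(const NumericVector& x, const NumericVector& w,
                             const NumericVector& bias,
                             IntegerVector dims, int kw, int cin, int cout) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nxy = nx * ny;
  const int kcols = kw * kw * kw * cin;
  NumericVector out((size_t)nxy * nz * cout);
  std::vector<double> col((size_t)nxy * kcols);
  const double one = 1.0, zero = 0.0;
  for (int z = 0; z < nz; ++z) {
    im2col_slice(x.begin(), nx, ny, nz, cin, kw, z, col.data());
    // Y (nxy x cout) = col (nxy x kcols) * W (kcols x cout)
    std::vector<double> y((size_t)nxy * cout);
    F77_CALL(dgemm)("N", "N", &nxy, &cout, &kcols, &one, col.data(), &nxy,
                    const_cast<double*>(w.begin()), &kcols, &zero, y.data(),
                    &nxy FCONE FCONE);
    for (int co = 0; co < cout; ++co) {
      const double b = bias[co];
      double* dst = out.begin() + idx4(0, 0, z, co, nx, ny, nz);
      const double* src = y.data() + (size_t)co * nxy;
      for (int v = 0; v < nxy; ++v) dst[v] = src[v] + b;
    }
  }
  return out;
}

// gradient w.r.t. the input: convolution of gy with the flipped kernel and
// transposed channels, via the same im2col machinery
// [[Rcpp::export]]
NumericVector conv3d_bwd_input_cpp(const NumericVector& gy,
                                   const NumericVector& w,
                                   IntegerVector dims, int kw, int cin,
                                   int cout) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nxy = nx * ny;
  const int kvol = kw * kw * kw;
  // build flipped/transposed kernel: wt[(k), co, ci] = w[flip(k), ci, co]
  std::vector<double> wt((size_t)kvol * cout * cin);
  for (int co = 0; co < cout; ++co) {
    for (int ci = 0; ci < cin; ++ci) {
      for (int k = 0; k < kvol; ++k) {
        wt[(kvol - 1 - k) + (size_t)kvol * (co + (size_t)cout * ci)] =
            w[k + (size_t)kvol * (ci + (size_t)cin * co)];
      }
    }
  }
  const int kcols = kvol * cout;
  NumericVector gx((size_t)nxy * nz * cin);
  std::vector<double> col((size_t)nxy * kcols);
  const double one = 1.0, zero = 0.0;
  for (int z = 0; z < nz; ++z) {
    im2col_slice(gy.begin(), nx, ny, nz, cout, kw, z, col.data());
    std::vector<double> y((size_t)nxy * cin);
    F77_CALL(dgemm)("N", "N", &nxy, &cin, &kcols, &one, col.data(), &nxy,
                    wt.data(), &kcols, &zero, y.data(), &nxy FCONE FCONE);
    for (int ci = 0; ci < cin; ++ci) {
      double* dst = gx.begin() + idx4(0, 0, z, ci, nx, ny, nz);
      const double* src = y.data() + (size_t)ci * nxy;
      std::copy(src, src + nxy, dst);
    }
  }
  return gx;
}

// gradients w.r.t. kernel and bias: GW = sum_z col_z^T * GY_z
// [[Rcpp::export]]
List conv3d_bwd_weight_cpp(const NumericVector& x, const NumericVector& gy,
                           IntegerVector dims, int kw, int cin, int cout) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nxy = nx * ny;
  const int kcols = kw * kw * kw * cin;
  NumericVector gw((size_t)kcols * cout);
  NumericVector gb(cout);
  std::vector<double> col((size_t)nxy * kcols);
  std::vector<double> gyz((size_t)nxy * cout);
  const double one = 1.0;
  for (int z = 0; z < nz; ++z) {
    im2col_slice(x.begin(), nx, ny, nz, cin, kw, z, col.data());
    for (int co = 0; co < cout; ++co) {
      const double* src = gy.begin() + idx4(0, 0, z, co, nx, ny, nz);
      double* dst = gyz.data() + (size_t)co * nxy;
      std::copy(src, src + nxy, dst);
      double s = 0.0;
      for (int v = 0; v < nxy; ++v) s += src[v];
      gb[co] += s;
    }
    F77_CALL(dgemm)("T", "N", &kcols, &cout, &nxy, &one, col.data(), &nxy,
                    gyz.data(), &nxy, &one, gw.begin(), &kcols FCONE FCONE);
  }
  return List::create(_["gw"] = gw, _["gb"] = gb);
}

// 2x2x2 max pooling; returns pooled values and argmax linear indices (1-based
// into the input) for the backward pass
// [[Rcpp::export]]
List maxpool3d_cpp(const NumericVector& x, IntegerVector dims, int ch) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = nx / 2, my = ny / 2, mz = nz / 2;
  NumericVector out(mx * my * mz * ch);
  IntegerVector arg(mx * my * mz * ch);
  const double* px = x.begin();
  for (int c = 0; c < ch; ++c) {
    for (int z = 0; z < mz; ++z) {
      for (int y = 0; y < my; ++y) {
        for (int xx = 0; xx < mx; ++xx) {
          double best = -INFINITY;
          int bi = 0;
          for (int dz = 0; dz < 2; ++dz) {
            for (int dy = 0; dy < 2; ++dy) {
              for (int dxk = 0; dxk < 2; ++dxk) {
                int i = idx4(2 * xx + dxk, 2 * y + dy, 2 * z + dz, c, nx, ny, nz);
                if (px[i] > best) {
                  best = px[i];
                  bi = i;
                }
              }
            }
          }
          int o = xx + mx * (y + my * (z + mz * c));
          out[o] = best;
          arg[o] = bi + 1;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd_cpp(const NumericVector& gy,
                                const IntegerVector& arg, int n_in) {
  NumericVector gx(n_in);
  for (int i = 0; i < gy.size(); ++i) {
    gx[arg[i] - 1] += gy[i];
  }
  return gx;
}

// nearest-neighbour 2x upsampling and its adjoint (block sum)
// [[Rcpp::export]]
NumericVector upsample3d_cpp(const NumericVector& x, IntegerVector dims, int ch) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ux = 2 * nx, uy = 2 * ny, uz = 2 * nz;
  NumericVector out(ux * uy * uz * ch);
  const double* px = x.begin();
  double* po = out.begin();
  for (int c = 0; c < ch; ++c) {
    for (int z = 0; z < uz; ++z) {
      for (int y = 0; y < uy; ++y) {
        const double* xrow = px + nx * ((y / 2) + ny * ((z / 2) + nz * c));
        double* orow = po + ux * (y + uy * (z + uz * c));
        for (int x = 0; x < ux; ++x) {
          orow[x] = xrow[x / 2];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector upsample3d_bwd_cpp(const NumericVector& gy, IntegerVector dims,
                                 int ch) {
  // dims are the coarse dims of the forward input
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ux = 2 * nx, uy = 2 * ny, uz = 2 * nz;
  NumericVector gx(nx * ny * nz * ch);
  const double* pg = gy.begin();
  double* po = gx.begin();
  for (int c = 0; c < ch; ++c) {
    for (int z = 0; z < uz; ++z) {
      for (int y = 0; y < uy; ++y) {
        const double* grow = pg + ux * (y + uy * (z + uz * c));
        double* orow = po + nx * ((y / 2) + ny * ((z / 2) + nz * c));
        for (int x = 0; x < ux; ++x) {
          orow[x / 2] += grow[x];
        }
      }
    }
  }
  return gx;
}
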