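// Low-level image/tensor kernels backing the network layers.
//
// Layout convention: an activation is an R array dim c(H, W, C) or batched
// c(H, W, C, N) (column-major, rows fastest). A conv weight is an R array
// dim c(kh, kw, Cin, Cout); flattened column-major it gives the
// (kh*kw*Cin) x Cout weight matrix whose row index is di + kh*(dj + kw*c).
// im2col uses the same unrolling so plain GEMM performs the convolution.
// Loops run over output pixels in the outer position so each patch is
// written contiguously down one column of the patch matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col_ptr(const double* xp, int H, int W, int C,
                       int kh, int kw, int stride, int pad, arma::mat& cols) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  cols.zeros();
  const long HW = (long)H * W;
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      double* cp = cols.colptr((arma::uword)io + (arma::uword)Ho * jo);
      const int i0 = io * stride - pad;
      const int j0 = jo * stride - pad;
      for (int c = 0; c < C; ++c) {
        const double* xc = xp + (long)c * HW;
        for (int dj = 0; dj < kw; ++dj) {
          const int j = j0 + dj;
          if (j < 0 || j >= W) continue;  // stays zero
          double* dst = cp + kh * (dj + kw * c);
          const double* src = xc + (long)j * H + i0;
          if (i0 >= 0 && i0 + kh <= H) {
            for (int di = 0; di < kh; ++di) dst[di] = src[di];
          } else {
            for (int di = 0; di < kh; ++di) {
              const int i = i0 + di;
              if (i >= 0 && i < H) dst[di] = src[di];
            }
          }
        }
      }
    }
  }
}

static void col2im_ptr(const arma::mat& cols, int H, int W, int C,
                       int kh, int kw, int stride, int pad, double* xp) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const long HW = (long)H * W;
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      const double* cp = cols.colptr((arma::uword)io + (arma::uword)Ho * jo);
      const int i0 = io * stride - pad;
      const int j0 = jo * stride - pad;
      for (int c = 0; c < C; ++c) {
        double* xc = xp + (long)c * HW;
        for (int dj = 0; dj < kw; ++dj) {
          const int j = j0 + dj;
          if (j < 0 || j >= W) continue;
          const double* src = cp + kh * (dj + kw * c);
          double* dst = xc + (long)j * H + i0;
          if (i0 >= 0 && i0 + kh <= H) {
            for (int di = 0; di < kh; ++di) dst[di] += src[di];
          } else {
            for (int di = 0; di < kh; ++di) {
              const int i = i0 + di;
              if (i >= 0 && i < H) dst[di] += src[di];
            }
          }
        }
      }
    }
  }
}

// Batched convolution forward. x has dim c(H, W, C, N) (N may be 1); the
// result has dim c(Ho, Wo, cout, N).
// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, IntegerVector xdim,
                            const arma::mat& wm, const arma::vec& b,
                            int kh, int kw, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int cout = wm.n_cols;
  const long P = (long)Ho * Wo;
  NumericVector y((long)P * cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, cout, N);
  const bool one_by_one = (kh == 1 && kw == 1 && pad == 0 && stride == 1);
  arma::mat cols(one_by_one ? 1 : kh * kw * C, one_by_one ? 1 : P);
  for (int n = 0; n < N; ++n) {
    arma::mat ym(REAL(y) + (long)n * P * cout, P, cout, false, true);
    if (one_by_one) {
      const arma::mat xm(const_cast<double*>(REAL(x)) + (long)n * H * W * C,
                         P, C, false, true);
      ym = xm * wm;  // pointwise convolution is a plain channel mix
    } else {
      im2col_ptr(REAL(x) + (long)n * H * W * C, H, W, C, kh, kw, stride, pad,
                 cols);
      ym = cols.t() * wm;
    }
    ym.each_row() += b.t();
  }
  return y;
}

// Batched convolution backward: gradients for input, weights and bias.
// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bw(NumericVector x, IntegerVector xdim,
                         const arma::mat& wm, NumericVector g,
                         int kh, int kw, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int cout = wm.n_cols;
  const long P = (long)Ho * Wo;
  NumericVector dx((long)H * W * C * N);
  dx.attr("dim") = xdim;
  arma::mat dw(wm.n_rows, cout, arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  const bool one_by_one = (kh == 1 && kw == 1 && pad == 0 && stride == 1);
  arma::mat cols(one_by_one ? 1 : kh * kw * C, one_by_one ? 1 : P);
  for (int n = 0; n < N; ++n) {
    arma::mat gm(REAL(g) + (long)n * P * cout, P, cout, false, true);
    if (one_by_one) {
      const arma::mat xm(const_cast<double*>(REAL(x)) + (long)n * H * W * C,
                         P, C, false, true);
      arma::mat dxm(REAL(dx) + (long)n * H * W * C, P, C, false, true);
      dw += xm.t() * gm;
      db += arma::sum(gm, 0).t();
      dxm = gm * wm.t();
      continue;
    }
    im2col_ptr(REAL(x) + (long)n * H * W * C, H, W, C, kh, kw, stride, pad, cols);
    dw += cols * gm;
    db += arma::sum(gm, 0).t();
    arma::mat dcols = wm * gm.t();
    col2im_ptr(dcols, H, W, C, kh, kw, stride, pad,
               REAL(dx) + (long)n * H * W * C);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// Nearest-neighbour 2x upsampling over C*N slices.
// [[Rcpp::export]]
arma::cube cpp_upsample2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j) {
      const double* src = x.slice_colptr(c, j);
      double* d0 = y.slice_colptr(c, 2 * j);
      double* d1 = y.slice_colptr(c, 2 * j + 1);
      for (int i = 0; i < H; ++i) {
        const double v = src[i];
        d0[2 * i] = v; d0[2 * i + 1] = v;
        d1[2 * i] = v; d1[2 * i + 1] = v;
      }
    }
  return y;
}

// Adjoint of nearest-neighbour 2x upsampling (2x2 block sum).
// [[Rcpp::export]]
arma::cube cpp_downsum2(const arma::cube& g) {
  const int H = g.n_rows / 2, W = g.n_cols / 2, C = g.n_slices;
  arma::cube y(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j) {
      const double* s0 = g.slice_colptr(c, 2 * j);
      const double* s1 = g.slice_colptr(c, 2 * j + 1);
      double* dst = y.slice_colptr(c, j);
      for (int i = 0; i < H; ++i)
        dst[i] = s0[2 * i] + s0[2 * i + 1] + s1[2 * i] + s1[2 * i + 1];
    }
  return y;
}

// Instance-norm forward over an N_hw x CN column layout. Returns y and the
// cached standardised activations + inverse stds for the backward pass.
// [[Rcpp::export]]
Rcpp::List cpp_instnorm_fw(NumericVector x, int nhw, int cn,
                           const arma::vec& gv, const arma::vec& bv,
                           double eps) {
  NumericVector y(x.size());
  NumericVector xhat(x.size());
  arma::vec istd(cn);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  double* hp = REAL(xhat);
  for (int c = 0; c < cn; ++c) {
    const double* col = xp + (long)c * nhw;
    double mu = 0;
    for (int i = 0; i < nhw; ++i) mu += col[i];
    mu /= nhw;
    double v = 0;
    for (int i = 0; i < nhw; ++i) { const double d = col[i] - mu; v += d * d; }
    v /= nhw;
    const double is = 1.0 / std::sqrt(v + eps);
    istd[c] = is;
    const double gg = gv[c], bb = bv[c];
    double* yc = yp + (long)c * nhw;
    double* hc = hp + (long)c * nhw;
    for (int i = 0; i < nhw; ++i) {
      const double h = (col[i] - mu) * is;
      hc[i] = h;
      yc[i] = gg * h + bb;
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("istd") = istd);
}

// Instance-norm backward; dgamma/dbeta are returned per (channel, sample)
// column and folded across the batch by the caller.
// [[Rcpp::export]]
Rcpp::List cpp_instnorm_bw(NumericVector xhat, const arma::vec& istd,
                           NumericVector g, const arma::vec& gv,
                           int nhw, int cn) {
  NumericVector dx(g.size());
  arma::vec dgamma(cn), dbeta(cn);
  const double* hp = REAL(xhat);
  const double* gp = REAL(g);
  double* dp = REAL(dx);
  for (int c = 0; c < cn; ++c) {
    const double* hc = hp + (long)c * nhw;
    const double* gc = gp + (long)c * nhw;
    double* dc = dp + (long)c * nhw;
    double sg = 0, sgh = 0;
    for (int i = 0; i < nhw; ++i) { sg += gc[i]; sgh += gc[i] * hc[i]; }
    dgamma[c] = sgh;
    dbeta[c] = sg;
    const double gg = gv[c];
    const double c1 = gg * sg / nhw;
    const double c2 = gg * sgh / nhw;
    const double is = istd[c];
    for (int i = 0; i < nhw; ++i)
      dc[i] = (gg * gc[i] - c1 - hc[i] * c2) * is;
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
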