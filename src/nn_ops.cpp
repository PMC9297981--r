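// Minimal CNN kernels used by the U-Net engine: same-padding 2D convolution
// (stride 1, odd kernel), its gradients, 2x2/stride-2 transpose convolution,
// and 2x2 max pooling. Tensors are column-major R arrays laid out (H, W, C, N);
// convolution weights are (k, k, Cin, Cout), transpose weights (2, 2, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int idx4(int h, int w, int c, int n, int H, int W, int C) {
  return h + H * (w + W * (c + C * n));
}

// im2col for one sample: rows = k*k*Cin (kh fastest, then kw, then ci),
// cols = H*W (h fastest). Zero padding, stride 1.
static void im2col(const double* x, int H, int W, int C, int k, arma::mat& col) {
  const int p = (k - 1) / 2;
  for (int ci = 0; ci < C; ++ci)
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * (kw + k * ci);
        for (int w = 0; w < W; ++w) {
          const int ws = w + kw - p;
          if (ws < 0 || ws >= W) {
            for (int h = 0; h < H; ++h) col(r, h + H * w) = 0.0;
            continue;
          }
          const double* src = x + H * (ws + W * ci);
          for (int h = 0; h < H; ++h) {
            const int hs = h + kh - p;
            col(r, h + H * w) = (hs < 0 || hs >= H) ? 0.0 : src[hs];
          }
        }
      }
}

static void col2im(const arma::mat& col, int H, int W, int C, int k, double* dx) {
  const int p = (k - 1) / 2;
  for (int ci = 0; ci < C; ++ci)
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * (kw + k * ci);
        for (int w = 0; w < W; ++w) {
          const int ws = w + kw - p;
          if (ws < 0 || ws >= W) continue;
          double* dst = dx + H * (ws + W * ci);
          for (int h = 0; h < H; ++h) {
            const int hs = h + kh - p;
            if (hs >= 0 && hs < H) dst[hs] += col(r, h + H * w);
          }
        }
      }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, IntegerVector xdim,
                            NumericVector Wt, IntegerVector wdim,
                            NumericVector b) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int k = wdim[0], Cin = wdim[2], Cout = wdim[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  arma::mat Wm(Cout, k * k * Cin);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh)
          Wm(co, kh + k * (kw + k * ci)) = Wt[kh + k * (kw + k * (ci + Cin * co))];
  NumericVector out(static_cast<R_xlen_t>(H) * W * Cout * N);
  IntegerVector odim = IntegerVector::create(H, W, Cout, N);
  arma::mat col(k * k * Cin, H * W);
  for (int n = 0; n < N; ++n) {
    if (k == 1) {
      arma::mat xm(const_cast<double*>(&x[idx4(0, 0, 0, n, H, W, C)]), H * W, C, false);
      arma::mat om = xm * Wm.t();  // (HW x Cout)
      for (int co = 0; co < Cout; ++co)
        for (int j = 0; j < H * W; ++j)
          out[j + static_cast<R_xlen_t>(H) * W * (co + Cout * n)] = om(j, co) + b[co];
    } else {
      im2col(&x[idx4(0, 0, 0, n, H, W, C)], H, W, C, k, col);
      arma::mat om = Wm * col;  // (Cout x HW)
      for (int co = 0; co < Cout; ++co)
        for (int j = 0; j < H * W; ++j)
          out[j + static_cast<R_xlen_t>(H) * W * (co + Cout * n)] = om(co, j) + b[co];
    }
  }
  out.attr("dim") = odim;
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, IntegerVector xdim,
                   NumericVector Wt, IntegerVector wdim,
                   NumericVector dout) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int k = wdim[0], Cin = wdim[2], Cout = wdim[3];
  arma::mat Wm(Cout, k * k * Cin);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh)
          Wm(co, kh + k * (kw + k * ci)) = Wt[kh + k * (kw + k * (ci + Cin * co))];
  arma::mat dWm(Cout, k * k * Cin, arma::fill::zeros);
  NumericVector dx(x.size());
  NumericVector db(Cout);
  arma::mat col(k * k * Cin, H * W);
  for (int n = 0; n < N; ++n) {
    arma::mat dom(Cout, H * W);
    for (int co = 0; co < Cout; ++co) {
      double s = 0.0;
      const double* dsrc = &dout[idx4(0, 0, co, n, H, W, Cout)];
      for (int j = 0; j < H * W; ++j) { dom(co, j) = dsrc[j]; s += dsrc[j]; }
      db[co] += s;
    }
    im2col(&x[idx4(0, 0, 0, n, H, W, C)], H, W, C, k, col);
    dWm += dom * col.t();
    arma::mat dcol = Wm.t() * dom;
    col2im(dcol, H, W, C, k, &dx[idx4(0, 0, 0, n, H, W, C)]);
  }
  NumericVector dW(Wt.size());
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh)
          dW[kh + k * (kw + k * (ci + Cin * co))] = dWm(co, kh + k * (kw + k * ci));
  dW.attr("dim") = wdim;
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Transpose convolution, kernel 2, stride 2 (each input pixel expands into a
// disjoint 2x2 output block, so no output overlap).
// [[Rcpp::export]]
NumericVector cpp_convt2_fw(NumericVector x, IntegerVector xdim,
                            NumericVector Wt, NumericVector b) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector wd = Wt.attr("dim");
  const int Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("convt2: channel mismatch");
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector out(static_cast<R_xlen_t>(Ho) * Wo * Cout * N);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double* dst = &out[idx4(0, 0, co, n, Ho, Wo, Cout)];
      for (int j = 0; j < Ho * Wo; ++j) dst[j] = b[co];
      for (int ci = 0; ci < C; ++ci) {
        const double* src = &x[idx4(0, 0, ci, n, H, W, C)];
        const double w00 = Wt[0 + 2 * (0 + 2 * (ci + Cin * co))];
        const double w10 = Wt[1 + 2 * (0 + 2 * (ci + Cin * co))];
        const double w01 = Wt[0 + 2 * (1 + 2 * (ci + Cin * co))];
        const double w11 = Wt[1 + 2 * (1 + 2 * (ci + Cin * co))];
        for (int w = 0; w < W; ++w)
          for (int h = 0; h < H; ++h) {
            const double v = src[h + H * w];
            double* o = dst + (2 * h) + Ho * (2 * w);
            o[0] += w00 * v;        // (2h,   2w)
            o[1] += w10 * v;        // (2h+1, 2w)
            o[Ho] += w01 * v;       // (2h,   2w+1)
            o[Ho + 1] += w11 * v;   // (2h+1, 2w+1)
          }
      }
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return out;
}

// [[Rcpp::export]]
List cpp_convt2_bw(NumericVector x, IntegerVector xdim,
                   NumericVector Wt, NumericVector dout) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector wd = Wt.attr("dim");
  const int Cin = wd[2], Cout = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx(x.size());
  NumericVector dW(Wt.size());
  NumericVector db(Cout);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* do_ = &dout[idx4(0, 0, co, n, Ho, Wo, Cout)];
      double s = 0.0;
      for (int j = 0; j < Ho * Wo; ++j) s += do_[j];
      db[co] += s;
      for (int ci = 0; ci < C; ++ci) {
        const double* src = &x[idx4(0, 0, ci, n, H, W, C)];
        double* dxp = &dx[idx4(0, 0, ci, n, H, W, C)];
        const double w00 = Wt[0 + 2 * (0 + 2 * (ci + Cin * co))];
        const double w10 = Wt[1 + 2 * (0 + 2 * (ci + Cin * co))];
        const double w01 = Wt[0 + 2 * (1 + 2 * (ci + Cin * co))];
        const double w11 = Wt[1 + 2 * (1 + 2 * (ci + Cin * co))];
        double g00 = 0, g10 = 0, g01 = 0, g11 = 0;
        for (int w = 0; w < W; ++w)
          for (int h = 0; h < H; ++h) {
            const double* o = do_ + (2 * h) + Ho * (2 * w);
            const double v = src[h + H * w];
            g00 += o[0] * v; g10 += o[1] * v; g01 += o[Ho] * v; g11 += o[Ho + 1] * v;
            dxp[h + H * w] += w00 * o[0] + w10 * o[1] + w01 * o[Ho] + w11 * o[Ho + 1];
          }
        dW[0 + 2 * (0 + 2 * (ci + Cin * co))] += g00;
        dW[1 + 2 * (0 + 2 * (ci + Cin * co))] += g10;
        dW[0 + 2 * (1 + 2 * (ci + Cin * co))] += g01;
        dW[1 + 2 * (1 + 2 * (ci + Cin * co))] += g11;
      }
    }
  dx.attr("dim") = xdim;
  dW.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  if (H % 2 || W % 2) stop("maxpool: odd spatial size");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  IntegerVector arg(out.size());
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = &x[idx4(0, 0, c, n, H, W, C)];
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          const int base = (2 * h) + H * (2 * w);
          double best = src[base]; int bi = 0;
          if (src[base + 1] > best) { best = src[base + 1]; bi = 1; }
          if (src[base + H] > best) { best = src[base + H]; bi = 2; }
          if (src[base + H + 1] > best) { best = src[base + H + 1]; bi = 3; }
          // out index is (h + Ho*w) within channel, matching loop order below
          out[o + h + static_cast<R_xlen_t>(Ho) * w] = best;
          arg[o + h + static_cast<R_xlen_t>(Ho) * w] = bi;
        }
      o += static_cast<R_xlen_t>(Ho) * Wo;
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  arg.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(NumericVector dout, IntegerVector arg,
                              IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* dst = &dx[idx4(0, 0, c, n, H, W, C)];
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          const int bi = arg[o + h + static_cast<R_xlen_t>(Ho) * w];
          const int base = (2 * h) + H * (2 * w);
          const int off = (bi == 0) ? 0 : (bi == 1) ? 1 : (bi == 2) ? H : H + 1;
          dst[base + off] += dout[o + h + static_cast<R_xlen_t>(Ho) * w];
        }
      o += static_cast<R_xlen_t>(Ho) * Wo;
    }
  dx.attr("dim") = xdim;
  return dx;
}
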