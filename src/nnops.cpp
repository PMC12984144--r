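// Convolutional compute core.
//
// Array conventions (all column-major, matching R):
//   activations: (H, W, C, N)  -- height, width, channels, batch
//   conv kernels: (KH, KW, Cin, Cout)
// Convolution is implemented as im2col + GEMM with the patch matrix laid
// out (Ho*Wo x fan) so patch writes are contiguous; 1x1/stride-1/no-pad
// convolutions skip the patch matrix entirely (the input already is one).

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill Kt (Ho*Wo x kh*kw*C) with zero-padded patches of one sample.
static void im2col_t(const arma::cube& x, int kh, int kw, int stride, int pad,
                     arma::mat& Kt, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kj * kh + c * kh * kw;
        double* dst = Kt.colptr(col);
        for (int j = 0; j < Wo; ++j) {
          double* d = dst + static_cast<size_t>(j) * Ho;
          const int wj = j * stride + kj - pad;
          if (wj < 0 || wj >= W) {
            std::memset(d, 0, sizeof(double) * Ho);
            continue;
          }
          const double* src = &x(0, wj, c);
          if (stride == 1) {
            const int off = ki - pad;                  // wi = i + off
            int i0 = off < 0 ? -off : 0;               // first valid i
            int i1 = H - off < Ho ? H - off : Ho;      // one past last valid
            if (i1 < i0) i1 = i0;
            if (i0 > 0) std::memset(d, 0, sizeof(double) * i0);
            if (i1 > i0) std::memcpy(d + i0, src + i0 + off,
                                     sizeof(double) * (i1 - i0));
            if (Ho > i1) std::memset(d + i1, 0, sizeof(double) * (Ho - i1));
          } else {
            for (int i = 0; i < Ho; ++i) {
              const int wi = i * stride + ki - pad;
              d[i] = (wi < 0 || wi >= H) ? 0.0 : src[wi];
            }
          }
        }
      }
    }
  }
}

// Scatter-add of the patch-gradient matrix (same layout) onto the input.
static void col2im_t(const arma::mat& dKt, int kh, int kw, int stride, int pad,
                     arma::cube& dx, int Ho, int Wo) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kj * kh + c * kh * kw;
        const double* s = dKt.colptr(col);
        for (int j = 0; j < Wo; ++j) {
          const int wj = j * stride + kj - pad;
          if (wj < 0 || wj >= W) continue;
          const double* sj = s + static_cast<size_t>(j) * Ho;
          double* dplane = &dx(0, wj, c);
          if (stride == 1) {
            const int off = ki - pad;
            int i0 = off < 0 ? -off : 0;
            int i1 = H - off < Ho ? H - off : Ho;
            for (int i = i0; i < i1; ++i) dplane[i + off] += sj[i];
          } else {
            for (int i = 0; i < Ho; ++i) {
              const int wi = i * stride + ki - pad;
              if (wi >= 0 && wi < H) dplane[wi] += sj[i];
            }
          }
        }
      }
    }
  }
}

static IntegerVector dim4(SEXP x) {
  IntegerVector d = as<IntegerVector>(Rf_getAttrib(x, R_DimSymbol));
  if (d.size() != 4) stop("expected a 4-d array");
  return d;
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int stride, int pad) {
  IntegerVector xd = dim4(x), wd = dim4(w);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels but kernel expects %d", C, Cin);
  if (b.size() != Cout) stop("conv2d: bias length mismatch");
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: output would be empty");
  const bool pointwise = (kh == 1 && kw == 1 && stride == 1 && pad == 0);

  arma::mat Wm(w.begin(), kh * kw * Cin, Cout, false);
  arma::rowvec bv(b.begin(), Cout);
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  arma::mat Kt;
  if (!pointwise) Kt.set_size(Ho * Wo, kh * kw * C);
  const size_t xstep = static_cast<size_t>(H) * W * C;
  const size_t ystep = static_cast<size_t>(Ho) * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    arma::mat out(y.begin() + n * ystep, Ho * Wo, Cout, false, true);
    if (pointwise) {
      arma::mat Xm(const_cast<double*>(x.begin()) + n * xstep, H * W, C, false);
      out = Xm * Wm;
    } else {
      arma::cube xs(const_cast<double*>(x.begin()) + n * xstep, H, W, C, false);
      im2col_t(xs, kh, kw, stride, pad, Kt, Ho, Wo);
      out = Kt * Wm;
    }
    out.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
               int stride, int pad) {
  IntegerVector xd = dim4(x), wd = dim4(w), yd = dim4(dy);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  if (yd[2] != Cout || yd[3] != N) stop("conv2d_bw: gradient shape mismatch");
  const bool pointwise = (kh == 1 && kw == 1 && stride == 1 && pad == 0);

  arma::mat Wm(w.begin(), kh * kw * C, Cout, false);
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), kh * kw * C, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);

  arma::mat Kt;
  if (!pointwise) Kt.set_size(Ho * Wo, kh * kw * C);
  const size_t xstep = static_cast<size_t>(H) * W * C;
  const size_t ystep = static_cast<size_t>(Ho) * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    arma::mat dYm(const_cast<double*>(dy.begin()) + n * ystep, Ho * Wo, Cout, false);
    dbv += arma::sum(dYm, 0).t();
    if (pointwise) {
      arma::mat Xm(const_cast<double*>(x.begin()) + n * xstep, H * W, C, false);
      arma::mat dXm(dx.begin() + n * xstep, H * W, C, false, true);
      dWm += Xm.t() * dYm;
      dXm += dYm * Wm.t();
    } else {
      arma::cube xs(const_cast<double*>(x.begin()) + n * xstep, H, W, C, false);
      im2col_t(xs, kh, kw, stride, pad, Kt, Ho, Wo);
      dWm += Kt.t() * dYm;
      arma::mat dKt = dYm * Wm.t();  // (Ho*Wo, fan)
      arma::cube dxs(dx.begin() + n * xstep, H, W, C, false, true);
      col2im_t(dKt, kh, kw, stride, pad, dxs, Ho, Wo);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = dim4(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("maxpool: output would be empty");
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  IntegerVector idx(y.size());  // argmax as wi + wj*H within the channel plane
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);

  const size_t xstep = static_cast<size_t>(H) * W * C;
  size_t p = 0;
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + n * xstep;
    for (int c = 0; c < C; ++c) {
      const double* plane = xs + static_cast<size_t>(c) * H * W;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          double best = R_NegInf;
          int besti = -1;
          for (int kj = 0; kj < k; ++kj) {
            const int wj = j * stride + kj - pad;
            if (wj < 0 || wj >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int wi = i * stride + ki - pad;
              if (wi < 0 || wi >= H) continue;
              const double v = plane[wi + wj * H];
              if (v > best) { best = v; besti = wi + wj * H; }
            }
          }
          if (besti < 0) best = 0.0;  // fully padded window
          y[p + static_cast<size_t>(i) + static_cast<size_t>(j) * Ho] = best;
          idx[p + static_cast<size_t>(i) + static_cast<size_t>(j) * Ho] = besti;
        }
      }
      p += static_cast<size_t>(Ho) * Wo;
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bw(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector yd = dim4(dy);
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const size_t planeo = static_cast<size_t>(Ho) * Wo;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = (static_cast<size_t>(n) * C + c) * planeo;
      double* plane = dx.begin() + (static_cast<size_t>(n) * C + c) *
                                       static_cast<size_t>(H) * W;
      for (size_t q = 0; q < planeo; ++q) {
        const int t = idx[off + q];
        if (t >= 0) plane[t] += dy[off + q];
      }
    }
  }
  return dx;
}

// Bilinear resize of a single (H, W, C) image, half-pixel-centre convention.
// [[Rcpp::export]]
NumericVector bilinear_resize(NumericVector x, int oh, int ow) {
  IntegerVector d = as<IntegerVector>(Rf_getAttrib(x, R_DimSymbol));
  if (d.size() != 3) stop("bilinear_resize expects an (H, W, C) array");
  const int H = d[0], W = d[1], C = d[2];
  NumericVector y(static_cast<R_xlen_t>(oh) * ow * C);
  y.attr("dim") = IntegerVector::create(oh, ow, C);
  const double sr = static_cast<double>(H) / oh;
  const double sc = static_cast<double>(W) / ow;
  for (int c = 0; c < C; ++c) {
    const double* plane = x.begin() + static_cast<size_t>(c) * H * W;
    double* out = y.begin() + static_cast<size_t>(c) * oh * ow;
    for (int j = 0; j < ow; ++j) {
      double fc = (j + 0.5) * sc - 0.5;
      if (fc < 0) fc = 0;
      if (fc > W - 1) fc = W - 1;
      const int c0 = static_cast<int>(fc);
      const int c1 = c0 + 1 < W ? c0 + 1 : c0;
      const double tc = fc - c0;
      for (int i = 0; i < oh; ++i) {
        double fr = (i + 0.5) * sr - 0.5;
        if (fr < 0) fr = 0;
        if (fr > H - 1) fr = H - 1;
        const int r0 = static_cast<int>(fr);
        const int r1 = r0 + 1 < H ? r0 + 1 : r0;
        const double tr = fr - r0;
        const double v00 = plane[r0 + c0 * H], v10 = plane[r1 + c0 * H];
        const double v01 = plane[r0 + c1 * H], v11 = plane[r1 + c1 * H];
        out[i + j * oh] = (1 - tr) * ((1 - tc) * v00 + tc * v01) +
                          tr * ((1 - tc) * v10 + tc * v11);
      }
    }
  }
  return y;
}
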