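// Low-level tensor kernels for the cascaded segmentation network.
// Tensor layout everywhere: R array dim (H, W, C, N), column-major, so
// element (h, w, c, n) lives at h + H*(w + W*(c + C*n)).
// Convolution weights: R array dim (K, K, Cin, Cout), viewed here as a
// (K*K*Cin) x Cout matrix; row index r = kh + K*(kw + K*cin).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad, int dil) {
  int eff = dil * (k - 1) + 1;
  return (in + 2 * pad - eff) / stride + 1;
}

// Gather the im2col matrix (K*K*Cin x OH*OW) for one sample.
static void im2col(const double* x, int H, int W, int Cin,
                   int K, int stride, int pad, int dil,
                   int OH, int OW, arma::mat& cols) {
  cols.zeros();
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        int r = kh + K * (kw + K * c);
        for (int ow = 0; ow < OW; ++ow) {
          int iw = ow * stride - pad + kw * dil;
          if (iw < 0 || iw >= W) continue;
          const double* xcol = xc + (size_t)iw * H;
          double* crow = cols.memptr() + r;  // stride K*K*Cin between cols
          size_t ld = cols.n_rows;
          for (int oh = 0; oh < OH; ++oh) {
            int ih = oh * stride - pad + kh * dil;
            if (ih < 0 || ih >= H) continue;
            crow[ld * (oh + (size_t)OH * ow)] = xcol[ih];
          }
        }
      }
    }
  }
}

// Scatter-add of a cols-shaped gradient back into dx for one sample.
static void col2im(const arma::mat& dcols, int H, int W, int Cin,
                   int K, int stride, int pad, int dil,
                   int OH, int OW, double* dx) {
  for (int c = 0; c < Cin; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        int r = kh + K * (kw + K * c);
        const double* crow = dcols.memptr() + r;
        size_t ld = dcols.n_rows;
        for (int ow = 0; ow < OW; ++ow) {
          int iw = ow * stride - pad + kw * dil;
          if (iw < 0 || iw >= W) continue;
          double* xcol = xc + (size_t)iw * H;
          for (int oh = 0; oh < OH; ++oh) {
            int ih = oh * stride - pad + kh * dil;
            if (ih < 0 || ih >= H) continue;
            xcol[ih] += crow[ld * (oh + (size_t)OH * ow)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad, int dilation) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int K = wd[0], Cout = wd[3];
  if (wd[1] != K || wd[2] != Cin) stop("weight dims incompatible with input");
  int OH = out_dim(H, K, stride, pad, dilation);
  int OW = out_dim(W, K, stride, pad, dilation);
  if (OH <= 0 || OW <= 0) stop("convolution output would be empty");

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)K * K * Cin, Cout, false);
  NumericVector out((size_t)OH * OW * Cout * N);
  out.attr("dim") = IntegerVector::create(OH, OW, Cout, N);

  arma::mat cols((size_t)K * K * Cin, (size_t)OH * OW);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin,
           K, stride, pad, dilation, OH, OW, cols);
    arma::mat O(out.begin() + (size_t)n * OH * OW * Cout,
                (size_t)OH * OW, Cout, false, true);
    O = cols.t() * Wm;
    if (bias.isNotNull()) {
      NumericVector b(bias);
      for (int co = 0; co < Cout; ++co) O.col(co) += b[co];
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dout,
                    int stride, int pad, int dilation, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), od = dout.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int K = wd[0], Cout = wd[3];
  int OH = od[0], OW = od[1];

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)K * K * Cin, Cout, false);
  NumericVector dx((size_t)H * W * Cin * N);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)K * K * Cin * Cout);
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), (size_t)K * K * Cin, Cout, false, true);

  arma::mat cols((size_t)K * K * Cin, (size_t)OH * OW);
  for (int n = 0; n < N; ++n) {
    arma::mat D(const_cast<double*>(dout.begin()) + (size_t)n * OH * OW * Cout,
                (size_t)OH * OW, Cout, false);
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin,
           K, stride, pad, dilation, OH, OW, cols);
    dWm += cols * D;
    arma::mat dcols = Wm * D.t();
    col2im(dcols, H, W, Cin, K, stride, pad, dilation, OH, OW,
           dx.begin() + (size_t)n * H * W * Cin);
    if (has_bias)
      for (int co = 0; co < Cout; ++co) db[co] += arma::accu(D.col(co));
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Precompute 1-D bilinear sampling (factor-2, half-pixel centers): for output
// index o, source coordinate is (o + 0.5)/2 - 0.5; edges clamp.
static void lin_idx(int O, int I, std::vector<int>& i0, std::vector<int>& i1,
                    std::vector<double>& w1) {
  i0.resize(O); i1.resize(O); w1.resize(O);
  for (int o = 0; o < O; ++o) {
    double s = (o + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > I - 1) s = I - 1;
    int lo = (int)std::floor(s);
    int hi = lo + 1 < I ? lo + 1 : I - 1;
    i0[o] = lo; i1[o] = hi; w1[o] = s - lo;
  }
}

// [[Rcpp::export(name = ".cpp_upsample2x_fwd")]]
NumericVector cpp_upsample2x_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int OH = 2 * H, OW = 2 * W;
  std::vector<int> h0, h1, w0, w1;
  std::vector<double> hf, wf;
  lin_idx(OH, H, h0, h1, hf);
  lin_idx(OW, W, w0, w1, wf);

  NumericVector out((size_t)OH * OW * C * N);
  out.attr("dim") = IntegerVector::create(OH, OW, C, N);
  for (int q = 0; q < C * N; ++q) {
    const double* xs = x.begin() + (size_t)q * H * W;
    double* os = out.begin() + (size_t)q * OH * OW;
    for (int ow = 0; ow < OW; ++ow) {
      const double* xa = xs + (size_t)w0[ow] * H;
      const double* xb = xs + (size_t)w1[ow] * H;
      double fw = wf[ow];
      double* oc = os + (size_t)ow * OH;
      for (int oh = 0; oh < OH; ++oh) {
        double fh = hf[oh];
        double top = xa[h0[oh]] * (1 - fh) + xa[h1[oh]] * fh;
        double bot = xb[h0[oh]] * (1 - fh) + xb[h1[oh]] * fh;
        oc[oh] = top * (1 - fw) + bot * fw;
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_upsample2x_bwd")]]
NumericVector cpp_upsample2x_bwd(NumericVector dout, int H, int W) {
  IntegerVector od = dout.attr("dim");
  int OH = od[0], OW = od[1], C = od[2], N = od[3];
  std::vector<int> h0, h1, w0, w1;
  std::vector<double> hf, wf;
  lin_idx(OH, H, h0, h1, hf);
  lin_idx(OW, W, w0, w1, wf);

  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int q = 0; q < C * N; ++q) {
    const double* ds = dout.begin() + (size_t)q * OH * OW;
    double* xs = dx.begin() + (size_t)q * H * W;
    for (int ow = 0; ow < OW; ++ow) {
      double fw = wf[ow];
      double* xa = xs + (size_t)w0[ow] * H;
      double* xb = xs + (size_t)w1[ow] * H;
      const double* dc = ds + (size_t)ow * OH;
      for (int oh = 0; oh < OH; ++oh) {
        double g = dc[oh], fh = hf[oh];
        xa[h0[oh]] += g * (1 - fh) * (1 - fw);
        xa[h1[oh]] += g * fh * (1 - fw);
        xb[h0[oh]] += g * (1 - fh) * fw;
        xb[h1[oh]] += g * fh * fw;
      }
    }
  }
  return dx;
}
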