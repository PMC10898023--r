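// Batched 2-D convolution / pooling / batchnorm kernels for the CNN tape
// engine. Tensor layout throughout: column-major R arrays (H, W, C, N).
// Convolution weights: matrix (kh*kw*Cin, Cout) with kernel row index
// k = i + kh*(j + kw*c)  (i = row offset, j = col offset, c = input channel).
//
// Patches are unfolded into a (P, K) matrix (P = Hout*Wout output positions,
// K = kh*kw*Cin): writes along a fixed k are contiguous, and the forward
// pass is a single (P,K) x (K,Cout) gemm per sample.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Convolutions run in single precision internally (standard deep-learning
// practice; halves gemm time and patch-matrix bandwidth). Inputs, outputs
// and parameters stay double on the R side.

static void im2colT(const double* x, int H, int W, int C,
                    int kh, int kw, int stride, int pad,
                    int Hout, int Wout, arma::fmat& colT) {
  const int P = Hout * Wout;
  colT.set_size(P, kh * kw * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        float* dst = colT.colptr(i + kh * (j + kw * c));
        for (int oy = 0; oy < Wout; ++oy) {
          const int iy = oy * stride - pad + j;
          float* drow = dst + (size_t)Hout * oy;
          if (iy < 0 || iy >= W) {
            std::fill(drow, drow + Hout, 0.0f);
            continue;
          }
          const double* src = xc + (size_t)H * iy;
          const int i0 = -pad + i;
          if (stride == 1) {
            for (int ox = 0; ox < Hout; ++ox) {
              const int ix = i0 + ox;
              drow[ox] = (ix >= 0 && ix < H) ? (float)src[ix] : 0.0f;
            }
          } else {
            for (int ox = 0; ox < Hout; ++ox) {
              const int ix = i0 + ox * stride;
              drow[ox] = (ix >= 0 && ix < H) ? (float)src[ix] : 0.0f;
            }
          }
        }
      }
    }
  }
}

static void col2imT(const arma::fmat& colT, int H, int W, int C,
                    int kh, int kw, int stride, int pad,
                    int Hout, int Wout, double* x) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const float* src = colT.colptr(i + kh * (j + kw * c));
        for (int oy = 0; oy < Wout; ++oy) {
          const int iy = oy * stride - pad + j;
          if (iy < 0 || iy >= W) continue;
          double* drow = xc + (size_t)H * iy;
          const float* srow = src + (size_t)Hout * oy;
          const int i0 = -pad + i;
          for (int ox = 0; ox < Hout; ++ox) {
            const int ix = i0 + ox * stride;
            if (ix >= 0 && ix < H) drow[ix] += srow[ox];
          }
        }
      }
    }
  }
}

static arma::fmat to_f(const double* p, int nr, int nc) {
  arma::fmat out(nr, nc);
  float* o = out.memptr();
  const size_t len = (size_t)nr * nc;
  for (size_t t = 0; t < len; ++t) o[t] = (float)p[t];
  return out;
}

static void copy_fd(const arma::fmat& src, double* dst) {
  const float* s = src.memptr();
  const size_t len = src.n_elem;
  for (size_t t = 0; t < len; ++t) dst[t] = (double)s[t];
}

static IntegerVector tdims(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H, W, C, N) tensor");
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericMatrix w, NumericVector bias,
                           int kh, int kw, int stride, int pad) {
  IntegerVector d = tdims(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = w.ncol();
  if (w.nrow() != kh * kw * C) stop("weight rows do not match kh*kw*Cin");
  // floor division: a trailing partial window is dropped (standard stride
  // semantics); the segmentation down/up path always tiles exactly
  const int Hout = (H + 2 * pad - kh) / stride + 1;
  const int Wout = (W + 2 * pad - kw) / stride + 1;
  if (Hout < 1 || Wout < 1) stop("kernel larger than padded input");
  const int P = Hout * Wout;
  NumericVector y((size_t)P * Cout * N);
  y.attr("dim") = IntegerVector::create(Hout, Wout, Cout, N);
  arma::fmat Wf = to_f(w.begin(), w.nrow(), Cout);
  arma::frowvec bf = arma::conv_to<arma::frowvec>::from(
    arma::rowvec(bias.begin(), Cout, false, true));
  const bool one_by_one = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  arma::fmat colT, yn;
  for (int n = 0; n < N; ++n) {
    if (one_by_one) {
      // a 1x1 convolution is a plain (H*W, Cin) x (Cin, Cout) product
      arma::fmat xf = to_f(x.begin() + (size_t)H * W * C * n, P, C);
      yn = xf * Wf;
    } else {
      im2colT(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
              Hout, Wout, colT);
      yn = colT * Wf;
    }
    yn.each_row() += bf;
    copy_fd(yn, y.begin() + (size_t)P * Cout * n);
  }
  return y;
}

// Combined data/filter/bias gradients; unfolds each sample once.
// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector dy, NumericMatrix w,
                  int kh, int kw, int stride, int pad) {
  IntegerVector d = tdims(x), dd = tdims(dy);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Hout = dd[0], Wout = dd[1], Cout = dd[2];
  if (dd[3] != N) stop("batch mismatch");
  const int P = Hout * Wout;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = d;
  arma::fmat Wf = to_f(w.begin(), w.nrow(), Cout);
  arma::fmat dWf(w.nrow(), Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  const bool one_by_one = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  arma::fmat colT, dcolT, dynf;
  for (int n = 0; n < N; ++n) {
    arma::mat dyn(dy.begin() + (size_t)P * Cout * n, P, Cout, false, true);
    dynf = to_f(dyn.memptr(), P, Cout);
    db += arma::sum(dyn, 0);
    if (one_by_one) {
      arma::fmat xf = to_f(x.begin() + (size_t)H * W * C * n, P, C);
      dWf += xf.t() * dynf;
      dcolT = dynf * Wf.t();          // (P, Cin) == the dx layout directly
      double* dxn = dx.begin() + (size_t)H * W * C * n;
      const float* sp = dcolT.memptr();
      for (size_t t = 0; t < (size_t)P * C; ++t) dxn[t] = (double)sp[t];
    } else {
      im2colT(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
              Hout, Wout, colT);
      dWf += colT.t() * dynf;
      dcolT = dynf * Wf.t();
      col2imT(dcolT, H, W, C, kh, kw, stride, pad, Hout, Wout,
              dx.begin() + (size_t)H * W * C * n);
    }
  }
  arma::mat dW = arma::conv_to<arma::mat>::from(dWf);
  return List::create(_["dx"] = dx, _["dw"] = wrap(dW), _["db"] = wrap(db));
}

// Adjoint of cpp_conv_fwd in the data argument; also the forward pass of a
// transposed convolution whose weight is stored in conv orientation.
// [[Rcpp::export]]
NumericVector cpp_conv_bwd_data(NumericVector dy, NumericMatrix w,
                                int kh, int kw, int stride, int pad,
                                int H, int W) {
  IntegerVector dd = tdims(dy);
  const int Hout = dd[0], Wout = dd[1], Cout = dd[2], N = dd[3];
  const int C = w.nrow() / (kh * kw);
  if (w.nrow() != kh * kw * C || w.ncol() != Cout) stop("weight shape mismatch");
  const int P = Hout * Wout;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::fmat Wf = to_f(w.begin(), w.nrow(), Cout);
  arma::fmat dcolT, dynf;
  for (int n = 0; n < N; ++n) {
    dynf = to_f(dy.begin() + (size_t)P * Cout * n, P, Cout);
    dcolT = dynf * Wf.t();
    col2imT(dcolT, H, W, C, kh, kw, stride, pad, Hout, Wout,
            dx.begin() + (size_t)H * W * C * n);
  }
  return dx;
}

// Filter gradient alone (used by the transposed-convolution backward pass).
// [[Rcpp::export]]
NumericMatrix cpp_conv_bwd_filter(NumericVector x, NumericVector dy,
                                  int kh, int kw, int stride, int pad) {
  IntegerVector d = tdims(x), dd = tdims(dy);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Hout = dd[0], Wout = dd[1], Cout = dd[2];
  arma::fmat dWf(kh * kw * C, Cout, arma::fill::zeros);
  arma::fmat colT, dynf;
  const int P = Hout * Wout;
  for (int n = 0; n < N; ++n) {
    dynf = to_f(dy.begin() + (size_t)P * Cout * n, P, Cout);
    im2colT(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
            Hout, Wout, colT);
    dWf += colT.t() * dynf;
  }
  return wrap(arma::conv_to<arma::mat>::from(dWf));
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector d = tdims(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  if (Hout < 1 || Wout < 1) stop("pool kernel larger than padded input");
  NumericVector y((size_t)Hout * Wout * C * N);
  y.attr("dim") = IntegerVector::create(Hout, Wout, C, N);
  IntegerVector idx(y.size());  // 0-based linear index into x per output cell
  double* yp = y.begin();
  int* ip = idx.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    const size_t base_n = (size_t)H * W * C * n;
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + base_n + (size_t)H * W * c;
      for (int oy = 0; oy < Wout; ++oy) {
        for (int ox = 0; ox < Hout; ++ox) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int j = 0; j < k; ++j) {
            const int iy = oy * stride - pad + j;
            if (iy < 0 || iy >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int ix = ox * stride - pad + i;
              if (ix < 0 || ix >= H) continue;
              const double v = xc[ix + (size_t)H * iy];
              if (v > best) { best = v; besti = ix + H * iy; }
            }
          }
          yp[o] = best;
          ip[o] = (int)(base_n + (size_t)H * W * c + besti);
          ++o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx,
                              IntegerVector xdim) {
  size_t len = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(len);
  dx.attr("dim") = xdim;
  const double* gp = dy.begin();
  double* dp = dx.begin();
  for (R_xlen_t t = 0; t < dy.size(); ++t) dp[idx[t]] += gp[t];
  return dx;
}

// per-channel sums and sums of squares over (H, W, N)
// [[Rcpp::export]]
NumericMatrix cpp_chan_stats(NumericVector x) {
  IntegerVector d = tdims(x);
  const size_t hw = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericMatrix out(C, 2);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* b = xp + hw * (c + (size_t)C * n);
      double s = 0, q = 0;
      for (size_t t = 0; t < hw; ++t) { s += b[t]; q += b[t] * b[t]; }
      out(c, 0) += s;
      out(c, 1) += q;
    }
  }
  return out;
}

// y = x * scale[c] + shift[c]
// [[Rcpp::export]]
NumericVector cpp_chan_affine(NumericVector x, NumericVector scale,
                              NumericVector shift) {
  IntegerVector d = tdims(x);
  const size_t hw = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector y(x.size());
  y.attr("dim") = d;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = hw * (c + (size_t)C * n);
      const double sc = scale[c], sh = shift[c];
      for (size_t t = 0; t < hw; ++t) yp[off + t] = xp[off + t] * sc + sh;
    }
  }
  return y;
}

// batchnorm backward: dx, dgamma, dbeta from upstream grad and saved stats
// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector g, NumericVector x, NumericVector mu,
                NumericVector istd, NumericVector gamma, bool training) {
  IntegerVector d = tdims(x);
  const size_t hw = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  const double m = (double)hw * N;
  NumericVector s1(C), s2(C);
  const double* gp = g.begin();
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = hw * (c + (size_t)C * n);
      const double mc = mu[c], ic = istd[c];
      double a = 0, b = 0;
      for (size_t t = 0; t < hw; ++t) {
        const double gv = gp[off + t];
        a += gv;
        b += gv * (xp[off + t] - mc) * ic;
      }
      s1[c] += a;
      s2[c] += b;
    }
  }
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  double* dp = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = hw * (c + (size_t)C * n);
      const double gi = gamma[c] * istd[c];
      if (training) {
        const double mc = mu[c], ic = istd[c];
        const double t1 = s1[c] / m, t2 = s2[c] / m;
        for (size_t t = 0; t < hw; ++t) {
          const double xh = (xp[off + t] - mc) * ic;
          dp[off + t] = gi * (gp[off + t] - t1 - xh * t2);
        }
      } else {
        for (size_t t = 0; t < hw; ++t) dp[off + t] = gi * gp[off + t];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = s2, _["dbeta"] = s1);
}

// channel concatenation and its adjoint
// [[Rcpp::export]]
NumericVector cpp_concat(NumericVector a, NumericVector b) {
  IntegerVector da = tdims(a), db = tdims(b);
  if (da[0] != db[0] || da[1] != db[1] || da[3] != db[3])
    stop("concat: spatial/batch dims differ");
  const size_t hw = (size_t)da[0] * da[1];
  const int ca = da[2], cb = db[2], N = da[3];
  NumericVector y(hw * (ca + cb) * N);
  y.attr("dim") = IntegerVector::create(da[0], da[1], ca + cb, N);
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    std::copy(a.begin() + hw * ca * (size_t)n, a.begin() + hw * ca * (size_t)(n + 1),
              yp + hw * (ca + cb) * (size_t)n);
    std::copy(b.begin() + hw * cb * (size_t)n, b.begin() + hw * cb * (size_t)(n + 1),
              yp + hw * (ca + cb) * (size_t)n + hw * ca);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_split_channels(NumericVector g, int ca) {
  IntegerVector d = tdims(g);
  const size_t hw = (size_t)d[0] * d[1];
  const int ct = d[2], N = d[3];
  const int cb = ct - ca;
  NumericVector ga(hw * ca * N), gb(hw * cb * N);
  ga.attr("dim") = IntegerVector::create(d[0], d[1], ca, N);
  gb.attr("dim") = IntegerVector::create(d[0], d[1], cb, N);
  for (int n = 0; n < N; ++n) {
    const double* src = g.begin() + hw * ct * (size_t)n;
    std::copy(src, src + hw * ca, ga.begin() + hw * ca * (size_t)n);
    std::copy(src + hw * ca, src + hw * ct, gb.begin() + hw * cb * (size_t)n);
  }
  return List::create(_["a"] = ga, _["b"] = gb);
}
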