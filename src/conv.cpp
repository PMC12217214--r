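// Minimal 2-D convolution engine (im2col + BLAS GEMM) used by the
// U-Net generator and the convolutional discriminator, plus the small
// elementwise/resampling kernels of the network (leaky ReLU, 2x2 average
// pooling, nearest upsampling, channel concatenation).
//
// Layout conventions (all column-major, as R stores arrays):
//   x  : H x W x Cin x N      input batch
//   w  : (kh*kw*Cin) x Cout   filter bank, column-major patch unrolling
//        (patch index runs ki fastest, then kj, then ci)
//   y  : Ho x Wo x Cout x N   output batch
// Zero padding `pad` on all sides, square stride `stride`.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int k, int pad, int stride) {
  return (n + 2 * pad - k) / stride + 1;
}

// Valid output range [o0, o1) for which o*stride - pad + k lies in [0, n).
static inline void valid_range(int n, int no, int k, int pad, int stride,
                               int& o0, int& o1) {
  int lo = pad - k;
  o0 = lo <= 0 ? 0 : (lo + stride - 1) / stride;
  int hi = n - 1 + pad - k;
  o1 = hi < 0 ? 0 : std::min(no, hi / stride + 1);
  if (o1 < o0) o1 = o0;
}

// Unroll one sample into rows [row0, row0 + Ho*Wo) of `cols`.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int pad, int stride,
                   int Ho, int Wo, arma::mat& cols, int row0) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      int jo0, jo1;
      valid_range(W, Wo, kj, pad, stride, jo0, jo1);
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * c);
        double* dst = cols.colptr(col) + row0;
        int io0, io1;
        valid_range(H, Ho, ki, pad, stride, io0, io1);
        for (int jo = 0; jo < Wo; ++jo) {
          double* d = dst + (size_t)jo * Ho;
          if (jo < jo0 || jo >= jo1) { std::fill(d, d + Ho, 0.0); continue; }
          const double* src = xc + (size_t)(jo * stride - pad + kj) * H - pad + ki;
          if (io0 > 0) std::fill(d, d + io0, 0.0);
          if (stride == 1) {
            std::copy(src + io0, src + io1, d + io0);
          } else {
            for (int io = io0; io < io1; ++io) d[io] = src[io * stride];
          }
          if (io1 < Ho) std::fill(d + io1, d + Ho, 0.0);
        }
      }
    }
  }
}

// Scatter-add rows [row0, row0 + Ho*Wo) of `cols` back onto one sample grid.
static void col2im(const arma::mat& cols, int H, int W, int C,
                   int kh, int kw, int pad, int stride,
                   int Ho, int Wo, double* dx, int row0) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      int jo0, jo1;
      valid_range(W, Wo, kj, pad, stride, jo0, jo1);
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * c);
        const double* src = cols.colptr(col) + row0;
        int io0, io1;
        valid_range(H, Ho, ki, pad, stride, io0, io1);
        for (int jo = jo0; jo < jo1; ++jo) {
          const double* s = src + (size_t)jo * Ho;
          double* d = xc + (size_t)(jo * stride - pad + kj) * H - pad + ki;
          if (stride == 1) {
            for (int io = io0; io < io1; ++io) d[io] += s[io];
          } else {
            for (int io = io0; io < io1; ++io) d[io * stride] += s[io];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericMatrix w, NumericVector bias,
                         int kh, int kw, int pad, int stride) {
  IntegerVector dims = x.attr("dim");
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Cout = w.ncol();
  if (w.nrow() != kh * kw * C)
    stop("filter bank rows (%d) do not match kh*kw*Cin (%d)", w.nrow(), kh * kw * C);
  const int Ho = out_size(H, kh, pad, stride);
  const int Wo = out_size(W, kw, pad, stride);
  if (Ho < 1 || Wo < 1) stop("convolution output would be empty");

  arma::mat wm(w.begin(), w.nrow(), Cout, false);
  arma::rowvec b(bias.begin(), Cout);
  NumericVector y(R_xlen_t(Ho) * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  const int hw = Ho * Wo;
  arma::mat cols(hw, kh * kw * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, pad, stride,
           Ho, Wo, cols, 0);
    arma::mat out = cols * wm;
    out.each_row() += b;
    std::copy(out.begin(), out.end(), y.begin() + (size_t)n * hw * Cout);
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericMatrix w, NumericVector dy,
                int kh, int kw, int pad, int stride, bool need_dx) {
  IntegerVector dims = x.attr("dim");
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Cout = w.ncol();
  const int Ho = out_size(H, kh, pad, stride);
  const int Wo = out_size(W, kw, pad, stride);
  const int hw = Ho * Wo;

  arma::mat wm(w.begin(), w.nrow(), Cout, false);
  arma::mat cols(hw, kh * kw * C);
  arma::mat dw(w.nrow(), Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  NumericVector dx(need_dx ? x.size() : R_xlen_t(0));
  if (need_dx) dx.attr("dim") = dims;
  for (int n = 0; n < N; ++n) {
    arma::mat dyn(dy.begin() + (size_t)n * hw * Cout, hw, Cout, false);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, pad, stride,
           Ho, Wo, cols, 0);
    dw += cols.t() * dyn;
    db += arma::sum(dyn, 0);
    if (need_dx) {
      arma::mat dcols = dyn * wm.t();
      col2im(dcols, H, W, C, kh, kw, pad, stride, Ho, Wo,
             dx.begin() + (size_t)n * H * W * C, 0);
    }
  }
  NumericMatrix dwr(w.nrow(), Cout);
  std::copy(dw.begin(), dw.end(), dwr.begin());
  NumericVector dbr(Cout);
  std::copy(db.begin(), db.end(), dbr.begin());
  return List::create(_["dx"] = dx, _["dw"] = dwr, _["db"] = dbr);
}

// [[Rcpp::export(name = ".lrelu_fwd")]]
NumericVector lrelu_fwd(NumericVector x, double slope) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xi = x.begin(); double* yi = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i)
    yi[i] = xi[i] > 0 ? xi[i] : slope * xi[i];
  return y;
}

// [[Rcpp::export(name = ".lrelu_bwd")]]
NumericVector lrelu_bwd_cpp(NumericVector dy, NumericVector pre, double slope) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double* d = dy.begin(); const double* p = pre.begin();
  double* o = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    o[i] = p[i] > 0 ? d[i] : slope * d[i];
  return dx;
}

// [[Rcpp::export(name = ".pool2_cpp")]]
NumericVector pool2_cpp(NumericVector x) {
  IntegerVector dims = x.attr("dim");
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(R_xlen_t(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int s = 0; s < C * N; ++s) {
    const double* xs = x.begin() + (size_t)s * H * W;
    double* ys = y.begin() + (size_t)s * Ho * Wo;
    for (int jo = 0; jo < Wo; ++jo) {
      const double* c0 = xs + (size_t)(2 * jo) * H;
      const double* c1 = c0 + H;
      double* d = ys + (size_t)jo * Ho;
      for (int io = 0; io < Ho; ++io)
        d[io] = 0.25 * (c0[2 * io] + c0[2 * io + 1] + c1[2 * io] + c1[2 * io + 1]);
    }
  }
  return y;
}

// [[Rcpp::export(name = ".pool2_bwd_cpp")]]
NumericVector pool2_bwd_cpp(NumericVector dy) {
  IntegerVector dims = dy.attr("dim");
  const int Ho = dims[0], Wo = dims[1], C = dims[2], N = dims[3];
  const int H = 2 * Ho, W = 2 * Wo;
  NumericVector dx(R_xlen_t(H) * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int s = 0; s < C * N; ++s) {
    const double* ds = dy.begin() + (size_t)s * Ho * Wo;
    double* xs = dx.begin() + (size_t)s * H * W;
    for (int jo = 0; jo < Wo; ++jo) {
      const double* d = ds + (size_t)jo * Ho;
      double* c0 = xs + (size_t)(2 * jo) * H;
      double* c1 = c0 + H;
      for (int io = 0; io < Ho; ++io) {
        const double v = 0.25 * d[io];
        c0[2 * io] = v; c0[2 * io + 1] = v; c1[2 * io] = v; c1[2 * io + 1] = v;
      }
    }
  }
  return dx;
}

// [[Rcpp::export(name = ".up2_cpp")]]
NumericVector up2_cpp(NumericVector x) {
  IntegerVector dims = x.attr("dim");
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(R_xlen_t(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int s = 0; s < C * N; ++s) {
    const double* xs = x.begin() + (size_t)s * H * W;
    double* ys = y.begin() + (size_t)s * Ho * Wo;
    for (int j = 0; j < W; ++j) {
      const double* c = xs + (size_t)j * H;
      double* d0 = ys + (size_t)(2 * j) * Ho;
      double* d1 = d0 + Ho;
      for (int i = 0; i < H; ++i) {
        d0[2 * i] = c[i]; d0[2 * i + 1] = c[i];
        d1[2 * i] = c[i]; d1[2 * i + 1] = c[i];
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".up2_bwd_cpp")]]
NumericVector up2_bwd_cpp(NumericVector dy) {
  IntegerVector dims = dy.attr("dim");
  const int Ho = dims[0], Wo = dims[1], C = dims[2], N = dims[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx(R_xlen_t(H) * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int s = 0; s < C * N; ++s) {
    const double* ds = dy.begin() + (size_t)s * Ho * Wo;
    double* xs = dx.begin() + (size_t)s * H * W;
    for (int j = 0; j < W; ++j) {
      const double* d0 = ds + (size_t)(2 * j) * Ho;
      const double* d1 = d0 + Ho;
      double* c = xs + (size_t)j * H;
      for (int i = 0; i < H; ++i)
        c[i] = d0[2 * i] + d0[2 * i + 1] + d1[2 * i] + d1[2 * i + 1];
    }
  }
  return dx;
}

// [[Rcpp::export(name = ".cat_ch_cpp")]]
NumericVector cat_ch_cpp(NumericVector a, NumericVector b) {
  IntegerVector da = a.attr("dim"), db = b.attr("dim");
  const int H = da[0], W = da[1], Ca = da[2], N = da[3], Cb = db[2];
  NumericVector y(R_xlen_t(H) * W * (Ca + Cb) * N);
  y.attr("dim") = IntegerVector::create(H, W, Ca + Cb, N);
  const size_t hw = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    std::copy(a.begin() + n * hw * Ca, a.begin() + (n + 1) * hw * Ca,
              y.begin() + n * hw * (Ca + Cb));
    std::copy(b.begin() + n * hw * Cb, b.begin() + (n + 1) * hw * Cb,
              y.begin() + n * hw * (Ca + Cb) + hw * Ca);
  }
  return y;
}

// [[Rcpp::export(name = ".split_ch_cpp")]]
List split_ch_cpp(NumericVector x, int ca) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int cb = C - ca;
  NumericVector a(R_xlen_t(H) * W * ca * N), b(R_xlen_t(H) * W * cb * N);
  a.attr("dim") = IntegerVector::create(H, W, ca, N);
  b.attr("dim") = IntegerVector::create(H, W, cb, N);
  const size_t hw = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    std::copy(x.begin() + n * hw * C, x.begin() + n * hw * C + hw * ca,
              a.begin() + n * hw * ca);
    std::copy(x.begin() + n * hw * C + hw * ca, x.begin() + (n + 1) * hw * C,
              b.begin() + n * hw * cb);
  }
  return List::create(_["a"] = a, _["b"] = b);
}

// Bilinear pull-back warp of an H x W x C image: out(i,j) = img(i+u(i,j), j+v(i,j)).
// Samples outside the canvas take `fill` (per channel).
// [[Rcpp::export(name = ".warp_field_cpp")]]
NumericVector warp_field_cpp(NumericVector img, NumericMatrix u, NumericMatrix v,
                             NumericVector fill) {
  IntegerVector dims = img.attr("dim");
  const int H = dims[0], W = dims[1], C = dims.size() > 2 ? dims[2] : 1;
  NumericVector out(img.size());
  out.attr("dim") = img.attr("dim");
  for (int c = 0; c < C; ++c) {
    const double* x = img.begin() + (size_t)c * H * W;
    double* y = out.begin() + (size_t)c * H * W;
    const double f = fill[c % fill.size()];
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const double si = i + u(i, j), sj = j + v(i, j);
        if (si < 0 || sj < 0 || si > H - 1 || sj > W - 1) {
          y[i + (size_t)j * H] = f;
          continue;
        }
        const int i0 = (int)std::floor(si), j0 = (int)std::floor(sj);
        const int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
        const double a = si - i0, b = sj - j0;
        y[i + (size_t)j * H] =
            (1 - a) * (1 - b) * x[i0 + (size_t)j0 * H] +
            a * (1 - b) * x[i1 + (size_t)j0 * H] +
            (1 - a) * b * x[i0 + (size_t)j1 * H] +
            a * b * x[i1 + (size_t)j1 * H];
      }
    }
  }
  return out;
}
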