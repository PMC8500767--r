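// Hot numerical kernels for the encoder-decoder density network.
// Layout convention: image batches are R arrays of dim (h, w, channels, n),
// column-major as R stores them.  3x3 convolutions use same-padding via
// im2col + GEMM; weight matrices have 9*cin rows ordered with the spatial
// offset fastest (di, then dj), then input channel, and cout columns.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col3(const double* x, int h, int w, int cin, int n, arma::mat& X) {
  const int hw = h * w;
  X.zeros(static_cast<arma::uword>(hw) * n, 9 * cin);
  for (int s = 0; s < n; ++s) {
    for (int c = 0; c < cin; ++c) {
      const double* xc = x + (static_cast<size_t>(s) * cin + c) * hw;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          const int k = (di + 1) + 3 * (dj + 1);
          double* col = X.colptr(k + 9 * c);
          const int i0 = std::max(0, -di), i1 = std::min(h, h - di);
          const int j0 = std::max(0, -dj), j1 = std::min(w, w - dj);
          for (int j = j0; j < j1; ++j) {
            const double* src = xc + (j + dj) * h + (i0 + di);
            double* dst = col + static_cast<size_t>(s) * hw + j * h + i0;
            std::copy(src, src + (i1 - i0), dst);
          }
        }
      }
    }
  }
}

static void col2im3(const arma::mat& dX, int h, int w, int cin, int n, double* dx) {
  const int hw = h * w;
  std::fill(dx, dx + static_cast<size_t>(hw) * cin * n, 0.0);
  for (int s = 0; s < n; ++s) {
    for (int c = 0; c < cin; ++c) {
      double* xc = dx + (static_cast<size_t>(s) * cin + c) * hw;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          const int k = (di + 1) + 3 * (dj + 1);
          const double* col = dX.colptr(k + 9 * c);
          const int i0 = std::max(0, -di), i1 = std::min(h, h - di);
          const int j0 = std::max(0, -dj), j1 = std::min(w, w - dj);
          for (int j = j0; j < j1; ++j) {
            double* dst = xc + (j + dj) * h + (i0 + di);
            const double* src = col + static_cast<size_t>(s) * hw + j * h + i0;
            for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3x3_fwd_cpp(NumericVector x, NumericMatrix W, NumericVector b,
                              bool relu) {
  IntegerVector d = x.attr("dim");
  const int h = d[0], w = d[1], cin = d[2], n = d[3];
  const int cout = W.ncol();
  const int hw = h * w;
  arma::mat X;
  im2col3(x.begin(), h, w, cin, n, X);
  arma::mat Wm(W.begin(), W.nrow(), cout, false);
  arma::mat Y = X * Wm;
  NumericVector out(static_cast<R_xlen_t>(hw) * cout * n);
  out.attr("dim") = IntegerVector::create(h, w, cout, n);
  double* o = out.begin();
  for (int s = 0; s < n; ++s) {
    for (int co = 0; co < cout; ++co) {
      const double* yc = Y.colptr(co) + static_cast<size_t>(s) * hw;
      double* dst = o + (static_cast<size_t>(s) * cout + co) * hw;
      const double bb = b[co];
      if (relu) {
        for (int p = 0; p < hw; ++p) { double v = yc[p] + bb; dst[p] = v > 0 ? v : 0; }
      } else {
        for (int p = 0; p < hw; ++p) dst[p] = yc[p] + bb;
      }
    }
  }
  return out;
}

// Backward pass; y (post-activation) is needed only when relu = TRUE.
// [[Rcpp::export]]
List conv3x3_bwd_cpp(NumericVector x, NumericMatrix W, NumericVector dy,
                     NumericVector y, bool relu, bool need_dx) {
  IntegerVector d = x.attr("dim");
  const int h = d[0], w = d[1], cin = d[2], n = d[3];
  const int cout = W.ncol();
  const int hw = h * w;

  // gradient through ReLU, reshaped to (hw*n) x cout
  arma::mat dY(static_cast<arma::uword>(hw) * n, cout);
  const double* dyp = dy.begin();
  const double* yp = y.begin();
  for (int s = 0; s < n; ++s) {
    for (int co = 0; co < cout; ++co) {
      const double* src = dyp + (static_cast<size_t>(s) * cout + co) * hw;
      double* dst = dY.colptr(co) + static_cast<size_t>(s) * hw;
      if (relu) {
        const double* ys = yp + (static_cast<size_t>(s) * cout + co) * hw;
        for (int p = 0; p < hw; ++p) dst[p] = ys[p] > 0 ? src[p] : 0.0;
      } else {
        std::copy(src, src + hw, dst);
      }
    }
  }

  arma::mat X;
  im2col3(x.begin(), h, w, cin, n, X);
  arma::mat dW = X.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);

  List out = List::create(Named("dW") = wrap(dW),
                          Named("db") = wrap(arma::vec(db.t())));
  if (need_dx) {
    arma::mat Wm(W.begin(), W.nrow(), cout, false);
    arma::mat dXc = dY * Wm.t();
    NumericVector dx(static_cast<R_xlen_t>(hw) * cin * n);
    dx.attr("dim") = IntegerVector::create(h, w, cin, n);
    col2im3(dXc, h, w, cin, n, dx.begin());
    out["dx"] = dx;
  }
  return out;
}

// 2x2 max pooling, stride 2; dims must be even.  Returns pooled map and the
// winning offset (0..3, column-major within the 2x2 window) for routing.
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int h = d[0], w = d[1], c = d[2], n = d[3];
  const int ho = h / 2, wo = w / 2;
  NumericVector y(static_cast<R_xlen_t>(ho) * wo * c * n);
  IntegerVector arg(y.size());
  y.attr("dim") = IntegerVector::create(ho, wo, c, n);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = arg.begin();
  const size_t hw = static_cast<size_t>(h) * w;
  const size_t hwo = static_cast<size_t>(ho) * wo;
  for (int sc = 0; sc < c * n; ++sc) {
    const double* xc = xp + sc * hw;
    double* yc = yp + sc * hwo;
    int* ac = ap + sc * hwo;
    for (int j = 0; j < wo; ++j) {
      for (int i = 0; i < ho; ++i) {
        const int i2 = 2 * i, j2 = 2 * j;
        double best = xc[i2 + j2 * h]; int bk = 0;
        double v = xc[i2 + 1 + j2 * h]; if (v > best) { best = v; bk = 1; }
        v = xc[i2 + (j2 + 1) * h]; if (v > best) { best = v; bk = 2; }
        v = xc[i2 + 1 + (j2 + 1) * h]; if (v > best) { best = v; bk = 3; }
        yc[i + j * ho] = best;
        ac[i + j * ho] = bk;
      }
    }
  }
  return List::create(Named("y") = y, Named("arg") = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dy, IntegerVector arg, int h, int w) {
  IntegerVector d = dy.attr("dim");
  const int ho = d[0], wo = d[1], c = d[2], n = d[3];
  NumericVector dx(static_cast<R_xlen_t>(h) * w * c * n);
  dx.attr("dim") = IntegerVector::create(h, w, c, n);
  const double* dyp = dy.begin();
  const int* ap = arg.begin();
  double* dxp = dx.begin();
  const size_t hw = static_cast<size_t>(h) * w;
  const size_t hwo = static_cast<size_t>(ho) * wo;
  for (int sc = 0; sc < c * n; ++sc) {
    const double* dyc = dyp + sc * hwo;
    const int* ac = ap + sc * hwo;
    double* dxc = dxp + sc * hw;
    for (int j = 0; j < wo; ++j) {
      for (int i = 0; i < ho; ++i) {
        const int k = ac[i + j * ho];
        const int ii = 2 * i + (k & 1), jj = 2 * j + (k >> 1);
        dxc[ii + jj * h] += dyc[i + j * ho];
      }
    }
  }
  return dx;
}

// Nearest-neighbour 2x upsampling and its adjoint (2x2 block sum).
// [[Rcpp::export]]
NumericVector upsample2_fwd_cpp(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int h = d[0], w = d[1], c = d[2], n = d[3];
  const int ho = 2 * h, wo = 2 * w;
  NumericVector y(static_cast<R_xlen_t>(ho) * wo * c * n);
  y.attr("dim") = IntegerVector::create(ho, wo, c, n);
  const double* xp = x.begin();
  double* yp = y.begin();
  const size_t hw = static_cast<size_t>(h) * w;
  const size_t hwo = static_cast<size_t>(ho) * wo;
  for (int sc = 0; sc < c * n; ++sc) {
    const double* xc = xp + sc * hw;
    double* yc = yp + sc * hwo;
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        const double v = xc[i + j * h];
        const int i2 = 2 * i, j2 = 2 * j;
        yc[i2 + j2 * ho] = v;
        yc[i2 + 1 + j2 * ho] = v;
        yc[i2 + (j2 + 1) * ho] = v;
        yc[i2 + 1 + (j2 + 1) * ho] = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd_cpp(NumericVector dy) {
  IntegerVector d = dy.attr("dim");
  const int ho = d[0], wo = d[1], c = d[2], n = d[3];
  const int h = ho / 2, w = wo / 2;
  NumericVector dx(static_cast<R_xlen_t>(h) * w * c * n);
  dx.attr("dim") = IntegerVector::create(h, w, c, n);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  const size_t hw = static_cast<size_t>(h) * w;
  const size_t hwo = static_cast<size_t>(ho) * wo;
  for (int sc = 0; sc < c * n; ++sc) {
    const double* dyc = dyp + sc * hwo;
    double* dxc = dxp + sc * hw;
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        const int i2 = 2 * i, j2 = 2 * j;
        dxc[i + j * h] = dyc[i2 + j2 * ho] + dyc[i2 + 1 + j2 * ho] +
                         dyc[i2 + (j2 + 1) * ho] + dyc[i2 + 1 + (j2 + 1) * ho];
      }
    }
  }
  return dx;
}

// Max-unpooling: place each value at the position its (encoder) pooling
// switch recorded inside the 2x2 window; other positions stay zero.
// [[Rcpp::export]]
NumericVector unpool2_fwd_cpp(NumericVector x, IntegerVector arg, int h, int w) {
  IntegerVector d = x.attr("dim");
  const int ho = d[0], wo = d[1], c = d[2], n = d[3];
  NumericVector y(static_cast<R_xlen_t>(h) * w * c * n);
  y.attr("dim") = IntegerVector::create(h, w, c, n);
  const double* xp = x.begin();
  const int* ap = arg.begin();
  double* yp = y.begin();
  const size_t hw = static_cast<size_t>(h) * w;
  const size_t hwo = static_cast<size_t>(ho) * wo;
  for (int sc = 0; sc < c * n; ++sc) {
    const double* xc = xp + sc * hwo;
    const int* ac = ap + sc * hwo;
    double* yc = yp + sc * hw;
    for (int j = 0; j < wo; ++j) {
      for (int i = 0; i < ho; ++i) {
        const int k = ac[i + j * ho];
        const int ii = 2 * i + (k & 1), jj = 2 * j + (k >> 1);
        yc[ii + jj * h] = xc[i + j * ho];
      }
    }
  }
  return y;
}

// Adjoint of unpooling: gather the gradient from each switch position.
// [[Rcpp::export]]
NumericVector unpool2_bwd_cpp(NumericVector dy, IntegerVector arg) {
  IntegerVector d = dy.attr("dim");
  const int h = d[0], w = d[1], c = d[2], n = d[3];
  const int ho = h / 2, wo = w / 2;
  NumericVector dx(static_cast<R_xlen_t>(ho) * wo * c * n);
  dx.attr("dim") = IntegerVector::create(ho, wo, c, n);
  const double* dyp = dy.begin();
  const int* ap = arg.begin();
  double* dxp = dx.begin();
  const size_t hw = static_cast<size_t>(h) * w;
  const size_t hwo = static_cast<size_t>(ho) * wo;
  for (int sc = 0; sc < c * n; ++sc) {
    const double* dyc = dyp + sc * hw;
    const int* ac = ap + sc * hwo;
    double* dxc = dxp + sc * hwo;
    for (int j = 0; j < wo; ++j) {
      for (int i = 0; i < ho; ++i) {
        const int k = ac[i + j * ho];
        const int ii = 2 * i + (k & 1), jj = 2 * j + (k >> 1);
        dxc[i + j * ho] = dyc[ii + jj * h];
      }
    }
  }
  return dx;
}
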