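// Low-level tensor primitives for the CNN graph engine: im2col/col2im
// convolution lowering and max-pooling with argmax bookkeeping.
// Layout conventions (match R's column-major array(dim = c(H, W, C))):
//   activations: arma::cube H x W x C
//   im2col rows: di + kh*(dj + kw*c)   (di fastest, then dj, then channel)
//   im2col cols: oi + oH*oj            (output row fastest)

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(name = ".im2col_cpp")]]
arma::mat im2col_cpp(const arma::cube& x, int kh, int kw, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int oH = out_dim(H, kh, stride, pad), oW = out_dim(W, kw, stride, pad);
  arma::mat cols(kh * kw * C, oH * oW, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int row = di + kh * (dj + kw * c);
        for (int oj = 0; oj < oW; ++oj) {
          const int j = oj * stride - pad + dj;
          if (j < 0 || j >= W) continue;
          for (int oi = 0; oi < oH; ++oi) {
            const int i = oi * stride - pad + di;
            if (i < 0 || i >= H) continue;
            cols(row, oi + oH * oj) = x(i, j, c);
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".col2im_cpp")]]
arma::cube col2im_cpp(const arma::mat& cols, int H, int W, int C,
                      int kh, int kw, int stride, int pad) {
  const int oH = out_dim(H, kh, stride, pad), oW = out_dim(W, kw, stride, pad);
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int row = di + kh * (dj + kw * c);
        for (int oj = 0; oj < oW; ++oj) {
          const int j = oj * stride - pad + dj;
          if (j < 0 || j >= W) continue;
          for (int oi = 0; oi < oH; ++oi) {
            const int i = oi * stride - pad + di;
            if (i < 0 || i >= H) continue;
            x(i, j, c) += cols(row, oi + oH * oj);
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export(name = ".maxpool_fwd_cpp")]]
List maxpool_fwd_cpp(const arma::cube& x, int kh, int kw, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int oH = out_dim(H, kh, stride, pad), oW = out_dim(W, kw, stride, pad);
  arma::cube out(oH, oW, C);
  arma::icube arg(oH, oW, C);
  for (int c = 0; c < C; ++c) {
    for (int oj = 0; oj < oW; ++oj) {
      for (int oi = 0; oi < oH; ++oi) {
        double best = -std::numeric_limits<double>::infinity();
        long long bidx = -1;
        for (int dj = 0; dj < kw; ++dj) {
          const int j = oj * stride - pad + dj;
          if (j < 0 || j >= W) continue;
          for (int di = 0; di < kh; ++di) {
            const int i = oi * stride - pad + di;
            if (i < 0 || i >= H) continue;
            const double v = x(i, j, c);
            if (v > best) { best = v; bidx = i + (long long)H * j; }
          }
        }
        out(oi, oj, c) = best;
        arg(oi, oj, c) = bidx;
      }
    }
  }
  return List::create(Named("out") = out, Named("argmax") = arg);
}

// [[Rcpp::export(name = ".maxpool_bwd_cpp")]]
arma::cube maxpool_bwd_cpp(const arma::cube& dout, const arma::icube& arg,
                           int H, int W) {
  const int C = dout.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (unsigned int oj = 0; oj < dout.n_cols; ++oj) {
      for (unsigned int oi = 0; oi < dout.n_rows; ++oi) {
        const long long idx = arg(oi, oj, c);
        if (idx < 0) continue;
        const int i = (int)(idx % H), j = (int)(idx / H);
        dx(i, j, c) += dout(oi, oj, c);
      }
    }
  }
  return dx;
}
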