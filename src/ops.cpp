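// Hot spatial kernels for the network tape.  Feature maps are dense
// matrices with one row per (pixel, sample): row = h + w*H + n*H*W, one
// column per channel.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gather 3x3 neighborhoods (zero padding) into an im2col matrix with
// column layout offset-fastest: col = o + 9*c, offsets ordered
// (dj, di) in {-1,0,1} x {-1,0,1} with di fastest.
// [[Rcpp::export]]
arma::mat cpp_im2col3(const arma::mat& X, int H, int W, int N) {
  const int C = X.n_cols, hwn = H * W * N;
  arma::mat cols(hwn, 9 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    for (int o = 0; o < 9; ++o) {
      const int dj = o / 3 - 1, di = o % 3 - 1;
      double* out = cols.colptr(o + 9 * c);
      for (int n = 0; n < N; ++n) {
        const int base = n * H * W;
        for (int w = 0; w < W; ++w) {
          const int ws = w + dj;
          if (ws < 0 || ws >= W) continue;
          const int outbase = base + w * H, srcbase = base + ws * H;
          const int h0 = std::max(0, -di), h1 = std::min(H, H - di);
          const double* src = xc + srcbase + di;
          double* dst = out + outbase;
          for (int h = h0; h < h1; ++h) dst[h] = src[h];
        }
      }
    }
  }
  return cols;
}

// Adjoint of cpp_im2col3: scatter-add column blocks back onto the image.
// [[Rcpp::export]]
arma::mat cpp_col2im3(const arma::mat& dcols, int H, int W, int N, int C) {
  const int hwn = H * W * N;
  arma::mat dX(hwn, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* xc = dX.colptr(c);
    for (int o = 0; o < 9; ++o) {
      const int dj = o / 3 - 1, di = o % 3 - 1;
      const double* g = dcols.colptr(o + 9 * c);
      for (int n = 0; n < N; ++n) {
        const int base = n * H * W;
        for (int w = 0; w < W; ++w) {
          const int ws = w + dj;
          if (ws < 0 || ws >= W) continue;
          const int outbase = base + w * H, srcbase = base + ws * H;
          const int h0 = std::max(0, -di), h1 = std::min(H, H - di);
          double* dst = xc + srcbase + di;
          const double* src = g + outbase;
          for (int h = h0; h < h1; ++h) dst[h] += src[h];
        }
      }
    }
  }
  return dX;
}

// 2x2 max pooling; `which` records the winning corner (0..3, first wins,
// corners ordered (0,0), (1,0), (0,1), (1,1)).
// [[Rcpp::export]]
List cpp_pool2_fwd(const arma::mat& X, int H, int W, int N) {
  const int H2 = H / 2, W2 = W / 2, C = X.n_cols;
  const int out_n = H2 * W2 * N;
  arma::mat Y(out_n, C);
  IntegerMatrix which(out_n, C);
  const int dh[4] = {0, 1, 0, 1};
  const int dw[4] = {0, 0, 1, 1};
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    double* yc = Y.colptr(c);
    for (int n = 0; n < N; ++n) {
      for (int w2 = 0; w2 < W2; ++w2) {
        for (int h2 = 0; h2 < H2; ++h2) {
          const int r_out = h2 + w2 * H2 + n * H2 * W2;
          double best = -std::numeric_limits<double>::infinity();
          int bi = 0;
          for (int k = 0; k < 4; ++k) {
            const int r_in = (2 * h2 + dh[k]) + (2 * w2 + dw[k]) * H + n * H * W;
            const double v = xc[r_in];
            if (v > best) { best = v; bi = k; }
          }
          yc[r_out] = best;
          which(r_out, c) = bi;
        }
      }
    }
  }
  return List::create(_["y"] = Y, _["which"] = which);
}

// [[Rcpp::export]]
arma::mat cpp_pool2_bwd(const arma::mat& G, const IntegerMatrix& which,
                        int H, int W, int N) {
  const int H2 = H / 2, W2 = W / 2, C = G.n_cols;
  arma::mat dX(H * W * N, C, arma::fill::zeros);
  const int dh[4] = {0, 1, 0, 1};
  const int dw[4] = {0, 0, 1, 1};
  for (int c = 0; c < C; ++c) {
    const double* gc = G.colptr(c);
    double* xc = dX.colptr(c);
    for (int n = 0; n < N; ++n) {
      for (int w2 = 0; w2 < W2; ++w2) {
        for (int h2 = 0; h2 < H2; ++h2) {
          const int r_out = h2 + w2 * H2 + n * H2 * W2;
          const int k = which(r_out, c);
          const int r_in = (2 * h2 + dh[k]) + (2 * w2 + dw[k]) * H + n * H * W;
          xc[r_in] = gc[r_out];
        }
      }
    }
  }
  return dX;
}

// nearest-neighbour x2 upsampling (input H x W -> output 2H x 2W)
// [[Rcpp::export]]
arma::mat cpp_up2_fwd(const arma::mat& X, int H, int W, int N) {
  const int H2 = 2 * H, W2 = 2 * W, C = X.n_cols;
  arma::mat Y(H2 * W2 * N, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    double* yc = Y.colptr(c);
    for (int n = 0; n < N; ++n) {
      for (int w = 0; w < W2; ++w) {
        const int srcw = (w / 2) * H + n * H * W;
        const int outw = w * H2 + n * H2 * W2;
        for (int h = 0; h < H2; ++h) {
          yc[outw + h] = xc[srcw + h / 2];
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
arma::mat cpp_up2_bwd(const arma::mat& G, int H, int W, int N) {
  const int H2 = 2 * H, W2 = 2 * W, C = G.n_cols;
  arma::mat dX(H * W * N, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* gc = G.colptr(c);
    double* xc = dX.colptr(c);
    for (int n = 0; n < N; ++n) {
      for (int w = 0; w < W2; ++w) {
        const int srcw = (w / 2) * H + n * H * W;
        const int outw = w * H2 + n * H2 * W2;
        for (int h = 0; h < H2; ++h) {
          xc[srcw + h / 2] += gc[outw + h];
        }
      }
    }
  }
  return dX;
}

// y[, c] = x[, c] * a[c] + b[c] in one pass
// [[Rcpp::export]]
arma::mat cpp_axpb_cols(const arma::mat& X, const arma::vec& a,
                        const arma::vec& b) {
  arma::mat Y(X.n_rows, X.n_cols);
  for (unsigned c = 0; c < X.n_cols; ++c) {
    const double ac = a(c), bc = b(c);
    const double* x = X.colptr(c);
    double* y = Y.colptr(c);
    for (unsigned r = 0; r < X.n_rows; ++r) y[r] = x[r] * ac + bc;
  }
  return Y;
}

// fused batch-norm input gradient:
// dx[, c] = (dxhat[, c] - mean_d[c] - xhat[, c] * mean_dx[c]) * invs[c]
// [[Rcpp::export]]
arma::mat cpp_bn_bwd(const arma::mat& dxhat, const arma::mat& xhat,
                     const arma::vec& invs, const arma::vec& mean_d,
                     const arma::vec& mean_dx) {
  arma::mat dX(dxhat.n_rows, dxhat.n_cols);
  for (unsigned c = 0; c < dxhat.n_cols; ++c) {
    const double is = invs(c), md = mean_d(c), mdx = mean_dx(c);
    const double* dh = dxhat.colptr(c);
    const double* xh = xhat.colptr(c);
    double* dx = dX.colptr(c);
    for (unsigned r = 0; r < dxhat.n_rows; ++r)
      dx[r] = (dh[r] - md - xh[r] * mdx) * is;
  }
  return dX;
}
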