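// Convolution and pooling kernels for the TBNet autodiff engine.
// Feature maps are H x W x C arma::cubes; convolution weights arrive
// flattened as (Cout x kh*kw*Cin) matrices with the kh-fastest, then kw,
// then Cin ordering produced by im2col below.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(name = ".cpp_im2col")]]
arma::mat cpp_im2col(const arma::cube& x, int kh, int kw, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  arma::mat cols(kh * kw * C, Ho * Wo, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int row = c * kh * kw + j * kh + i;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wsrc = wo * stride + j - pad;
          if (wsrc < 0 || wsrc >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hsrc = ho * stride + i - pad;
            if (hsrc < 0 || hsrc >= H) continue;
            cols(row, wo * Ho + ho) = x(hsrc, wsrc, c);
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col: scatter-add column gradients back onto the image grid.
// [[Rcpp::export(name = ".cpp_col2im")]]
arma::cube cpp_col2im(const arma::mat& cols, int H, int W, int C,
                      int kh, int kw, int stride, int pad) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int row = c * kh * kw + j * kh + i;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wsrc = wo * stride + j - pad;
          if (wsrc < 0 || wsrc >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hsrc = ho * stride + i - pad;
            if (hsrc < 0 || hsrc >= H) continue;
            x(hsrc, wsrc, c) += cols(row, wo * Ho + ho);
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export(name = ".cpp_conv2d_fw")]]
List cpp_conv2d_fw(const arma::cube& x, const arma::mat& wmat,
                   const arma::vec& bias, int kh, int kw, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  const int Cout = wmat.n_rows;
  arma::mat cols = cpp_im2col(x, kh, kw, stride, pad);
  arma::mat ymat = wmat * cols;          // Cout x (Ho*Wo)
  ymat.each_col() += bias;
  arma::cube y(Ho, Wo, Cout);
  for (int c = 0; c < Cout; ++c) {
    y.slice(c) = arma::reshape(ymat.row(c), Ho, Wo);
  }
  return List::create(_["y"] = y, _["cols"] = cols);
}

// [[Rcpp::export(name = ".cpp_conv2d_bw")]]
List cpp_conv2d_bw(const arma::cube& gy, const arma::mat& wmat,
                   const arma::mat& cols, int H, int W, int C,
                   int kh, int kw, int stride, int pad) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, Cout = gy.n_slices;
  arma::mat gymat(Cout, Ho * Wo);
  for (int c = 0; c < Cout; ++c) {
    gymat.row(c) = arma::vectorise(gy.slice(c)).t();
  }
  arma::mat gw = gymat * cols.t();
  arma::vec gb = arma::sum(gymat, 1);
  arma::mat gcols = wmat.t() * gymat;
  arma::cube gx = cpp_col2im(gcols, H, W, C, kh, kw, stride, pad);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling with argmax bookkeeping (H, W even).
// [[Rcpp::export(name = ".cpp_maxpool2_fw")]]
List cpp_maxpool2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);  // linear index into the full cube
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -arma::datum::inf;
        int bi = 0, bj = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const double v = x(2 * ho + di, 2 * wo + dj, c);
            if (v > best) { best = v; bi = 2 * ho + di; bj = 2 * wo + dj; }
          }
        }
        y(ho, wo, c) = best;
        idx(ho, wo, c) = (arma::uword)(c) * H * W + (arma::uword)bj * H + bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bw")]]
arma::cube cpp_maxpool2_bw(const arma::cube& gy, const arma::ucube& idx,
                           int H, int W) {
  const int C = gy.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (arma::uword k = 0; k < gy.n_elem; ++k) {
    gx(idx(k)) += gy(k);
  }
  return gx;
}
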