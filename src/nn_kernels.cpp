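// Low-level numeric kernels for the native neural-network layers.
// Images and feature maps are R arrays dim c(H, W, C) mapped to arma::cube
// (n_rows = H, n_cols = W, n_slices = C). Convolution uses im2col + BLAS.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Patch matrix P is (Ho*Wo) x (C*k*k): one row per output pixel (column-
// major over the output plane), one column per patch element, ordered
// column = c*k*k + kj*k + ki. Column-wise fill keeps every access
// contiguous. Weight matrices built in R are (Cout x C*k*k) in the same
// patch-element order.
// [[Rcpp::export]]
arma::mat im2col_cpp(const arma::cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  arma::mat P(Ho * Wo, C * k * k, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& sl = x.slice(c);
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        double* dst = P.colptr(c * k * k + kj * k + ki);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          const double* src = sl.colptr(wi);
          double* d = dst + (size_t)wo * Ho;
          if (stride == 1) {
            const int h0 = std::max(0, pad - ki);
            const int h1 = std::min(Ho, H + pad - ki);
            for (int ho = h0; ho < h1; ++ho) d[ho] = src[ho - pad + ki];
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + ki;
              if (hi >= 0 && hi < H) d[ho] = src[hi];
            }
          }
        }
      }
  }
  return P;
}

// [[Rcpp::export]]
arma::cube col2im_cpp(const arma::mat& P, int H, int W, int C,
                      int k, int stride, int pad) {
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& sl = x.slice(c);
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const double* src0 = P.colptr(c * k * k + kj * k + ki);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          double* dcol = sl.colptr(wi);
          const double* s = src0 + (size_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + ki;
            if (hi >= 0 && hi < H) dcol[hi] += s[ho];
          }
        }
      }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube conv2d_forward_cpp(const arma::cube& x, const arma::mat& Wm,
                              const arma::vec& b, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  const int Cout = Wm.n_rows;
  arma::mat P = im2col_cpp(x, k, stride, pad);
  arma::mat om = P * Wm.t();          // (Ho*Wo) x Cout
  om.each_row() += b.t();
  arma::cube out(Ho, Wo, Cout);
  std::memcpy(out.memptr(), om.memptr(), sizeof(double) * om.n_elem);
  return out;
}

// recomputes the patch matrix from the cached layer input x (cheaper than
// shuttling it between C++ and R on every forward pass)
// [[Rcpp::export]]
List conv2d_backward_cpp(const arma::cube& dy, const arma::cube& x,
                         const arma::mat& Wm, int k, int stride, int pad) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  arma::mat P = im2col_cpp(x, k, stride, pad);
  arma::mat dym((double*)dy.memptr(), Ho * Wo, Cout);  // view, same layout
  arma::mat dW = dym.t() * P;
  arma::vec db = arma::sum(dym, 0).t();
  arma::mat dP = dym * Wm;
  arma::cube dx = col2im_cpp(dP, x.n_rows, x.n_cols, x.n_slices,
                             k, stride, pad);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2 max pooling, stride 2; idx records the winning offset 0..3 (ki + 2*kj).
// [[Rcpp::export]]
List maxpool2_forward_cpp(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube out(Ho, Wo, C);
  arma::icube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -arma::datum::inf; int bi = 0;
        for (int kj = 0; kj < 2; ++kj)
          for (int ki = 0; ki < 2; ++ki) {
            double v = x(2 * ho + ki, 2 * wo + kj, c);
            if (v > best) { best = v; bi = ki + 2 * kj; }
          }
        out(ho, wo, c) = best; idx(ho, wo, c) = bi;
      }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_backward_cpp(const arma::cube& dy, const arma::icube& idx,
                                 int H, int W) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        int bi = idx(ho, wo, c);
        dx(2 * ho + bi % 2, 2 * wo + bi / 2, c) += dy(ho, wo, c);
      }
  return dx;
}

struct LinW { int i0, i1; double w0, w1; };

static std::vector<LinW> lin_weights(int n_in, int n_out) {
  // half-pixel-center convention (align_corners = false)
  std::vector<LinW> w(n_out);
  const double scale = (double)n_in / n_out;
  for (int o = 0; o < n_out; ++o) {
    double src = (o + 0.5) * scale - 0.5;
    if (src < 0) src = 0;
    if (src > n_in - 1) src = n_in - 1;
    int i0 = (int)std::floor(src);
    int i1 = std::min(i0 + 1, n_in - 1);
    double f = src - i0;
    w[o] = {i0, i1, 1.0 - f, f};
  }
  return w;
}

// [[Rcpp::export]]
arma::cube resize_bilinear_cpp(const arma::cube& x, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  auto wh = lin_weights(H, Ho), ww = lin_weights(W, Wo);
  arma::cube out(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& sl = x.slice(c);
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        out(ho, wo, c) =
          wh[ho].w0 * (ww[wo].w0 * sl(wh[ho].i0, ww[wo].i0) +
                       ww[wo].w1 * sl(wh[ho].i0, ww[wo].i1)) +
          wh[ho].w1 * (ww[wo].w0 * sl(wh[ho].i1, ww[wo].i0) +
                       ww[wo].w1 * sl(wh[ho].i1, ww[wo].i1));
  }
  return out;
}

// exact adjoint of resize_bilinear_cpp
// [[Rcpp::export]]
arma::cube resize_bilinear_backward_cpp(const arma::cube& dy, int H, int W) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  auto wh = lin_weights(H, Ho), ww = lin_weights(W, Wo);
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& sl = dx.slice(c);
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = dy(ho, wo, c);
        sl(wh[ho].i0, ww[wo].i0) += wh[ho].w0 * ww[wo].w0 * g;
        sl(wh[ho].i0, ww[wo].i1) += wh[ho].w0 * ww[wo].w1 * g;
        sl(wh[ho].i1, ww[wo].i0) += wh[ho].w1 * ww[wo].w0 * g;
        sl(wh[ho].i1, ww[wo].i1) += wh[ho].w1 * ww[wo].w1 * g;
      }
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube resize_nearest_cpp(const arma::cube& x, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube out(Ho, Wo, C);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  for (int wo = 0; wo < Wo; ++wo) {
    int wi = std::min((int)std::floor((wo + 0.5) * sw), W - 1);
    for (int ho = 0; ho < Ho; ++ho) {
      int hi = std::min((int)std::floor((ho + 0.5) * sh), H - 1);
      for (int c = 0; c < C; ++c) out(ho, wo, c) = x(hi, wi, c);
    }
  }
  return out;
}

// nearest-neighbour 2x upsample adjoint (sum over the 2x2 block)
// [[Rcpp::export]]
arma::cube upsample2_nearest_backward_cpp(const arma::cube& dy) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  arma::cube dx(Ho / 2, Wo / 2, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        dx(ho / 2, wo / 2, c) += dy(ho, wo, c);
  return dx;
}

// [[Rcpp::export]]
double crc32_cpp(RawVector data) {
  static uint32_t table[256];
  static bool have_table = false;
  if (!have_table) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t r = i;
      for (int j = 0; j < 8; ++j)
        r = (r & 1) ? (0xEDB88320u ^ (r >> 1)) : (r >> 1);
      table[i] = r;
    }
    have_table = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}
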