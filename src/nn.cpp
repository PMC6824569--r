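// im2col-based 2-D convolution primitives for the sinogram U-net.
//
// Feature maps are R arrays dim (H, W, C), i.e. arma::cube with
// n_rows = H, n_cols = W, n_slices = C. A kernel bank is the matrix
// K of shape (kh*kw*cin) x cout obtained from an R array (kh, kw,
// cin, cout) by matrix(K, kh*kw*cin, cout) (column-major, so row
// index = i_kh + kh*(i_kw + kw*i_cin)).
//
// All three routines share one geometry: an "input" grid (Hi, Wi,
// cin) and an "output" grid (Ho, Wo, cout) related by
//   h_in = ho*sh - pt + u,  w_in = wo*sw - pl + v,  u<kh, v<kw,
// with out-of-range positions treated as zeros (this realises
// asymmetric bottom/right padding implicitly). Transposed
// convolution is conv_grad_input applied to the layer input.
//
// The unrolled patch matrix is laid out transposed, (Ho*Wo) x
// (kh*kw*cin), so that the hot inner loop over output rows walks
// both the source cube and the patch matrix contiguously.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// colT(q, u + kh*(v + kw*c)) = x(ho*sh - pt + u, wo*sw - pl + v, c)
static arma::mat im2colT(const arma::cube& x, int kh, int kw,
                         int sh, int sw, int pt, int pl,
                         int Ho, int Wo) {
  const int Hi = x.n_rows, Wi = x.n_cols, cin = x.n_slices;
  arma::mat colT(Ho * Wo, kh * kw * cin, arma::fill::zeros);
  for (int c = 0; c < cin; ++c) {
    for (int v = 0; v < kw; ++v) {
      for (int u = 0; u < kh; ++u) {
        double* dst = colT.colptr(u + kh * (v + kw * c));
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * sw - pl + v;
          if (wi < 0 || wi >= Wi) continue;
          const double* src = x.slice_colptr(c, wi);
          double* d = dst + (arma::uword)Ho * wo;
          if (sh == 1) {
            int ho0 = std::max(0, pt - u);
            int ho1 = std::min(Ho - 1, Hi - 1 + pt - u);
            for (int ho = ho0; ho <= ho1; ++ho)
              d[ho] = src[ho - pt + u];
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * sh - pt + u;
              if (hi < 0 || hi >= Hi) continue;
              d[ho] = src[hi];
            }
          }
        }
      }
    }
  }
  return colT;
}

// y(Ho, Wo, cout) = conv(x; K) + bias
// [[Rcpp::export]]
arma::cube cpp_conv_fwd(const arma::cube& x, const arma::mat& K,
                        const arma::vec& bias,
                        int kh, int kw, int sh, int sw,
                        int pt, int pl, int Ho, int Wo) {
  arma::mat colT = im2colT(x, kh, kw, sh, sw, pt, pl, Ho, Wo);
  arma::mat out = colT * K;              // (Ho*Wo) x cout
  const int cout = K.n_cols;
  arma::cube y(Ho, Wo, cout);
  for (int c = 0; c < cout; ++c) {
    std::memcpy(y.slice_memptr(c), out.colptr(c),
                sizeof(double) * Ho * Wo);
    y.slice(c) += bias[c];
  }
  return y;
}

static arma::mat flatten_slices(const arma::cube& a) {
  // (H*W) x C view-copy of a cube
  const arma::uword n = a.n_rows * a.n_cols;
  arma::mat m(n, a.n_slices);
  for (arma::uword c = 0; c < a.n_slices; ++c)
    std::memcpy(m.colptr(c), a.slice_memptr(c), sizeof(double) * n);
  return m;
}

// dx(Hi, Wi, cin) given dy(Ho, Wo, cout); also the forward pass of a
// transposed convolution with target size (Hi, Wi).
// [[Rcpp::export]]
arma::cube cpp_conv_gradin(const arma::cube& dy, const arma::mat& K,
                           int kh, int kw, int sh, int sw,
                           int pt, int pl, int Hi, int Wi) {
  const int Ho = dy.n_rows, Wo = dy.n_cols;
  const int cin = K.n_rows / (kh * kw);
  arma::mat dcolT = flatten_slices(dy) * K.t();  // (Ho*Wo) x (kh*kw*cin)
  arma::cube dx(Hi, Wi, cin, arma::fill::zeros);
  for (int c = 0; c < cin; ++c) {
    for (int v = 0; v < kw; ++v) {
      for (int u = 0; u < kh; ++u) {
        const double* src0 = dcolT.colptr(u + kh * (v + kw * c));
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * sw - pl + v;
          if (wi < 0 || wi >= Wi) continue;
          double* dst = dx.slice_colptr(c, wi);
          const double* s = src0 + (arma::uword)Ho * wo;
          if (sh == 1) {
            int ho0 = std::max(0, pt - u);
            int ho1 = std::min(Ho - 1, Hi - 1 + pt - u);
            for (int ho = ho0; ho <= ho1; ++ho)
              dst[ho - pt + u] += s[ho];
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * sh - pt + u;
              if (hi < 0 || hi >= Hi) continue;
              dst[hi] += s[ho];
            }
          }
        }
      }
    }
  }
  return dx;
}

// dK given the layer input x and upstream gradient dy.
// [[Rcpp::export]]
arma::mat cpp_conv_gradK(const arma::cube& x, const arma::cube& dy,
                         int kh, int kw, int sh, int sw,
                         int pt, int pl) {
  const int Ho = dy.n_rows, Wo = dy.n_cols;
  arma::mat colT = im2colT(x, kh, kw, sh, sw, pt, pl, Ho, Wo);
  return colT.t() * flatten_slices(dy);  // (kh*kw*cin) x cout
}

// per-slice sums (bias gradient)
// [[Rcpp::export]]
arma::vec cpp_slice_sums(const arma::cube& a) {
  arma::vec s(a.n_slices);
  for (arma::uword c = 0; c < a.n_slices; ++c)
    s[c] = arma::accu(a.slice(c));
  return s;
}

// 2x2 stride-2 pooling with ceil-mode output sizes. mode 0 = max
// (invalid/padded positions ignored), mode 1 = mean as zero-padded
// sum/4 (so a 2x2 strided convolution with all four coefficients 1/4
// is exactly equivalent). Returns the pooled cube and, for max, the
// 1-based linear argmax index into x for each output element.
// [[Rcpp::export]]
List cpp_pool_fwd(const arma::cube& x, int mode) {
  const int Hi = x.n_rows, Wi = x.n_cols, C = x.n_slices;
  const int Ho = (Hi + 1) / 2, Wo = (Wi + 1) / 2;
  arma::cube y(Ho, Wo, C, arma::fill::zeros);
  arma::ucube arg(Ho, Wo, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -std::numeric_limits<double>::infinity();
        arma::uword bidx = 0; double sum = 0.0;
        for (int v = 0; v < 2; ++v) {
          const int wi = 2 * wo + v; if (wi >= Wi) continue;
          for (int u = 0; u < 2; ++u) {
            const int hi = 2 * ho + u; if (hi >= Hi) continue;
            const double val = x(hi, wi, c);
            sum += val;
            if (val > best) {
              best = val;
              bidx = hi + (arma::uword)Hi * (wi + (arma::uword)Wi * c);
            }
          }
        }
        if (mode == 0) { y(ho, wo, c) = best; arg(ho, wo, c) = bidx + 1; }
        else           { y(ho, wo, c) = sum / 4.0; }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// Gradient of cpp_pool_fwd.
// [[Rcpp::export]]
arma::cube cpp_pool_bwd(const arma::cube& dy, const arma::ucube& arg,
                        int mode, int Hi, int Wi) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  arma::cube dx(Hi, Wi, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = dy(ho, wo, c);
        if (mode == 0) {
          const arma::uword idx = arg(ho, wo, c) - 1;
          dx(idx % Hi, (idx / Hi) % Wi, idx / ((arma::uword)Hi * Wi)) += g;
        } else {
          for (int v = 0; v < 2; ++v) {
            const int wi = 2 * wo + v; if (wi >= Wi) continue;
            for (int u = 0; u < 2; ++u) {
              const int hi = 2 * ho + u; if (hi >= Hi) continue;
              dx(hi, wi, c) += g / 4.0;
            }
          }
        }
      }
    }
  }
  return dx;
}
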