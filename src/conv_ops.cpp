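// Convolution primitives for the CNN engine: im2col + GEMM forward and
// backward passes for 1-D (temporal) and 2-D (image) convolutions with
// symmetric zero padding. Layer bookkeeping (batch norm, dropout, Adam)
// lives in R; only the convolutions are compiled.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_len(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// x slice: (L, Cin); col: (k*Cin, Lout), row order cin*k + kk
static void im2col1d(const arma::mat& x, int k, int stride, int pad,
                     arma::mat& col) {
  const int L = x.n_rows, Cin = x.n_cols;
  const int Lout = out_len(L, k, stride, pad);
  for (int j = 0; j < Lout; ++j) {
    const int j0 = j * stride - pad;
    for (int c = 0; c < Cin; ++c) {
      const double* xc = x.colptr(c);
      double* cp = col.colptr(j) + c * k;
      for (int kk = 0; kk < k; ++kk) {
        const int s = j0 + kk;
        cp[kk] = (s >= 0 && s < L) ? xc[s] : 0.0;
      }
    }
  }
}

static void col2im1d(const arma::mat& gcol, int L, int Cin, int k, int stride,
                     int pad, arma::mat& gx) {
  const int Lout = gcol.n_cols;
  for (int j = 0; j < Lout; ++j) {
    const int j0 = j * stride - pad;
    for (int c = 0; c < Cin; ++c) {
      const double* cp = gcol.colptr(j) + c * k;
      double* gxc = gx.colptr(c);
      for (int kk = 0; kk < k; ++kk) {
        const int s = j0 + kk;
        if (s >= 0 && s < L) gxc[s] += cp[kk];
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv1d_fw(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b, int stride, int pad) {
  const int L = x.n_rows, Cin = x.n_cols, N = x.n_slices;
  const int k = w.n_rows / Cin, Cout = w.n_cols;
  const int Lout = out_len(L, k, stride, pad);
  arma::cube out(Lout, Cout, N);
  arma::mat col(k * Cin, Lout);
  for (int n = 0; n < N; ++n) {
    im2col1d(x.slice(n), k, stride, pad, col);
    out.slice(n) = col.t() * w;
    out.slice(n).each_row() += b.t();
  }
  return out;
}

// [[Rcpp::export]]
List conv1d_bw(const arma::cube& x, const arma::mat& w, const arma::cube& gout,
               int stride, int pad) {
  const int L = x.n_rows, Cin = x.n_cols, N = x.n_slices;
  const int k = w.n_rows / Cin, Cout = w.n_cols;
  const int Lout = gout.n_rows;
  arma::cube gx(L, Cin, N, arma::fill::zeros);
  arma::mat gw(k * Cin, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  arma::mat col(k * Cin, Lout);
  for (int n = 0; n < N; ++n) {
    im2col1d(x.slice(n), k, stride, pad, col);
    const arma::mat& go = gout.slice(n);       // (Lout, Cout)
    gw += col * go;
    gb += arma::sum(go, 0).t();
    arma::mat gcol = w * go.t();               // (k*Cin, Lout)
    arma::mat gxs(L, Cin, arma::fill::zeros);
    col2im1d(gcol, L, Cin, k, stride, pad, gxs);
    gx.slice(n) = gxs;
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// x sample viewed as cube (H, W, Cin); col: (kh*kw*Cin, Ho*Wo),
// row order cin*kh*kw + j*kh + i, column order q = ho + wo*Ho
static void im2col2d(const arma::cube& x, int kh, int kw, int stride, int pad,
                     arma::mat& col) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Ho = out_len(H, kh, stride, pad), Wo = out_len(W, kw, stride, pad);
  for (int wo = 0; wo < Wo; ++wo) {
    const int w0 = wo * stride - pad;
    for (int ho = 0; ho < Ho; ++ho) {
      const int h0 = ho * stride - pad;
      double* cp = col.colptr(ho + wo * Ho);
      for (int c = 0; c < Cin; ++c) {
        for (int j = 0; j < kw; ++j) {
          const int sw = w0 + j;
          double* dst = cp + c * kh * kw + j * kh;
          if (sw < 0 || sw >= W) {
            for (int i = 0; i < kh; ++i) dst[i] = 0.0;
          } else {
            const double* src = x.slice_colptr(c, sw);
            for (int i = 0; i < kh; ++i) {
              const int sh = h0 + i;
              dst[i] = (sh >= 0 && sh < H) ? src[sh] : 0.0;
            }
          }
        }
      }
    }
  }
}

static void col2im2d(const arma::mat& gcol, int H, int W, int Cin, int kh,
                     int kw, int stride, int pad, arma::cube& gx) {
  const int Ho = out_len(H, kh, stride, pad), Wo = out_len(W, kw, stride, pad);
  for (int wo = 0; wo < Wo; ++wo) {
    const int w0 = wo * stride - pad;
    for (int ho = 0; ho < Ho; ++ho) {
      const int h0 = ho * stride - pad;
      const double* cp = gcol.colptr(ho + wo * Ho);
      for (int c = 0; c < Cin; ++c) {
        for (int j = 0; j < kw; ++j) {
          const int sw = w0 + j;
          if (sw < 0 || sw >= W) continue;
          const double* src = cp + c * kh * kw + j * kh;
          double* dst = gx.slice_colptr(c, sw);
          for (int i = 0; i < kh; ++i) {
            const int sh = h0 + i;
            if (sh >= 0 && sh < H) dst[sh] += src[i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, const arma::mat& w, const arma::vec& b,
                        int stride, int pad, int kh, int kw) {
  IntegerVector dims = x.attr("dim");
  const int H = dims[0], W = dims[1], Cin = dims[2], N = dims[3];
  const int Cout = w.n_cols;
  const int Ho = out_len(H, kh, stride, pad), Wo = out_len(W, kw, stride, pad);
  NumericVector out(static_cast<R_xlen_t>(Ho) * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(kh * kw * Cin, Ho * Wo);
  const size_t in_per_n = static_cast<size_t>(H) * W * Cin;
  const size_t out_per_n = static_cast<size_t>(Ho) * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    arma::cube xc(const_cast<double*>(REAL(x)) + n * in_per_n, H, W, Cin,
                  false, true);
    im2col2d(xc, kh, kw, stride, pad, col);
    arma::mat o = col.t() * w;             // (Ho*Wo, Cout)
    o.each_row() += b.t();
    std::copy(o.memptr(), o.memptr() + out_per_n, REAL(out) + n * out_per_n);
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, const arma::mat& w, NumericVector gout,
               int stride, int pad, int kh, int kw) {
  IntegerVector dims = x.attr("dim");
  const int H = dims[0], W = dims[1], Cin = dims[2], N = dims[3];
  IntegerVector odims = gout.attr("dim");
  const int Ho = odims[0], Wo = odims[1], Cout = odims[2];
  NumericVector gxv(x.size());
  gxv.attr("dim") = x.attr("dim");
  arma::mat gw(kh * kw * Cin, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  arma::mat col(kh * kw * Cin, Ho * Wo);
  const size_t in_per_n = static_cast<size_t>(H) * W * Cin;
  const size_t out_per_n = static_cast<size_t>(Ho) * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    arma::cube xc(const_cast<double*>(REAL(x)) + n * in_per_n, H, W, Cin,
                  false, true);
    im2col2d(xc, kh, kw, stride, pad, col);
    arma::mat go(const_cast<double*>(REAL(gout)) + n * out_per_n, Ho * Wo,
                 Cout, false, true);
    gw += col * go;
    gb += arma::sum(go, 0).t();
    arma::mat gcol = w * go.t();           // (kh*kw*Cin, Ho*Wo)
    arma::cube gxc(REAL(gxv) + n * in_per_n, H, W, Cin, false, true);
    col2im2d(gcol, H, W, Cin, kh, kw, stride, pad, gxc);
  }
  return List::create(_["gx"] = gxv, _["gw"] = gw, _["gb"] = gb);
}
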