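// Planar convolution (cross-correlation) and max-pool primitives.
// Layout convention: feature arrays are column-major R arrays with
// dim (H, W, C, N); kernels are (k, k, Cin, Cout). im2col columns are
// ordered (kernel row fastest, then kernel col, then input channel) to
// match the column-major flattening of the kernel array, so the forward
// pass is a single BLAS matmul per image.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, arma::mat& cols) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  // cols is (k*k*C, Ho*Wo)
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      double* dst = cols.colptr(col);
      for (int c = 0; c < C; ++c) {
        const double* plane = x + (size_t)c * H * W;
        for (int j = 0; j < k; ++j) {
          const int wsrc = wo * stride - pad + j;
          if (wsrc < 0 || wsrc >= W) {
            for (int i = 0; i < k; ++i) dst[i + k * (j + k * c)] = 0.0;
            continue;
          }
          const double* colsrc = plane + (size_t)wsrc * H;
          for (int i = 0; i < k; ++i) {
            const int hsrc = ho * stride - pad + i;
            dst[i + k * (j + k * c)] =
              (hsrc < 0 || hsrc >= H) ? 0.0 : colsrc[hsrc];
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& cols, int H, int W, int C,
                       int k, int stride, int pad, double* x) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      const double* src = cols.colptr(col);
      for (int c = 0; c < C; ++c) {
        double* plane = x + (size_t)c * H * W;
        for (int j = 0; j < k; ++j) {
          const int wdst = wo * stride - pad + j;
          if (wdst < 0 || wdst >= W) continue;
          double* coldst = plane + (size_t)wdst * H;
          for (int i = 0; i < k; ++i) {
            const int hdst = ho * stride - pad + i;
            if (hdst < 0 || hdst >= H) continue;
            coldst[hdst] += src[i + k * (j + k * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                           int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("kernel must be square");
  if (Cin != C) stop("input channel count (%d) does not match kernel (%d)", C, Cin);
  if (H + 2 * pad < k || W + 2 * pad < k) stop("kernel larger than padded input");
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  const int K = k * k * C, L = Ho * Wo;

  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * Cout * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat cols(K, L);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, cols);
    arma::mat out(y.begin() + (size_t)n * L * Cout, L, Cout, false, true);
    out = cols.t() * Wm;
    for (int c = 0; c < Cout; ++c) out.col(c) += b[c];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector gy,
                  int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  const int K = k * k * C, L = Ho * Wo;

  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector gx(Rf_allocVector(REALSXP, x.size()));
  gx.attr("dim") = xd;
  std::fill(gx.begin(), gx.end(), 0.0);
  arma::mat gW(K, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  arma::mat cols(K, L);
  for (int n = 0; n < N; ++n) {
    arma::mat gout(const_cast<double*>(gy.begin()) + (size_t)n * L * Cout,
                   L, Cout, false, true);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, cols);
    gW += cols * gout;
    gb += arma::sum(gout, 0).t();
    arma::mat gcols = Wm * gout.t();  // (K, L)
    col2im_add(gcols, H, W, C, k, stride, pad,
               gx.begin() + (size_t)n * H * W * C);
  }
  NumericVector gWout(gW.begin(), gW.end());
  gWout.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gWout,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int size, int stride) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (size > H || size > W) stop("pooling window larger than input");
  const int Ho = out_size(H, size, stride, 0);
  const int Wo = out_size(W, size, stride, 0);
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(Rf_allocVector(INTSXP, (R_xlen_t)Ho * Wo * C * N));
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = xp + (size_t)(n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = 0;
          for (int j = 0; j < size; ++j) {
            const int wsrc = wo * stride + j;
            for (int i = 0; i < size; ++i) {
              const int hsrc = ho * stride + i;
              const int lin = hsrc + H * wsrc;
              if (plane[lin] > best) { best = plane[lin]; besti = lin; }
            }
          }
          const size_t o = (size_t)(n * C + c) * Ho * Wo + ho + Ho * wo;
          yp[o] = best;
          ip[o] = besti;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector idx,
                              IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector yd = gy.attr("dim");
  const int Ho = yd[0], Wo = yd[1];
  NumericVector gx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
  gx.attr("dim") = xdim;
  std::fill(gx.begin(), gx.end(), 0.0);
  double* gxp = gx.begin();
  const double* gyp = gy.begin();
  const int* ip = idx.begin();
  const size_t plane_out = (size_t)Ho * Wo, plane_in = (size_t)H * W;
  for (int nc = 0; nc < N * C; ++nc) {
    double* dst = gxp + plane_in * nc;
    const double* src = gyp + plane_out * nc;
    const int* id = ip + plane_out * nc;
    for (size_t l = 0; l < plane_out; ++l) dst[id[l]] += src[l];
  }
  return gx;
}
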