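// Numerical core for the 3D convolutional stack.
//
// Feature volumes are R arrays with dim (D, H, W, C), column-major, so the
// flat buffer doubles as an (N = D*H*W) x C matrix. Convolutions use
// im2col + GEMM; "same" zero padding with left pad floor((k-1)/2). Weight
// arrays have dim (kd, kh, kw, Cin, Cout), whose column-major layout equals
// the (K = kd*kh*kw*Cin) x Cout GEMM matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col3d(const double* x, int D, int H, int W, int C,
                     int kd, int kh, int kw, arma::mat& col) {
  const int N = D * H * W;
  const int pd0 = (kd - 1) / 2, ph0 = (kh - 1) / 2, pw0 = (kw - 1) / 2;
  for (int ci = 0; ci < C; ++ci) {
    for (int pw = 0; pw < kw; ++pw) {
      for (int ph = 0; ph < kh; ++ph) {
        for (int pd = 0; pd < kd; ++pd) {
          const int kcol = pd + kd * (ph + kh * (pw + kw * ci));
          double* dst = col.colptr(kcol);
          const double* src = x + (std::size_t)N * ci;
          for (int w = 0; w < W; ++w) {
            const int sw = w + pw - pw0;
            const bool w_ok = sw >= 0 && sw < W;
            for (int h = 0; h < H; ++h) {
              const int sh = h + ph - ph0;
              const bool hw_ok = w_ok && sh >= 0 && sh < H;
              double* drow = dst + (std::size_t)D * (h + (std::size_t)H * w);
              if (!hw_ok) {
                std::fill(drow, drow + D, 0.0);
                continue;
              }
              const double* srow = src + (std::size_t)D * (sh + (std::size_t)H * sw);
              const int pdd = pd - pd0;
              const int d_lo = std::max(0, -pdd);
              const int d_hi = std::min(D, D - pdd);
              for (int d = 0; d < d_lo; ++d) drow[d] = 0.0;
              for (int d = d_lo; d < d_hi; ++d) drow[d] = srow[d + pdd];
              for (int d = d_hi; d < D; ++d) drow[d] = 0.0;
            }
          }
        }
      }
    }
  }
}

static void col2im3d(const arma::mat& col, int D, int H, int W, int C,
                     int kd, int kh, int kw, double* dx) {
  const int N = D * H * W;
  const int pd0 = (kd - 1) / 2, ph0 = (kh - 1) / 2, pw0 = (kw - 1) / 2;
  std::fill(dx, dx + (std::size_t)N * C, 0.0);
  for (int ci = 0; ci < C; ++ci) {
    for (int pw = 0; pw < kw; ++pw) {
      for (int ph = 0; ph < kh; ++ph) {
        for (int pd = 0; pd < kd; ++pd) {
          const int kcol = pd + kd * (ph + kh * (pw + kw * ci));
          const double* src = col.colptr(kcol);
          double* dst = dx + (std::size_t)N * ci;
          for (int w = 0; w < W; ++w) {
            const int sw = w + pw - pw0;
            if (sw < 0 || sw >= W) continue;
            for (int h = 0; h < H; ++h) {
              const int sh = h + ph - ph0;
              if (sh < 0 || sh >= H) continue;
              const double* srow = src + (std::size_t)D * (h + (std::size_t)H * w);
              double* drow = dst + (std::size_t)D * (sh + (std::size_t)H * sw);
              const int pdd = pd - pd0;
              const int d_lo = std::max(0, -pdd);
              const int d_hi = std::min(D, D - pdd);
              for (int d = d_lo; d < d_hi; ++d) drow[d + pdd] += srow[d];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, IntegerVector xdim,
                             NumericMatrix wmat, IntegerVector kdim,
                             NumericVector bias) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  const int kd = kdim[0], kh = kdim[1], kw = kdim[2];
  const int N = D * H * W;
  const int K = kd * kh * kw * C;
  const int Cout = wmat.ncol();
  if (wmat.nrow() != K) stop("kernel/input channel mismatch");
  if (bias.size() != Cout) stop("bias length mismatch");
  arma::mat col(N, K);
  im2col3d(x.begin(), D, H, W, C, kd, kh, kw, col);
  const arma::mat Wm(wmat.begin(), K, Cout, false, true);
  arma::mat out = col * Wm;
  const arma::rowvec b(const_cast<double*>(bias.begin()), Cout, false, true);
  out.each_row() += b;
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(D, H, W, Cout);
  return res;
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, IntegerVector xdim,
                    NumericMatrix wmat, IntegerVector kdim,
                    NumericMatrix dy) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  const int kd = kdim[0], kh = kdim[1], kw = kdim[2];
  const int N = D * H * W;
  const int K = kd * kh * kw * C;
  const int Cout = wmat.ncol();
  if (dy.nrow() != N || dy.ncol() != Cout) stop("dy shape mismatch");
  arma::mat col(N, K);
  im2col3d(x.begin(), D, H, W, C, kd, kh, kw, col);
  const arma::mat Wm(wmat.begin(), K, Cout, false, true);
  const arma::mat dY(dy.begin(), N, Cout, false, true);
  arma::mat dW = col.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dcol = dY * Wm.t();
  NumericVector dx(x.size());
  col2im3d(dcol, D, H, W, C, kd, kh, kw, dx.begin());
  dx.attr("dim") = xdim;
  NumericMatrix dWr(K, Cout, dW.begin());
  return List::create(_["dx"] = dx, _["dw"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
List maxpool3d_fwd_cpp(NumericVector x, IntegerVector xdim) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  if (D % 2 || H % 2 || W % 2) stop("pooling requires even extents");
  const int D2 = D / 2, H2 = H / 2, W2 = W / 2;
  const std::size_t N = (std::size_t)D * H * W;
  const std::size_t N2 = (std::size_t)D2 * H2 * W2;
  NumericVector y((R_xlen_t)(N2 * C));
  IntegerVector amax((R_xlen_t)(N2 * C));
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int w = 0; w < W2; ++w) {
      for (int h = 0; h < H2; ++h) {
        for (int d = 0; d < D2; ++d) {
          double best = -std::numeric_limits<double>::infinity();
          std::size_t bidx = 0;
          for (int ow = 0; ow < 2; ++ow)
            for (int oh = 0; oh < 2; ++oh)
              for (int od = 0; od < 2; ++od) {
                std::size_t idx = (std::size_t)(2 * d + od) +
                  (std::size_t)D * ((2 * h + oh) + (std::size_t)H * (2 * w + ow)) +
                  N * c;
                if (px[idx] > best) { best = px[idx]; bidx = idx; }
              }
          std::size_t oidx = (std::size_t)d + (std::size_t)D2 *
            (h + (std::size_t)H2 * w) + N2 * c;
          y[oidx] = best;
          amax[oidx] = (int)bidx;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(D2, H2, W2, C);
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd_cpp(NumericVector dy, IntegerVector argmax,
                                IntegerVector xdim) {
  const std::size_t n = (std::size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx((R_xlen_t)n);
  const R_xlen_t m = dy.size();
  if (argmax.size() != m) stop("argmax/dy length mismatch");
  for (R_xlen_t i = 0; i < m; ++i) dx[argmax[i]] += dy[i];
  dx.attr("dim") = xdim;
  return dx;
}
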