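// Batched 2D convolution primitives for the separation network.
//
// Images are H x W x C arrays (R column-major); kernels are flattened to
// (k * k * Cin) x Cout matrices with row index ki + k*kj + k*k*c, so both
// directions of every layer reduce to im2col/col2im plus a GEMM, which is
// where virtually all training time is spent. Convolution is
// cross-correlation with symmetric zero padding; transposed convolution
// (stride = kernel, no padding) is implemented as the exact adjoint of the
// strided convolution with the kernel matrix shaped (k * k * Cout) x Cin.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::cube asCube(SEXP a) {
  NumericVector v(a);
  IntegerVector d = v.attr("dim");
  if (d.size() != 3) stop("expected a 3D array");
  arma::cube x(v.begin(), d[0], d[1], d[2]);
  return x;
}

static NumericVector cubeToR(const arma::cube& x) {
  NumericVector out(x.begin(), x.end());
  out.attr("dim") =
      IntegerVector::create(x.n_rows, x.n_cols, x.n_slices);
  return out;
}

static arma::mat im2col(const arma::cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::mat cols(k * k * C, Ho * Wo, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int row = ki + k * kj + k * k * c;
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * stride - pad + kj;
          if (j < 0 || j >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int i = io * stride - pad + ki;
            if (i < 0 || i >= H) continue;
            cols(row, io + Ho * jo) = x(i, j, c);
          }
        }
      }
    }
  }
  return cols;
}

static void col2imAdd(arma::cube& gx, const arma::mat& cols, int k,
                      int stride, int pad) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int row = ki + k * kj + k * k * c;
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * stride - pad + kj;
          if (j < 0 || j >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int i = io * stride - pad + ki;
            if (i < 0 || i >= H) continue;
            gx(i, j, c) += cols(row, io + Ho * jo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List convForwardCpp(List xs, const arma::mat& w, const arma::vec& b, int k,
                    int stride, int pad) {
  const int n = xs.size();
  const int cout = w.n_cols;
  List ys(n);
  for (int t = 0; t < n; ++t) {
    arma::cube x = asCube(xs[t]);
    const int Ho = ((int)x.n_rows + 2 * pad - k) / stride + 1;
    const int Wo = ((int)x.n_cols + 2 * pad - k) / stride + 1;
    arma::mat cols = im2col(x, k, stride, pad);
    arma::mat yf = cols.t() * w; // (Ho*Wo) x Cout
    yf.each_row() += b.t();
    arma::cube y(yf.memptr(), Ho, Wo, cout);
    ys[t] = cubeToR(y);
  }
  return ys;
}

// [[Rcpp::export]]
List convBackwardCpp(List xs, const arma::mat& w, List gys, int k,
                     int stride, int pad) {
  const int n = xs.size();
  arma::mat gw(w.n_rows, w.n_cols, arma::fill::zeros);
  arma::vec gb(w.n_cols, arma::fill::zeros);
  List gxs(n);
  for (int t = 0; t < n; ++t) {
    arma::cube x = asCube(xs[t]);
    arma::cube gy = asCube(gys[t]);
    arma::mat gyf(gy.memptr(), gy.n_rows * gy.n_cols, gy.n_slices, false);
    arma::mat cols = im2col(x, k, stride, pad);
    gw += cols * gyf;
    gb += arma::sum(gyf, 0).t();
    arma::mat gcols = w * gyf.t(); // (k*k*Cin) x (Ho*Wo)
    arma::cube gx(x.n_rows, x.n_cols, x.n_slices, arma::fill::zeros);
    col2imAdd(gx, gcols, k, stride, pad);
    gxs[t] = cubeToR(gx);
  }
  return List::create(_["gx"] = gxs, _["gw"] = gw, _["gb"] = gb);
}

// Transposed convolution, stride = k, no padding. Kernel matrix is
// (k * k * Cout) x Cin; the output of an H x W x Cin input is
// (k H) x (k W) x Cout.
// [[Rcpp::export]]
List convTForwardCpp(List xs, const arma::mat& w, const arma::vec& b,
                     int k) {
  const int n = xs.size();
  const int cout = w.n_rows / (k * k);
  List ys(n);
  for (int t = 0; t < n; ++t) {
    arma::cube x = asCube(xs[t]);
    arma::mat xf(x.memptr(), x.n_rows * x.n_cols, x.n_slices, false);
    arma::mat gcols = w * xf.t(); // (k*k*Cout) x (H*W)
    arma::cube y(k * x.n_rows, k * x.n_cols, cout, arma::fill::zeros);
    col2imAdd(y, gcols, k, k, 0);
    for (int c = 0; c < cout; ++c) y.slice(c) += b[c];
    ys[t] = cubeToR(y);
  }
  return ys;
}

// [[Rcpp::export]]
List convTBackwardCpp(List xs, const arma::mat& w, List gys, int k) {
  const int n = xs.size();
  arma::mat gw(w.n_rows, w.n_cols, arma::fill::zeros);
  arma::vec gb(w.n_rows / (k * k), arma::fill::zeros);
  List gxs(n);
  for (int t = 0; t < n; ++t) {
    arma::cube x = asCube(xs[t]);
    arma::cube gy = asCube(gys[t]);
    arma::mat xf(x.memptr(), x.n_rows * x.n_cols, x.n_slices, false);
    arma::mat cols = im2col(gy, k, k, 0); // (k*k*Cout) x (H*W)
    gw += cols * xf;
    arma::mat gxf = cols.t() * w; // (H*W) x Cin
    arma::cube gx(gxf.memptr(), x.n_rows, x.n_cols, x.n_slices);
    gxs[t] = cubeToR(gx);
    for (arma::uword c = 0; c < gy.n_slices; ++c) {
      gb[c] += arma::accu(gy.slice(c));
    }
  }
  return List::create(_["gx"] = gxs, _["gw"] = gw, _["gb"] = gb);
}
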