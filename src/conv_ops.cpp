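// Minimal dense conv-net primitives used by the Sobel-skip U-Net.
// Activations are H x W x C cubes; convolution weights are (Cout, Cin*K*K)
// matrices with column index c*K*K + (dy+r)*K + (dx+r); transposed-conv
// (2x2, stride 2) weights are flat vectors indexed dy + 2*dx + 4*c +
// 4*Cin*o.  Convolutions are "same" with zero padding; im2col + BLAS
// matmul carries the bulk of the arithmetic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

static mat im2col(const cube &x, int K) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, r = K / 2;
  mat cols(C * K * K, H * W);
  mat padded(H + 2 * r, W + 2 * r, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    padded.submat(r, r, r + H - 1, r + W - 1) = x.slice(c);
    for (int dx = 0; dx < K; ++dx)
      for (int dy = 0; dy < K; ++dy) {
        int row = c * K * K + dy * K + dx;
        cols.row(row) =
            arma::vectorise(padded.submat(dy, dx, dy + H - 1, dx + W - 1)).t();
      }
  }
  return cols;
}

// [[Rcpp::export(name = ".cg_conv2d_fwd")]]
arma::cube cg_conv2d_fwd(arma::cube x, arma::mat w, arma::vec b, int K) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_rows;
  mat cols = im2col(x, K);
  mat y = w * cols;
  y.each_col() += b;
  cube out(H, W, Cout);
  for (int o = 0; o < Cout; ++o)
    out.slice(o) = arma::reshape(y.row(o), H, W);
  return out;
}

// [[Rcpp::export(name = ".cg_conv2d_bwd")]]
List cg_conv2d_bwd(arma::cube x, arma::mat w, arma::cube dy, int K) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices, r = K / 2;
  const int Cout = w.n_rows;
  mat dymat(Cout, H * W);
  for (int o = 0; o < Cout; ++o)
    dymat.row(o) = arma::vectorise(dy.slice(o)).t();
  mat cols = im2col(x, K);
  mat dw = dymat * cols.t();
  vec db = arma::sum(dymat, 1);
  mat dcols = w.t() * dymat;
  cube dx(H, W, Cin, arma::fill::zeros);
  mat padded(H + 2 * r, W + 2 * r);
  for (int c = 0; c < Cin; ++c) {
    padded.zeros();
    for (int dxk = 0; dxk < K; ++dxk)
      for (int dyk = 0; dyk < K; ++dyk) {
        int row = c * K * K + dyk * K + dxk;
        padded.submat(dyk, dxk, dyk + H - 1, dxk + W - 1) +=
            arma::reshape(dcols.row(row), H, W);
      }
    dx.slice(c) = padded.submat(r, r, r + H - 1, r + W - 1);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2; H and W must be even.  idx records the argmax
// corner (dy + 2*dx) for the backward scatter.
// [[Rcpp::export(name = ".cg_maxpool_fwd")]]
List cg_maxpool_fwd(arma::cube x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) stop("maxpool needs even spatial dimensions");
  const int h = H / 2, w = W / 2;
  cube y(h, w, C);
  arma::ucube idx(h, w, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        double best = x(2 * i, 2 * j, c);
        int bk = 0;
        for (int dx = 0; dx < 2; ++dx)
          for (int dy = 0; dy < 2; ++dy) {
            double v = x(2 * i + dy, 2 * j + dx, c);
            if (v > best) { best = v; bk = dy + 2 * dx; }
          }
        y(i, j, c) = best;
        idx(i, j, c) = bk;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cg_maxpool_bwd")]]
arma::cube cg_maxpool_bwd(arma::cube dy, arma::ucube idx) {
  const int h = dy.n_rows, w = dy.n_cols, C = dy.n_slices;
  cube dx(2 * h, 2 * w, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        int k = idx(i, j, c);
        dx(2 * i + k % 2, 2 * j + k / 2, c) = dy(i, j, c);
      }
  return dx;
}

// Transposed convolution, 2x2 kernel, stride 2 (learned x2 upsampling).
// [[Rcpp::export(name = ".cg_tconv_fwd")]]
arma::cube cg_tconv_fwd(arma::cube x, arma::vec w, arma::vec b) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = b.n_elem;
  if ((int)w.n_elem != 4 * Cin * Cout) stop("tconv weight length mismatch");
  mat xmat(Cin, H * W);
  for (int c = 0; c < Cin; ++c)
    xmat.row(c) = arma::vectorise(x.slice(c)).t();
  cube y(2 * H, 2 * W, Cout);
  for (int o = 0; o < Cout; ++o) y.slice(o).fill(b(o));
  for (int dx = 0; dx < 2; ++dx)
    for (int dy = 0; dy < 2; ++dy) {
      mat wm(Cout, Cin);
      for (int o = 0; o < Cout; ++o)
        for (int c = 0; c < Cin; ++c)
          wm(o, c) = w(dy + 2 * dx + 4 * c + 4 * Cin * o);
      mat out = wm * xmat;  // Cout x HW
      for (int o = 0; o < Cout; ++o)
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            y(2 * i + dy, 2 * j + dx, o) += out(o, i + j * H);
    }
  return y;
}

// [[Rcpp::export(name = ".cg_tconv_bwd")]]
List cg_tconv_bwd(arma::cube x, arma::vec w, arma::cube dy) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  mat xmat(Cin, H * W);
  for (int c = 0; c < Cin; ++c)
    xmat.row(c) = arma::vectorise(x.slice(c)).t();
  vec db(Cout);
  for (int o = 0; o < Cout; ++o) db(o) = arma::accu(dy.slice(o));
  vec dw(4 * Cin * Cout, arma::fill::zeros);
  mat dxmat(Cin, H * W, arma::fill::zeros);
  for (int dx = 0; dx < 2; ++dx)
    for (int dyk = 0; dyk < 2; ++dyk) {
      mat dmat(Cout, H * W);
      for (int o = 0; o < Cout; ++o)
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            dmat(o, i + j * H) = dy(2 * i + dyk, 2 * j + dx, o);
      mat dwm = dmat * xmat.t();  // Cout x Cin
      mat wm(Cout, Cin);
      for (int o = 0; o < Cout; ++o)
        for (int c = 0; c < Cin; ++c) {
          int id = dyk + 2 * dx + 4 * c + 4 * Cin * o;
          dw(id) = dwm(o, c);
          wm(o, c) = w(id);
        }
      dxmat += wm.t() * dmat;
    }
  cube dxc(H, W, Cin);
  for (int c = 0; c < Cin; ++c)
    dxc.slice(c) = arma::reshape(dxmat.row(c), H, W);
  return List::create(_["dx"] = dxc, _["dw"] = dw, _["db"] = db);
}

// 2x2 average pooling of a single-channel map (fixed Sobel skip pathway).
// [[Rcpp::export(name = ".cg_avgpool2")]]
arma::mat cg_avgpool2(arma::mat x) {
  const int H = x.n_rows, W = x.n_cols;
  if (H % 2 || W % 2) stop("avgpool needs even spatial dimensions");
  mat y(H / 2, W / 2);
  for (int j = 0; j < W / 2; ++j)
    for (int i = 0; i < H / 2; ++i)
      y(i, j) = 0.25 * (x(2 * i, 2 * j) + x(2 * i + 1, 2 * j) +
                        x(2 * i, 2 * j + 1) + x(2 * i + 1, 2 * j + 1));
  return y;
}
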