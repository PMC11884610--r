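// Low-level numerical kernels for the denoising network.
//
// Feature maps are H x W x C arma::cubes (column-major, matching R arrays);
// convolution weights are R arrays of dim (k, k, Cin, Cout), flattened
// column-major so that reshaping to a (k*k*Cin) x Cout matrix lines up with
// the im2col column ordering used here (di fastest, then dj, then channel).
// All convolutions are stride-1, "same" zero padding, odd kernel size.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static mat im2col_same(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = k / 2;
  mat out(H * W, k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * k * k + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, p - di);
          const int i1 = std::min(H, H + p - di);
          for (int i = i0; i < i1; ++i)
            out(j * H + i, col) = x(i + di - p, sj, c);
        }
      }
    }
  }
  return out;
}

static void col2im_same(const mat& cols, const int k, cube& gx) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices, p = k / 2;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * k * k + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, p - di);
          const int i1 = std::min(H, H + p - di);
          for (int i = i0; i < i1; ++i)
            gx(i + di - p, sj, c) += cols(j * H + i, col);
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
arma::cube conv2d_fw(const arma::cube& x, const arma::vec& w_flat,
                     const arma::vec& b, const int k, const int cout) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const mat Wm(const_cast<double*>(w_flat.memptr()), k * k * Cin, cout,
               false, true);
  mat y;
  if (k == 1) {
    // 1x1 convolution: plain channel mixing, skip im2col
    const mat Xm(const_cast<double*>(x.memptr()), H * W, Cin, false, true);
    y = Xm * Wm;
  } else {
    y = im2col_same(x, k) * Wm;
  }
  y.each_row() += b.t();
  return cube(y.memptr(), H, W, cout);
}

// [[Rcpp::export(name = ".conv2d_bw")]]
Rcpp::List conv2d_bw(const arma::cube& x, const arma::vec& w_flat,
                     const arma::cube& gy, const int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int cout = gy.n_slices;
  const mat Wm(const_cast<double*>(w_flat.memptr()), k * k * Cin, cout,
               false, true);
  const mat GY(const_cast<double*>(gy.memptr()), H * W, cout, false, true);
  vec gb = sum(GY, 0).t();
  mat gw;
  cube gx(H, W, Cin, fill::zeros);
  if (k == 1) {
    const mat Xm(const_cast<double*>(x.memptr()), H * W, Cin, false, true);
    gw = Xm.t() * GY;
    mat GX = GY * Wm.t();
    std::memcpy(gx.memptr(), GX.memptr(), sizeof(double) * H * W * Cin);
  } else {
    const mat X = im2col_same(x, k);
    gw = X.t() * GY;
    const mat Gcols = GY * Wm.t();
    col2im_same(Gcols, k, gx);
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = vec(gw.memptr(),
                                                    gw.n_elem),
                            Rcpp::Named("gb") = gb);
}

// 2x2 max pooling, stride 2. Returns pooled cube and the linear index
// (1-based, within x) of each winner for exact gradient routing.
// [[Rcpp::export(name = ".maxpool2_fw")]]
Rcpp::List maxpool2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int h = H / 2, w = W / 2;
  cube y(h, w, C);
  arma::ucube idx(h, w, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        double best = x(2 * i, 2 * j, c);
        int bi = 2 * i, bj = 2 * j;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; bi = 2 * i + di; bj = 2 * j + dj; }
          }
        y(i, j, c) = best;
        idx(i, j, c) = (uword)(c) * H * W + (uword)bj * H + bi + 1;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
arma::cube maxpool2_bw(const arma::cube& gy, const arma::ucube& idx,
                       const int H, const int W) {
  const int C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  const uword n = gy.n_elem;
  for (uword e = 0; e < n; ++e) gx(idx(e) - 1) += gy(e);
  return gx;
}
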