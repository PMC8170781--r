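// Low-level layer kernels for the small U-net: same-padding k x k
// convolution via im2col + GEMM, 2x2 max pooling with argmax bookkeeping,
// and 2x2 stride-2 transposed convolution. Tensors are (H, W, C) cubes in
// R's column-major layout; weights are (k*k*Cin, Cout) matrices so that a
// forward pass is a single matrix product.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

static mat im2col(const cube &x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, pad = k / 2;
  mat out(H * W, k * k * C);
  for (int c = 0; c < C; ++c) {
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int col = c * k * k + dx * k + dy;
        double *o = out.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dx - pad;
          if (sj < 0 || sj >= W) {
            for (int i = 0; i < H; ++i) o[i + j * H] = 0.0;
            continue;
          }
          const double *xc = x.slice_colptr(c, sj);
          for (int i = 0; i < H; ++i) {
            const int si = i + dy - pad;
            o[i + j * H] = (si < 0 || si >= H) ? 0.0 : xc[si];
          }
        }
      }
    }
  }
  return out;
}

static cube col2im(const mat &cols, int H, int W, int C, int k) {
  const int pad = k / 2;
  cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int col = c * k * k + dx * k + dy;
        const double *o = cols.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dx - pad;
          if (sj < 0 || sj >= W) continue;
          double *xc = x.slice_colptr(c, sj);
          for (int i = 0; i < H; ++i) {
            const int si = i + dy - pad;
            if (si >= 0 && si < H) xc[si] += o[i + j * H];
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export(name = ".conv_fwd")]]
arma::cube conv_fwd(const arma::cube &x, const arma::mat &W,
                    const arma::vec &b, int k) {
  const int H = x.n_rows, Wd = x.n_cols, Cout = W.n_cols;
  mat y = im2col(x, k) * W;
  y.each_row() += b.t();
  cube out(H, Wd, Cout);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(const arma::cube &x, const arma::mat &W, const arma::cube &dy,
              int k) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int Cout = dy.n_slices;
  mat dY(const_cast<double *>(dy.memptr()), H * Wd, Cout, false, true);
  mat xc = im2col(x, k);
  mat dW = xc.t() * dY;
  vec db = arma::sum(dY, 0).t();
  cube dx = col2im(dY * W.t(), H, Wd, C, k);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(const arma::cube &x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int H2 = H / 2, W2 = W / 2;
  cube y(H2, W2, C);
  arma::umat idx(H2 * W2, C); // linear index into the H x W plane
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W2; ++j) {
      for (int i = 0; i < H2; ++i) {
        double best = -arma::datum::inf;
        int bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int si = 2 * i + di, sj = 2 * j + dj;
            const double v = x(si, sj, c);
            if (v > best) {
              best = v;
              bi = si + sj * H;
            }
          }
        }
        y(i, j, c) = best;
        idx(i + j * H2, c) = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
arma::cube maxpool_bwd(const arma::cube &dy, const arma::umat &idx, int H,
                       int W) {
  const int C = dy.n_slices, H2 = dy.n_rows, W2 = dy.n_cols;
  cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double *d = dx.slice_colptr(c, 0);
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i)
        d[idx(i + j * H2, c)] += dy(i, j, c);
  }
  return dx;
}

// Transposed 2x2 stride-2 convolution. W has shape (Cin, 4*Cout), the four
// blocks corresponding to output offsets (dy,dx) = (0,0),(1,0),(0,1),(1,1).
// [[Rcpp::export(name = ".upconv_fwd")]]
arma::cube upconv_fwd(const arma::cube &x, const arma::mat &W,
                      const arma::vec &b) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_cols / 4;
  mat X(const_cast<double *>(x.memptr()), H * Wd, Cin, false, true);
  mat Y = X * W; // (H*W, 4*Cout)
  cube out(2 * H, 2 * Wd, Cout);
  for (int c = 0; c < Cout; ++c) {
    for (int q = 0; q < 4; ++q) {
      const int di = q % 2, dj = q / 2;
      const double *y = Y.colptr(q * Cout + c);
      for (int j = 0; j < Wd; ++j)
        for (int i = 0; i < H; ++i)
          out(2 * i + di, 2 * j + dj, c) = y[i + j * H] + b[c];
    }
  }
  return out;
}

// [[Rcpp::export(name = ".upconv_bwd")]]
List upconv_bwd(const arma::cube &x, const arma::mat &W,
                const arma::cube &dy) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_cols / 4;
  mat X(const_cast<double *>(x.memptr()), H * Wd, Cin, false, true);
  mat dY(H * Wd, 4 * Cout);
  vec db(Cout, arma::fill::zeros);
  for (int c = 0; c < Cout; ++c) {
    for (int q = 0; q < 4; ++q) {
      const int di = q % 2, dj = q / 2;
      double *col = dY.colptr(q * Cout + c);
      for (int j = 0; j < Wd; ++j)
        for (int i = 0; i < H; ++i) {
          const double v = dy(2 * i + di, 2 * j + dj, c);
          col[i + j * H] = v;
          db[c] += v;
        }
    }
  }
  mat dW = X.t() * dY;
  mat dXm = dY * W.t();
  cube dx(H, Wd, Cin);
  std::memcpy(dx.memptr(), dXm.memptr(), sizeof(double) * dXm.n_elem);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
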