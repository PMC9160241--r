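// Low-level kernels for the CPU conv-net engine.
//
// Feature maps are stored as dense matrices of shape (H*W*N) x C with the
// row index flattened column-major as i + H*j + H*W*n (i = row within a
// slice, j = column, n = sample). Convolutions are expressed as im2col
// followed by a BLAS matmul in R; pooling keeps argmax indices so the
// backward pass is a scatter.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::mat& x, int H, int W, int N,
                     int kh, int kw, int pad) {
  const int C = x.n_cols;
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = W + 2 * pad - kw + 1;
  arma::mat out(static_cast<size_t>(Ho) * Wo * N,
                static_cast<size_t>(kh) * kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const size_t col = static_cast<size_t>(c) * kh * kw + kj * kh + ki;
        for (int n = 0; n < N; ++n) {
          const size_t xbase = static_cast<size_t>(n) * H * W;
          const size_t obase = static_cast<size_t>(n) * Ho * Wo;
          for (int jo = 0; jo < Wo; ++jo) {
            const int jx = jo + kj - pad;
            if (jx < 0 || jx >= W) continue;
            const size_t xcol = xbase + static_cast<size_t>(jx) * H;
            const size_t ocol = obase + static_cast<size_t>(jo) * Ho;
            for (int io = 0; io < Ho; ++io) {
              const int ix = io + ki - pad;
              if (ix < 0 || ix >= H) continue;
              out(ocol + io, col) = x(xcol + ix, c);
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_col2im(const arma::mat& dcols, int H, int W, int N,
                     int kh, int kw, int pad, int C) {
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = W + 2 * pad - kw + 1;
  arma::mat dx(static_cast<size_t>(H) * W * N, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const size_t col = static_cast<size_t>(c) * kh * kw + kj * kh + ki;
        for (int n = 0; n < N; ++n) {
          const size_t xbase = static_cast<size_t>(n) * H * W;
          const size_t obase = static_cast<size_t>(n) * Ho * Wo;
          for (int jo = 0; jo < Wo; ++jo) {
            const int jx = jo + kj - pad;
            if (jx < 0 || jx >= W) continue;
            const size_t xcol = xbase + static_cast<size_t>(jx) * H;
            const size_t ocol = obase + static_cast<size_t>(jo) * Ho;
            for (int io = 0; io < Ho; ++io) {
              const int ix = io + ki - pad;
              if (ix < 0 || ix >= H) continue;
              dx(xcol + ix, c) += dcols(ocol + io, col);
            }
          }
        }
      }
    }
  }
  return dx;
}

// 2x2 max pooling with stride 2; H and W must be even.
// [[Rcpp::export]]
List cpp_maxpool2(const arma::mat& x, int H, int W, int N) {
  const int C = x.n_cols;
  const int Ho = H / 2, Wo = W / 2;
  arma::mat y(static_cast<size_t>(Ho) * Wo * N, C);
  arma::umat idx(static_cast<size_t>(Ho) * Wo * N, C);
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const size_t xbase = static_cast<size_t>(n) * H * W;
      const size_t obase = static_cast<size_t>(n) * Ho * Wo;
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          const int i0 = 2 * io, j0 = 2 * jo;
          size_t best = xbase + static_cast<size_t>(j0) * H + i0;
          double bv = x(best, c);
          const size_t cand[3] = {
            xbase + static_cast<size_t>(j0) * H + i0 + 1,
            xbase + static_cast<size_t>(j0 + 1) * H + i0,
            xbase + static_cast<size_t>(j0 + 1) * H + i0 + 1};
          for (int k = 0; k < 3; ++k) {
            const double v = x(cand[k], c);
            if (v > bv) { bv = v; best = cand[k]; }
          }
          y(obase + static_cast<size_t>(jo) * Ho + io, c) = bv;
          idx(obase + static_cast<size_t>(jo) * Ho + io, c) = best + 1; // 1-based
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool2_backward(const arma::mat& dy, const arma::umat& idx,
                                int nrow_x) {
  const int C = dy.n_cols;
  arma::mat dx(nrow_x, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (size_t r = 0; r < dy.n_rows; ++r)
      dx(idx(r, c) - 1, c) += dy(r, c);
  return dx;
}

// Flood fill over 6-connected 3-D components of a logical mask, returning
// integer component labels (0 outside the mask).
// [[Rcpp::export]]
IntegerVector cpp_label_components_3d(const LogicalVector& mask,
                                      int nx, int ny, int nz) {
  const size_t n = static_cast<size_t>(nx) * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<size_t> stack;
  int current = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++current;
    stack.push_back(s);
    lab[s] = current;
    while (!stack.empty()) {
      const size_t v = stack.back();
      stack.pop_back();
      const int i = v % nx;
      const int j = (v / nx) % ny;
      const int k = v / (static_cast<size_t>(nx) * ny);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        const int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        const size_t w = static_cast<size_t>(kk) * nx * ny +
          static_cast<size_t>(jj) * nx + ii;
        if (mask[w] && lab[w] == 0) { lab[w] = current; stack.push_back(w); }
      }
    }
  }
  return lab;
}
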