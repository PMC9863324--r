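// Low-level numerical kernels for the segmentation network.
// Tensors are column-major arrays with dimensions [H, W, C], matching R's
// array layout, so views can be taken without copying. Convolutions are
// same-padded, stride 1, and implemented as im2col followed by a single
// BLAS matrix multiply; gradients reuse the same column matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Build the [H*W, k*k*C] patch matrix for a same-padded k x k convolution.
static mat im2col(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = (k - 1) / 2;
  mat cols(H * W, k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col_idx = c * k * k + kj * k + ki;
        const int di = ki - p, dj = kj - p;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j) {
          const double* src = &x(i0 + di, j + dj, c);
          double* dst = cols.colptr(col_idx) + (size_t)j * H + i0;
          std::copy(src, src + (i1 - i0), dst);
        }
      }
    }
  }
  return cols;
}

// Scatter-add the column matrix back to image space (adjoint of im2col).
static cube col2im(const mat& cols, const int H, const int W, const int C,
                   const int k) {
  const int p = (k - 1) / 2;
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col_idx = c * k * k + kj * k + ki;
        const int di = ki - p, dj = kj - p;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j) {
          const double* src = cols.colptr(col_idx) + (size_t)j * H + i0;
          double* dst = &x(i0 + di, j + dj, c);
          for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export(name = ".conv2d_fw")]]
arma::cube conv2d_fw(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b, const int k) {
  // w: [k*k*Cin, Cout]
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  mat out = im2col(x, k) * w;
  out.each_row() += b.t();
  return cube(out.memptr(), H, W, Cout);
}

// [[Rcpp::export(name = ".conv2d_bw")]]
Rcpp::List conv2d_bw(const arma::cube& x, const arma::mat& w,
                     const arma::cube& gout, const int k,
                     const bool need_gx = true) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = gout.n_slices;
  const mat cols = im2col(x, k);
  const mat gout_m(const_cast<double*>(gout.memptr()), (size_t)H * W, Cout,
                   false, true);
  mat gw = cols.t() * gout_m;
  vec gb = sum(gout_m, 0).t();
  Rcpp::List res = Rcpp::List::create(Rcpp::Named("gw") = gw,
                                      Rcpp::Named("gb") = gb);
  if (need_gx) {
    mat gcols = gout_m * w.t();
    res["gx"] = col2im(gcols, H, W, Cin, k);
  }
  return res;
}

// [[Rcpp::export(name = ".maxpool2_fw")]]
Rcpp::List maxpool2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube out(Ho, Wo, C);
  ucube idx(Ho, Wo, C);  // linear index into the input slice
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf;
        uword bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int ii = 2 * i + di, jj = 2 * j + dj;
            const double v = x(ii, jj, c);
            if (v > best) { best = v; bi = (uword)jj * H + ii; }
          }
        }
        out(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
arma::cube maxpool2_bw(const arma::cube& gout, const arma::ucube& idx,
                       const int H, const int W) {
  const int C = gout.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* slice = gx.slice_memptr(c);
    for (uword q = 0; q < gout.n_rows * gout.n_cols; ++q)
      slice[idx.slice(c)(q)] += gout.slice(c)(q);
  }
  return gx;
}

// [[Rcpp::export(name = ".upsample2_fw")]]
arma::cube upsample2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j)
      for (int i = 0; i < 2 * H; ++i)
        out(i, j, c) = x(i / 2, j / 2, c);
  return out;
}

// [[Rcpp::export(name = ".upsample2_bw")]]
arma::cube upsample2_bw(const arma::cube& gout) {
  const int H = gout.n_rows / 2, W = gout.n_cols / 2, C = gout.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j)
      for (int i = 0; i < 2 * H; ++i)
        gx(i / 2, j / 2, c) += gout(i, j, c);
  return gx;
}

// 4-connected component labelling of a binary matrix (iterative flood fill).
// [[Rcpp::export(name = ".label_components")]]
Rcpp::IntegerMatrix label_components(const Rcpp::IntegerMatrix& m) {
  const int H = m.nrow(), W = m.ncol();
  Rcpp::IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (m(i, j) != 0 && lab(i, j) == 0) {
        ++next;
        stack.push_back(j * H + i);
        lab(i, j) = next;
        while (!stack.empty()) {
          const int q = stack.back();
          stack.pop_back();
          const int qi = q % H, qj = q / H;
          const int ni[4] = {qi - 1, qi + 1, qi, qi};
          const int nj[4] = {qj, qj, qj - 1, qj + 1};
          for (int t = 0; t < 4; ++t) {
            if (ni[t] >= 0 && ni[t] < H && nj[t] >= 0 && nj[t] < W &&
                m(ni[t], nj[t]) != 0 && lab(ni[t], nj[t]) == 0) {
              lab(ni[t], nj[t]) = next;
              stack.push_back(nj[t] * H + ni[t]);
            }
          }
        }
      }
    }
  }
  return lab;
}
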