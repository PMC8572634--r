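#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are [H, W, C] column-major arrays (H fastest).
// im2col lowers a "same"-padded dilated 3x3 (or kxk) neighbourhood gather to a
// [k*k*C, H*W] matrix so the convolution itself is one BLAS matmul in R.
// Row order: channel-major, then kernel column, then kernel row; this order
// must match the weight matrix layout on the R side.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int k, int dil) {
  const int pad = dil * (k - 1) / 2;
  NumericMatrix out(k * k * C, H * W);
  const double* px = x.begin();
  double* po = out.begin();
  const int nrow = k * k * C;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const int col = i + H * j;
      double* pc = po + (R_xlen_t)col * nrow;
      int row = 0;
      for (int c = 0; c < C; ++c) {
        const double* pxc = px + (R_xlen_t)H * W * c;
        for (int kj = 0; kj < k; ++kj) {
          const int jj = j + dil * kj - pad;
          for (int ki = 0; ki < k; ++ki, ++row) {
            const int ii = i + dil * ki - pad;
            pc[row] = (ii >= 0 && ii < H && jj >= 0 && jj < W)
                        ? pxc[ii + H * jj] : 0.0;
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add column gradients back onto the input grid.

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int k, int dil) {
  const int pad = dil * (k - 1) / 2;
  NumericVector out((R_xlen_t)H * W * C);
  double* po = out.begin();
  const double* pc0 = cols.begin();
  const int nrow = k * k * C;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const int col = i + H * j;
      const double* pc = pc0 + (R_xlen_t)col * nrow;
      int row = 0;
      for (int c = 0; c < C; ++c) {
        double* poc = po + (R_xlen_t)H * W * c;
        for (int kj = 0; kj < k; ++kj) {
          const int jj = j + dil * kj - pad;
          for (int ki = 0; ki < k; ++ki, ++row) {
            const int ii = i + dil * ki - pad;
            if (ii >= 0 && ii < H && jj >= 0 && jj < W)
              poc[ii + H * jj] += pc[row];
          }
        }
      }
    }
  }
  return out;
}

// 2x2 max pooling with stride 2; returns pooled map and 0-based argmax flat
// indices into the input for the backward scatter.

// [[Rcpp::export]]
List maxpool2_cpp(NumericVector x, int H, int W, int C) {
  const int H2 = H / 2, W2 = W / 2;
  NumericVector out((R_xlen_t)H2 * W2 * C);
  IntegerVector arg((R_xlen_t)H2 * W2 * C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    const R_xlen_t oin = (R_xlen_t)H * W * c;
    const R_xlen_t oout = (R_xlen_t)H2 * W2 * c;
    for (int j = 0; j < W2; ++j) {
      for (int i = 0; i < H2; ++i) {
        int best = -1;
        double bv = -1e300;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int idx = (2 * i + di) + H * (2 * j + dj);
            const double v = px[oin + idx];
            if (v > bv) { bv = v; best = idx; }
          }
        }
        out[oout + i + H2 * j] = bv;
        arg[oout + i + H2 * j] = (int)(oin + best);
      }
    }
  }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_back_cpp(NumericVector g, IntegerVector arg, R_xlen_t n_in) {
  NumericVector out(n_in);
  for (R_xlen_t t = 0; t < g.size(); ++t) out[arg[t]] += g[t];
  return out;
}

// Factor-2 bilinear upsampling (half-pixel centre convention) and its adjoint.

static inline void up2_coeff(int i, int H, int& i0, int& i1, double& w) {
  double src = (i + 0.5) / 2.0 - 0.5;
  if (src < 0) src = 0;
  if (src > H - 1) src = H - 1;
  i0 = (int)std::floor(src);
  i1 = i0 + 1 < H ? i0 + 1 : i0;
  w = src - i0;
}

// [[Rcpp::export]]
NumericVector upsample2_cpp(NumericVector x, int H, int W, int C) {
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector out((R_xlen_t)H2 * W2 * C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    const R_xlen_t oin = (R_xlen_t)H * W * c;
    const R_xlen_t oout = (R_xlen_t)H2 * W2 * c;
    for (int j = 0; j < W2; ++j) {
      int j0, j1; double wj;
      up2_coeff(j, W, j0, j1, wj);
      for (int i = 0; i < H2; ++i) {
        int i0, i1; double wi;
        up2_coeff(i, H, i0, i1, wi);
        out[oout + i + H2 * j] =
          (1 - wi) * (1 - wj) * px[oin + i0 + H * j0] +
          wi * (1 - wj)       * px[oin + i1 + H * j0] +
          (1 - wi) * wj       * px[oin + i0 + H * j1] +
          wi * wj             * px[oin + i1 + H * j1];
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector upsample2_back_cpp(NumericVector g, int H, int W, int C) {
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector out((R_xlen_t)H * W * C);
  const double* pg = g.begin();
  for (int c = 0; c < C; ++c) {
    const R_xlen_t oin = (R_xlen_t)H * W * c;
    const R_xlen_t oout = (R_xlen_t)H2 * W2 * c;
    for (int j = 0; j < W2; ++j) {
      int j0, j1; double wj;
      up2_coeff(j, W, j0, j1, wj);
      for (int i = 0; i < H2; ++i) {
        int i0, i1; double wi;
        up2_coeff(i, H, i0, i1, wi);
        const double gv = pg[oout + i + H2 * j];
        out[oin + i0 + H * j0] += (1 - wi) * (1 - wj) * gv;
        out[oin + i1 + H * j0] += wi * (1 - wj) * gv;
        out[oin + i0 + H * j1] += (1 - wi) * wj * gv;
        out[oin + i1 + H * j1] += wi * wj * gv;
      }
    }
  }
  return out;
}
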