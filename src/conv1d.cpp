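// 1D convolution kernels (im2col gather + GEMM + col2im scatter).
// The R layer framework calls these for the forward and backward passes;
// gradients are validated against finite differences in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// x: cube (C, L, B); W: mat (cout, C*k); b: vec (cout)
// returns y = cube (cout, Lout, B) and the im2col matrix for backward
// [[Rcpp::export]]
List conv1d_fw_cpp(const arma::cube& x, const arma::mat& W,
                   const arma::vec& b, const int k, const int stride,
                   const int pad) {
  const int C = x.n_rows, L = x.n_cols, B = x.n_slices;
  const int Lp = L + 2 * pad;
  const int Lout = (Lp - k) / stride + 1;
  const int cout = W.n_rows;
  arma::mat xcol(C * k, (arma::uword)Lout * B, arma::fill::zeros);
  for (int bb = 0; bb < B; ++bb) {
    for (int p = 0; p < Lout; ++p) {
      double* dst = xcol.colptr((arma::uword)bb * Lout + p);
      for (int kk = 0; kk < k; ++kk) {
        const int l = p * stride + kk - pad;
        if (l >= 0 && l < L) {
          std::memcpy(dst + (arma::uword)kk * C, x.slice_colptr(bb, l),
                      C * sizeof(double));
        }
      }
    }
  }
  arma::mat y = W * xcol;
  y.each_col() += b;
  arma::cube yc(y.memptr(), cout, Lout, B);
  return List::create(_["y"] = yc, _["xcol"] = xcol);
}

// dy: cube (cout, Lout, B); returns dx, dW, db
// [[Rcpp::export]]
List conv1d_bw_cpp(const arma::cube& dy, const arma::mat& W,
                   const arma::mat& xcol, const int C, const int L,
                   const int k, const int stride, const int pad) {
  const int cout = dy.n_rows, Lout = dy.n_cols, B = dy.n_slices;
  const arma::mat dym(const_cast<double*>(dy.memptr()), cout,
                      (arma::uword)Lout * B, false, true);
  arma::mat dW = dym * xcol.t();
  arma::vec db = arma::sum(dym, 1);
  arma::mat dxcol = W.t() * dym;
  arma::cube dx(C, L, B, arma::fill::zeros);
  for (int bb = 0; bb < B; ++bb) {
    for (int p = 0; p < Lout; ++p) {
      const double* src = dxcol.colptr((arma::uword)bb * Lout + p);
      for (int kk = 0; kk < k; ++kk) {
        const int l = p * stride + kk - pad;
        if (l >= 0 && l < L) {
          double* dst = dx.slice_colptr(bb, l);
          const double* s = src + (arma::uword)kk * C;
          for (int c = 0; c < C; ++c) dst[c] += s[c];
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// channel concatenation and split, avoiding R's slow 3D subsetting
// [[Rcpp::export]]
arma::cube cat_channels_cpp(const arma::cube& a, const arma::cube& b) {
  const int Ca = a.n_rows, Cb = b.n_rows, L = a.n_cols, B = a.n_slices;
  arma::cube out(Ca + Cb, L, B);
  for (int bb = 0; bb < B; ++bb) {
    for (int l = 0; l < L; ++l) {
      std::memcpy(out.slice_colptr(bb, l), a.slice_colptr(bb, l),
                  Ca * sizeof(double));
      std::memcpy(out.slice_colptr(bb, l) + Ca, b.slice_colptr(bb, l),
                  Cb * sizeof(double));
    }
  }
  return out;
}

// [[Rcpp::export]]
List split_channels_cpp(const arma::cube& d, const int n_first) {
  const int C = d.n_rows, L = d.n_cols, B = d.n_slices;
  const int C2 = C - n_first;
  arma::cube a(n_first, L, B), b(C2, L, B);
  for (int bb = 0; bb < B; ++bb) {
    for (int l = 0; l < L; ++l) {
      std::memcpy(a.slice_colptr(bb, l), d.slice_colptr(bb, l),
                  n_first * sizeof(double));
      std::memcpy(b.slice_colptr(bb, l), d.slice_colptr(bb, l) + n_first,
                  C2 * sizeof(double));
    }
  }
  return List::create(_["first"] = a, _["second"] = b);
}

// group normalization over (C, L, B): statistics per (group, sample) cell
// [[Rcpp::export]]
List groupnorm_fw_cpp(const arma::cube& x, const arma::vec& gamma,
                      const arma::vec& beta, const int groups,
                      const double eps) {
  const int C = x.n_rows, L = x.n_cols, B = x.n_slices;
  const int Cg = C / groups;
  arma::cube xhat(C, L, B), y(C, L, B);
  arma::mat inv(groups, B);
  for (int bb = 0; bb < B; ++bb) {
    for (int g = 0; g < groups; ++g) {
      const int c0 = g * Cg;
      double s = 0.0, s2 = 0.0;
      for (int l = 0; l < L; ++l) {
        const double* xc = x.slice_colptr(bb, l) + c0;
        for (int c = 0; c < Cg; ++c) { s += xc[c]; s2 += xc[c] * xc[c]; }
      }
      const double n = (double)Cg * L;
      const double mu = s / n;
      const double v = s2 / n - mu * mu;
      const double iv = 1.0 / std::sqrt(v + eps);
      inv(g, bb) = iv;
      for (int l = 0; l < L; ++l) {
        const double* xc = x.slice_colptr(bb, l) + c0;
        double* xh = xhat.slice_colptr(bb, l) + c0;
        double* yy = y.slice_colptr(bb, l) + c0;
        for (int c = 0; c < Cg; ++c) {
          xh[c] = (xc[c] - mu) * iv;
          yy[c] = gamma[c0 + c] * xh[c] + beta[c0 + c];
        }
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv"] = inv);
}

// [[Rcpp::export]]
List groupnorm_bw_cpp(const arma::cube& dy, const arma::cube& xhat,
                      const arma::mat& inv, const arma::vec& gamma,
                      const int groups) {
  const int C = dy.n_rows, L = dy.n_cols, B = dy.n_slices;
  const int Cg = C / groups;
  arma::cube dx(C, L, B);
  arma::vec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
  for (int bb = 0; bb < B; ++bb) {
    for (int g = 0; g < groups; ++g) {
      const int c0 = g * Cg;
      double s1 = 0.0, s2 = 0.0;
      for (int l = 0; l < L; ++l) {
        const double* dyc = dy.slice_colptr(bb, l) + c0;
        const double* xh = xhat.slice_colptr(bb, l) + c0;
        for (int c = 0; c < Cg; ++c) {
          const double dxh = dyc[c] * gamma[c0 + c];
          s1 += dxh;
          s2 += dxh * xh[c];
          dgamma[c0 + c] += dyc[c] * xh[c];
          dbeta[c0 + c] += dyc[c];
        }
      }
      const double n = (double)Cg * L;
      const double m1 = s1 / n, m2 = s2 / n;
      const double iv = inv(g, bb);
      for (int l = 0; l < L; ++l) {
        const double* dyc = dy.slice_colptr(bb, l) + c0;
        const double* xh = xhat.slice_colptr(bb, l) + c0;
        double* dxc = dx.slice_colptr(bb, l) + c0;
        for (int c = 0; c < Cg; ++c) {
          const double dxh = dyc[c] * gamma[c0 + c];
          dxc[c] = (dxh - m1 - xh[c] * m2) * iv;
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
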