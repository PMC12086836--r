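// Convolution kernels for the residual classifier.
//
// Layout convention (column-major, fixed rank 3 with singleton spatial dims
// for 1D/2D inputs): X has dim (d1, d2, d3, C, N). Weights are stored as a
// (C_out, C*k1*k2*k3) matrix whose row index runs q1 fastest, then q2, q3,
// then input channel. Convolutions are implemented by im2col + GEMM; the
// column matrix built in the training forward pass is cached and reused in
// the backward pass.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_len(int d, int k, int s, int p) {
  return (d + 2 * p - k) / s + 1;
}

static void im2col(const double* x, const int d[3], int C, int N,
                   const int k[3], const int s[3], const int p[3],
                   const int o[3], arma::mat& cols) {
  const int rows = C * k[0] * k[1] * k[2];
  const long ncol = (long)o[0] * o[1] * o[2] * N;
  cols.set_size(rows, ncol);
  if (d[1] == 1 && d[2] == 1 && k[1] == 1 && k[2] == 1) {
    // 1-D fast path: columns indexed (o1, n), rows (q1, c)
    for (int n = 0; n < N; ++n) {
      for (int o1 = 0; o1 < o[0]; ++o1) {
        double* dst = cols.colptr(o1 + (long)o[0] * n);
        const int start = o1 * s[0] - p[0];
        for (int c = 0; c < C; ++c) {
          const double* src = x + (long)d[0] * (c + (long)C * n);
          double* dc = dst + k[0] * c;
          for (int q1 = 0; q1 < k[0]; ++q1) {
            const int i1 = start + q1;
            dc[q1] = (i1 >= 0 && i1 < d[0]) ? src[i1] : 0.0;
          }
        }
      }
    }
    return;
  }
  cols.zeros();
  for (int n = 0; n < N; ++n) {
    for (int o3 = 0; o3 < o[2]; ++o3) {
      for (int o2 = 0; o2 < o[1]; ++o2) {
        for (int o1 = 0; o1 < o[0]; ++o1) {
          const long col = o1 + (long)o[0] * (o2 + (long)o[1] * (o3 + (long)o[2] * n));
          double* dst = cols.colptr(col);
          for (int c = 0; c < C; ++c) {
            for (int q3 = 0; q3 < k[2]; ++q3) {
              const int i3 = o3 * s[2] - p[2] + q3;
              if (i3 < 0 || i3 >= d[2]) continue;
              for (int q2 = 0; q2 < k[1]; ++q2) {
                const int i2 = o2 * s[1] - p[1] + q2;
                if (i2 < 0 || i2 >= d[1]) continue;
                const long base = (long)d[0] * (i2 + (long)d[1] * (i3 + (long)d[2] * (c + (long)C * n)));
                const int  rbase = k[0] * (q2 + k[1] * (q3 + k[2] * c));
                for (int q1 = 0; q1 < k[0]; ++q1) {
                  const int i1 = o1 * s[0] - p[0] + q1;
                  if (i1 < 0 || i1 >= d[0]) continue;
                  dst[q1 + rbase] = x[i1 + base];
                }
              }
            }
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& cols, const int d[3], int C, int N,
                   const int k[3], const int s[3], const int p[3],
                   const int o[3], double* x) {
  std::fill(x, x + (long)d[0] * d[1] * d[2] * C * N, 0.0);
  if (d[1] == 1 && d[2] == 1 && k[1] == 1 && k[2] == 1) {
    for (int n = 0; n < N; ++n) {
      for (int o1 = 0; o1 < o[0]; ++o1) {
        const double* src = cols.colptr(o1 + (long)o[0] * n);
        const int start = o1 * s[0] - p[0];
        for (int c = 0; c < C; ++c) {
          double* dc = x + (long)d[0] * (c + (long)C * n);
          const double* sc = src + k[0] * c;
          for (int q1 = 0; q1 < k[0]; ++q1) {
            const int i1 = start + q1;
            if (i1 >= 0 && i1 < d[0]) dc[i1] += sc[q1];
          }
        }
      }
    }
    return;
  }
  for (int n = 0; n < N; ++n) {
    for (int o3 = 0; o3 < o[2]; ++o3) {
      for (int o2 = 0; o2 < o[1]; ++o2) {
        for (int o1 = 0; o1 < o[0]; ++o1) {
          const long col = o1 + (long)o[0] * (o2 + (long)o[1] * (o3 + (long)o[2] * n));
          const double* src = cols.colptr(col);
          for (int c = 0; c < C; ++c) {
            for (int q3 = 0; q3 < k[2]; ++q3) {
              const int i3 = o3 * s[2] - p[2] + q3;
              if (i3 < 0 || i3 >= d[2]) continue;
              for (int q2 = 0; q2 < k[1]; ++q2) {
                const int i2 = o2 * s[1] - p[1] + q2;
                if (i2 < 0 || i2 >= d[1]) continue;
                const long base = (long)d[0] * (i2 + (long)d[1] * (i3 + (long)d[2] * (c + (long)C * n)));
                const int  rbase = k[0] * (q2 + k[1] * (q3 + k[2] * c));
                for (int q1 = 0; q1 < k[0]; ++q1) {
                  const int i1 = o1 * s[0] - p[0] + q1;
                  if (i1 < 0 || i1 >= d[0]) continue;
                  x[i1 + base] += src[q1 + rbase];
                }
              }
            }
          }
        }
      }
    }
  }
}

static void get3(const IntegerVector& v, int out[3]) {
  for (int i = 0; i < 3; ++i) out[i] = v[i];
}

// [[Rcpp::export(name = ".conv_forward")]]
SEXP conv_forward_cpp(NumericVector X, NumericMatrix W, NumericVector b,
                      IntegerVector kernel, IntegerVector stride,
                      IntegerVector pad, bool keep_cols = false) {
  IntegerVector xd = X.attr("dim");
  const int d[3] = { xd[0], xd[1], xd[2] };
  const int C = xd[3], N = xd[4];
  int k[3], s[3], p[3];
  get3(kernel, k); get3(stride, s); get3(pad, p);
  const int o[3] = { out_len(d[0], k[0], s[0], p[0]),
                     out_len(d[1], k[1], s[1], p[1]),
                     out_len(d[2], k[2], s[2], p[2]) };
  const int Cout = W.nrow();
  arma::mat cols;
  im2col(X.begin(), d, C, N, k, s, p, o, cols);
  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  arma::mat Y = Wm * cols;                        // (Cout, O1*O2*O3*N)
  NumericVector out((long)o[0] * o[1] * o[2] * Cout * N);
  out.attr("dim") = IntegerVector::create(o[0], o[1], o[2], Cout, N);
  double* y = out.begin();
  const long spat = (long)o[0] * o[1] * o[2];
  for (int n = 0; n < N; ++n)
    for (long sp = 0; sp < spat; ++sp) {
      const long col = sp + spat * n;
      const double* src = Y.colptr(col);
      for (int co = 0; co < Cout; ++co)
        y[sp + spat * (co + (long)Cout * n)] = src[co] + b[co];
    }
  if (!keep_cols) return out;
  NumericMatrix colsr(cols.n_rows, cols.n_cols);
  std::copy(cols.begin(), cols.end(), colsr.begin());
  return List::create(_["y"] = out, _["cols"] = colsr);
}

// [[Rcpp::export(name = ".conv_backward")]]
List conv_backward_cpp(NumericVector X, NumericMatrix W, NumericVector dY,
                       IntegerVector kernel, IntegerVector stride,
                       IntegerVector pad, Nullable<NumericMatrix> cols_cache = R_NilValue,
                       bool need_dx = true) {
  IntegerVector xd = X.attr("dim");
  const int d[3] = { xd[0], xd[1], xd[2] };
  const int C = xd[3], N = xd[4];
  int k[3], s[3], p[3];
  get3(kernel, k); get3(stride, s); get3(pad, p);
  const int o[3] = { out_len(d[0], k[0], s[0], p[0]),
                     out_len(d[1], k[1], s[1], p[1]),
                     out_len(d[2], k[2], s[2], p[2]) };
  const int Cout = W.nrow();
  const long spat = (long)o[0] * o[1] * o[2];
  const long ncol = spat * N;

  // repack dY (O1,O2,O3,Cout,N) into (Cout, ncol)
  arma::mat dYm(Cout, ncol);
  const double* dy = dY.begin();
  for (int n = 0; n < N; ++n)
    for (long sp = 0; sp < spat; ++sp) {
      double* dst = dYm.colptr(sp + spat * n);
      for (int co = 0; co < Cout; ++co)
        dst[co] = dy[sp + spat * (co + (long)Cout * n)];
    }

  arma::mat dW;
  arma::vec db = arma::sum(dYm, 1);
  if (cols_cache.isNotNull()) {
    NumericMatrix cc(cols_cache);
    arma::mat cols(cc.begin(), cc.nrow(), cc.ncol(), false);
    dW = dYm * cols.t();
  } else {
    arma::mat cols;
    im2col(X.begin(), d, C, N, k, s, p, o, cols);
    dW = dYm * cols.t();
  }

  NumericMatrix dWr(dW.n_rows, dW.n_cols);
  std::copy(dW.begin(), dW.end(), dWr.begin());
  NumericVector dbr(db.begin(), db.end());

  if (!need_dx)
    return List::create(_["dX"] = R_NilValue, _["dW"] = dWr, _["db"] = dbr);

  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  arma::mat dcols = Wm.t() * dYm;
  NumericVector dX((long)d[0] * d[1] * d[2] * C * N);
  dX.attr("dim") = xd;
  col2im(dcols, d, C, N, k, s, p, o, dX.begin());
  return List::create(_["dX"] = dX, _["dW"] = dWr, _["db"] = dbr);
}
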