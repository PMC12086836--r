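// Batch-norm and ReLU kernels. The tensor is passed as a flat vector laid
// out (spat, C, N) column-major: element (s, c, n) = x[s + spat*(c + C*n)].

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".bn_stats")]]
List bn_stats_cpp(NumericVector x, int spat, int C, int N) {
  NumericVector mean(C), var(C);
  const double* p = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* col = p + (long)spat * (c + (long)C * n);
      double s = 0, s2 = 0;
      for (int i = 0; i < spat; ++i) { s += col[i]; s2 += col[i] * col[i]; }
      mean[c] += s; var[c] += s2;
    }
  const double m = (double)spat * N;
  for (int c = 0; c < C; ++c) {
    mean[c] /= m;
    var[c] = std::max(var[c] / m - mean[c] * mean[c], 0.0);
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export(name = ".bn_fwd")]]
NumericVector bn_fwd_cpp(NumericVector x, int spat, int C, int N,
                         NumericVector scale, NumericVector shift) {
  NumericVector y(x.size());
  const double* p = x.begin(); double* q = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const long off = (long)spat * (c + (long)C * n);
      const double a = scale[c], b = shift[c];
      for (int i = 0; i < spat; ++i) q[off + i] = a * p[off + i] + b;
    }
  return y;
}

// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd_cpp(NumericVector x, NumericVector dy, int spat, int C, int N,
                NumericVector gamma, NumericVector mu, NumericVector invstd) {
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  const double m = (double)spat * N;
  // pass 1: per-channel sums of dy and dy * xhat
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const long off = (long)spat * (c + (long)C * n);
      const double* px = x.begin() + off; const double* pd = dy.begin() + off;
      double s1 = 0, s2 = 0;
      for (int i = 0; i < spat; ++i) {
        const double xh = (px[i] - mu[c]) * invstd[c];
        s1 += pd[i]; s2 += pd[i] * xh;
      }
      dbeta[c] += s1; dgamma[c] += s2;
    }
  // pass 2: dx = gamma*invstd * (dy - dbeta/m - xhat * dgamma/m)
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const long off = (long)spat * (c + (long)C * n);
      const double* px = x.begin() + off; const double* pd = dy.begin() + off;
      double* pq = dx.begin() + off;
      const double g = gamma[c] * invstd[c];
      const double t1 = dbeta[c] / m, t2 = dgamma[c] / m;
      for (int i = 0; i < spat; ++i) {
        const double xh = (px[i] - mu[c]) * invstd[c];
        pq[i] = g * (pd[i] - t1 - xh * t2);
      }
    }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".relu_fwd")]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector y(x.size());
  for (long i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0;
  return y;
}

// [[Rcpp::export(name = ".relu_bwd")]]
NumericVector relu_bwd_cpp(NumericVector dout, NumericVector y) {
  NumericVector dx(dout.size());
  for (long i = 0; i < dout.size(); ++i) dx[i] = y[i] > 0 ? dout[i] : 0;
  return dx;
}
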