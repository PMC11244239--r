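// Numerical kernels: 3x3 same-padding convolution (forward/backward via
// im2col + BLAS), 2x2 max pooling with argmax routing, and the O(K^2)
// Sample Entropy template count. Tensors arrive as R arrays in column-major
// [H, W, C, N] layout; convolution weights as [3, 3, Cin, Cout].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat im2col3x3(const double* x, int H, int W, int C) {
  // rows: H*W spatial positions (h fastest), cols: 9*C (kh fastest, then
  // kw, then c) -- matches the R weight array layout [3,3,Cin,Cout]
  arma::mat col(H * W, 9 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        int k = kh + 3 * kw + 9 * c;
        double* dst = col.colptr(k);
        int dh = kh - 1, dw = kw - 1;
        for (int w = 0; w < W; ++w) {
          int sw = w + dw;
          if (sw < 0 || sw >= W) continue;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          const double* src = xc + (size_t)H * sw;
          double* d = dst + (size_t)H * w;
          for (int h = h0; h < h1; ++h) d[h] = src[h + dh];
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export(name = ".conv3x3_forward")]]
NumericVector conv3x3_forward(NumericVector x, NumericVector w,
                              NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3], Co = wd[3];
  arma::mat Wm(w.begin(), 9 * C, Co, false);
  NumericVector out((size_t)H * W * Co * N);
  out.attr("dim") = IntegerVector::create(H, W, Co, N);
  arma::rowvec bv(b.begin(), Co);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col3x3(x.begin() + (size_t)H * W * C * n, H, W, C);
    arma::mat y = col * Wm;          // [H*W, Co]
    y.each_row() += bv;
    std::copy(y.begin(), y.end(), out.begin() + (size_t)H * W * Co * n);
  }
  return out;
}

// [[Rcpp::export(name = ".conv3x3_backward")]]
List conv3x3_backward(NumericVector x, NumericVector w, NumericVector dy,
                      bool need_dx) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3], Co = wd[3];
  arma::mat Wm(w.begin(), 9 * C, Co, false);
  arma::mat dW(9 * C, Co, arma::fill::zeros);
  arma::rowvec db(Co, arma::fill::zeros);
  NumericVector dx(need_dx ? (size_t)H * W * C * N : 0);
  if (need_dx) dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col3x3(x.begin() + (size_t)H * W * C * n, H, W, C);
    arma::mat dYn(dy.begin() + (size_t)H * W * Co * n, H * W, Co, false);
    dW += col.t() * dYn;
    db += arma::sum(dYn, 0);
    if (!need_dx) continue;
    arma::mat dcol = dYn * Wm.t();   // [H*W, 9*C]
    // col2im: scatter-add back into dx
    double* dxn = dx.begin() + (size_t)H * W * C * n;
    for (int c = 0; c < C; ++c) {
      double* dxc = dxn + (size_t)H * W * c;
      for (int kw = 0; kw < 3; ++kw) {
        for (int kh = 0; kh < 3; ++kh) {
          int k = kh + 3 * kw + 9 * c;
          const double* src = dcol.colptr(k);
          int dh = kh - 1, dw = kw - 1;
          for (int w2 = 0; w2 < W; ++w2) {
            int sw = w2 + dw;
            if (sw < 0 || sw >= W) continue;
            int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
            double* d = dxc + (size_t)H * sw;
            const double* s = src + (size_t)H * w2;
            for (int h = h0; h < h1; ++h) d[h + dh] += s[h];
          }
        }
      }
    }
  }
  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = IntegerVector::create(3, 3, C, Co);
  return List::create(_["dW"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()),
                      _["dx"] = dx);
}

// [[Rcpp::export(name = ".maxpool2_forward")]]
List maxpool2_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((size_t)Ho * Wo * C * N);  // linear index into H*W plane
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yp = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      int* ip = idx.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          int best = 2 * h + H * (2 * w);
          double bv = xp[best];
          int cand[3] = {2 * h + 1 + H * (2 * w), 2 * h + H * (2 * w + 1),
                         2 * h + 1 + H * (2 * w + 1)};
          for (int t = 0; t < 3; ++t)
            if (xp[cand[t]] > bv) { bv = xp[cand[t]]; best = cand[t]; }
          yp[h + Ho * w] = bv;
          ip[h + Ho * w] = best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
NumericVector maxpool2_backward(NumericVector dy, IntegerVector idx,
                                IntegerVector in_dim) {
  int H = in_dim[0], W = in_dim[1], C = in_dim[2], N = in_dim[3];
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* dyp = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      const int* ip = idx.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* dxp = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int k = 0; k < Ho * Wo; ++k) dxp[ip[k]] += dyp[k];
    }
  return dx;
}

// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  // counts of template pairs (i < j) matching under Chebyshev distance at
  // lengths m and m+1; templates i = 0..K-m-1 so the m+1 extension exists
  int K = x.size();
  int n = K - m;          // number of templates
  long long B = 0, A = 0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double t = std::fabs(x[i + k] - x[j + k]);
        if (t > d) d = t;
      }
      if (d < r) {
        ++B;
        double t = std::fabs(x[i + m] - x[j + m]);
        if (std::max(d, t) < r) ++A;
      }
    }
  return NumericVector::create((double)A, (double)B);
}

// in-place rectifiers: the caller owns both buffers (fresh layer outputs
// and gradient slabs), so mutating avoids one allocation per call
// [[Rcpp::export(name = ".relu_forward")]]
NumericVector relu_forward(NumericVector x) {
  double* p = x.begin();
  R_xlen_t nn = x.size();
  for (R_xlen_t i = 0; i < nn; ++i) if (p[i] < 0) p[i] = 0.0;
  return x;
}

// [[Rcpp::export(name = ".relu_backward")]]
NumericVector relu_backward(NumericVector dy, NumericVector y) {
  double* p = dy.begin();
  const double* q = y.begin();
  R_xlen_t nn = dy.size();
  for (R_xlen_t i = 0; i < nn; ++i) if (q[i] <= 0) p[i] = 0.0;
  return dy;
}
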