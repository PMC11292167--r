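// Hot numeric kernels for the channel-embedding stack: same-padding 1D
// convolution, max pooling with argmax, and exact GELU. Layout convention
// matches the R code: time-expanded matrices are (B*T) x F with row index
// r = b + (t-1)*B (batch fastest), which is R's column-major order for a
// B x T matrix.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// x: B x L signal; W: k x F kernel; b: F bias. Same padding with
// pad_left = (k-1)/2. Returns (B*L) x F.
// [[Rcpp::export(name = ".cpp_conv1d_forward")]]
NumericMatrix cpp_conv1d_forward(const NumericMatrix& x,
                                 const NumericMatrix& W,
                                 const NumericVector& b) {
  const int B = x.nrow(), L = x.ncol(), k = W.nrow(), F = W.ncol();
  const int pl = (k - 1) / 2;
  const int n = B * L;
  const double* xv = x.begin();
  NumericMatrix out(n, F);
  for (int f = 0; f < F; ++f) {
    double* o = &out(0, f);
    const double bf = b[f];
    for (int r = 0; r < n; ++r) o[r] = bf;
    for (int j = 0; j < k; ++j) {
      const double w = W(j, f);
      if (w == 0.0) continue;
      // padded index offset: frame column j reads xpv[r + (j-pl-?)..]; with
      // explicit padding the source slice is xv shifted by (j - pl) * B
      const int shift = (j - pl) * B;
      int lo = std::max(0, -shift), hi = std::min(n, n - shift);
      const double* src = xv + shift;
      for (int r = lo; r < hi; ++r) o[r] += w * src[r];
    }
  }
  return out;
}

// dY: (B*L) x F; returns list(dW (k x F), db (F), dx (B x L))
// [[Rcpp::export(name = ".cpp_conv1d_backward")]]
List cpp_conv1d_backward(const NumericMatrix& x, const NumericMatrix& dY,
                         const NumericMatrix& W) {
  const int B = x.nrow(), L = x.ncol(), k = W.nrow(), F = W.ncol();
  const int pl = (k - 1) / 2;
  const int n = B * L;
  const double* xv = x.begin();
  NumericMatrix dW(k, F);
  NumericVector db(F);
  NumericMatrix dx(B, L);
  double* dxv = dx.begin();
  for (int f = 0; f < F; ++f) {
    const double* dy = &dY(0, f);
    double s = 0.0;
    for (int r = 0; r < n; ++r) s += dy[r];
    db[f] = s;
    for (int j = 0; j < k; ++j) {
      const int shift = (j - pl) * B;
      int lo = std::max(0, -shift), hi = std::min(n, n - shift);
      const double* src = xv + shift;
      // 4-way unrolled reduction so the compiler can vectorize it
      double a0 = 0.0, a1 = 0.0, a2 = 0.0, a3 = 0.0;
      int r = lo;
      for (; r + 3 < hi; r += 4) {
        a0 += src[r] * dy[r];
        a1 += src[r + 1] * dy[r + 1];
        a2 += src[r + 2] * dy[r + 2];
        a3 += src[r + 3] * dy[r + 3];
      }
      for (; r < hi; ++r) a0 += src[r] * dy[r];
      dW(j, f) = (a0 + a1) + (a2 + a3);
      const double w = W(j, f);
      if (w == 0.0) continue;
      double* dst = dxv + shift;
      for (int r = lo; r < hi; ++r) dst[r] += w * dy[r];
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// X: (B*L) x F, pool kernel = stride = k over t. Returns list(out (B*N) x F,
// amax (B*N) x F with the 1-based within-window index of the max).
// [[Rcpp::export(name = ".cpp_maxpool_forward")]]
List cpp_maxpool_forward(const NumericMatrix& X, const int B, const int k) {
  const int n = X.nrow(), F = X.ncol();
  const int L = n / B, N = L / k;
  NumericMatrix out(B * N, F);
  IntegerMatrix amax(B * N, F);
  for (int f = 0; f < F; ++f) {
    const double* col = &X(0, f);
    for (int nn = 0; nn < N; ++nn) {
      for (int b = 0; b < B; ++b) {
        const int base = b + nn * k * B;
        double best = col[base];
        int arg = 0;
        for (int j = 1; j < k; ++j) {
          const double v = col[base + j * B];
          if (v > best) { best = v; arg = j; }
        }
        out(b + nn * B, f) = best;
        amax(b + nn * B, f) = arg + 1;
      }
    }
  }
  return List::create(_["out"] = out, _["amax"] = amax);
}

// [[Rcpp::export(name = ".cpp_maxpool_backward")]]
NumericMatrix cpp_maxpool_backward(const NumericMatrix& dY,
                                   const IntegerMatrix& amax,
                                   const int B, const int k) {
  const int m = dY.nrow(), F = dY.ncol();
  const int N = m / B, L = N * k;
  NumericMatrix dX(B * L, F);
  for (int f = 0; f < F; ++f) {
    for (int nn = 0; nn < N; ++nn) {
      for (int b = 0; b < B; ++b) {
        const int j = amax(b + nn * B, f) - 1;
        dX(b + (nn * k + j) * B, f) += dY(b + nn * B, f);
      }
    }
  }
  return dX;
}

static inline double phi(double z) {
  return 0.3989422804014327 * std::exp(-0.5 * z * z);
}
static inline double Phi(double z) {
  return 0.5 * std::erfc(-z * M_SQRT1_2);
}

// exact GELU x * Phi(x)
// [[Rcpp::export(name = ".cpp_gelu_forward")]]
NumericVector cpp_gelu_forward(const NumericVector& x) {
  const int n = x.size();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) y[i] = x[i] * Phi(x[i]);
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export(name = ".cpp_gelu_backward")]]
NumericVector cpp_gelu_backward(const NumericVector& dY,
                                const NumericVector& x) {
  const int n = x.size();
  NumericVector g(n);
  for (int i = 0; i < n; ++i) g[i] = dY[i] * (Phi(x[i]) + x[i] * phi(x[i]));
  g.attr("dim") = dY.attr("dim");
  return g;
}
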