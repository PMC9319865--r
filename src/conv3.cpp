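// Compiled kernels for the same-padded bias-free 3x3 convolutions that
// dominate training time.  Feature maps arrive as (B*H*W) x C matrices in
// column-major pixel order (row fastest, then column, images stacked).
// Convolutions are evaluated as im2col gathers feeding BLAS dgemm.

#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Gather X (R x Cin) into the im2col buffer (R x 9*Cin), column block
// o = 3*j + i holding the shift (dr, dc) = (i-1, j-1), channel fastest
// within each block: column index = o*Cin + ci.
static void im2col(const double* xp, double* col, int H, int W, int B,
                   int Cin) {
  const int n = H * W;
  const size_t R = (size_t)B * n;
  std::memset(col, 0, R * 9 * Cin * sizeof(double));
  for (int j = 0; j < 3; ++j) {
    const int dc = j - 1;
    for (int i = 0; i < 3; ++i) {
      const int dr = i - 1;
      const int o = 3 * j + i;
      const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
      const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
      const int len = r1 - r0;
      if (len <= 0) continue;
      for (int ci = 0; ci < Cin; ++ci) {
        const double* xc = xp + (size_t)ci * R;
        double* cc = col + ((size_t)o * Cin + ci) * R;
        for (int b = 0; b < B; ++b) {
          const size_t base = (size_t)b * n;
          for (int c = c0; c < c1; ++c) {
            std::memcpy(cc + base + (size_t)c * H + r0,
                        xc + base + (size_t)(c + dc) * H + (r0 + dr),
                        len * sizeof(double));
          }
        }
      }
    }
  }
}

// Scatter-add the im2col-layout gradient back onto the input grid
// (transpose of im2col).
static void col2im_add(const double* col, double* gx, int H, int W, int B,
                       int Cin) {
  const int n = H * W;
  const size_t R = (size_t)B * n;
  for (int j = 0; j < 3; ++j) {
    const int dc = j - 1;
    for (int i = 0; i < 3; ++i) {
      const int dr = i - 1;
      const int o = 3 * j + i;
      const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
      const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
      const int len = r1 - r0;
      if (len <= 0) continue;
      for (int ci = 0; ci < Cin; ++ci) {
        double* gc = gx + (size_t)ci * R;
        const double* cc = col + ((size_t)o * Cin + ci) * R;
        for (int b = 0; b < B; ++b) {
          const size_t base = (size_t)b * n;
          for (int c = c0; c < c1; ++c) {
            const double* src = cc + base + (size_t)c * H + r0;
            double* dst = gc + base + (size_t)(c + dc) * H + (r0 + dr);
            for (int r = 0; r < len; ++r) dst[r] += src[r];
          }
        }
      }
    }
  }
}

// Reshape w (3,3,Cin,Cout) into the (9*Cin x Cout) matrix matching the
// im2col column order.
static void kernel_mat(const double* wp, double* wm, int Cin, int Cout) {
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int j = 0; j < 3; ++j)
        for (int i = 0; i < 3; ++i)
          wm[(size_t)(3 * j + i) * Cin + ci + (size_t)(9 * Cin) * co] =
            wp[i + 3 * j + 9 * ci + 9 * Cin * co];
}

static void kernel_unmat(const double* wm, double* wp, int Cin, int Cout) {
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int j = 0; j < 3; ++j)
        for (int i = 0; i < 3; ++i)
          wp[i + 3 * j + 9 * ci + 9 * Cin * co] =
            wm[(size_t)(3 * j + i) * Cin + ci + (size_t)(9 * Cin) * co];
}

// [[Rcpp::export(name = ".cpp_conv3_fw")]]
NumericMatrix cpp_conv3_fw(const NumericMatrix& X, const NumericVector& w,
                           int H, int W, int B) {
  const int R = B * H * W;
  const int Cin = X.ncol();
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[3];
  const int K = 9 * Cin;
  NumericMatrix Y(R, Cout);
  std::vector<double> col((size_t)R * K), wm((size_t)K * Cout);
  im2col(X.begin(), col.data(), H, W, B, Cin);
  kernel_mat(w.begin(), wm.data(), Cin, Cout);
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &R, &Cout, &K, &one, col.data(), &R,
                  wm.data(), &K, &zero, Y.begin(), &R FCONE FCONE);
  return Y;
}

// Fused input+kernel gradient of the 3x3 convolution.
// [[Rcpp::export(name = ".cpp_conv3_bw")]]
List cpp_conv3_bw(const NumericMatrix& X, const NumericMatrix& gY,
                  const NumericVector& w, int H, int W, int B) {
  const int R = B * H * W;
  const int Cin = X.ncol(), Cout = gY.ncol();
  const int K = 9 * Cin;
  NumericMatrix gX(R, Cin);
  NumericVector gW(9 * Cin * Cout);
  gW.attr("dim") = IntegerVector::create(3, 3, Cin, Cout);
  std::vector<double> col((size_t)R * K), wm((size_t)K * Cout),
      gwm((size_t)K * Cout);
  const double one = 1.0, zero = 0.0;
  // kernel gradient: t(im2col(X)) %*% gY
  im2col(X.begin(), col.data(), H, W, B, Cin);
  F77_CALL(dgemm)("T", "N", &K, &Cout, &R, &one, col.data(), &R,
                  gY.begin(), &R, &zero, gwm.data(), &K FCONE FCONE);
  kernel_unmat(gwm.data(), gW.begin(), Cin, Cout);
  // input gradient: col2im(gY %*% t(wm))
  kernel_mat(w.begin(), wm.data(), Cin, Cout);
  F77_CALL(dgemm)("N", "T", &R, &K, &Cout, &one, gY.begin(), &R,
                  wm.data(), &K, &zero, col.data(), &R FCONE FCONE);
  std::memset(gX.begin(), 0, (size_t)R * Cin * sizeof(double));
  col2im_add(col.data(), gX.begin(), H, W, B, Cin);
  return List::create(Named("gX") = gX, Named("gW") = gW);
}
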