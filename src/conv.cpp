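#include <Rcpp.h>
using namespace Rcpp;

// Spatial arrays are column-major (H, W, N, C): index r + H*(c + W*(n + N*ch)).
// im2col for a 3x3 kernel with padding 1, stride 1: returns the unfolded
// matrix (H*W*N) x (9*C) with row index pos + H*W*n (pos = r + H*c) and
// column index j + 9*ch, where j enumerates kernel offsets column-major
// (dy = j % 3, dx = j / 3), matching the R-side weight layout.

// [[Rcpp::export(name = ".im2col3")]]
NumericMatrix im2col3(NumericVector x, int H, int W, int N, int C) {
  const int HW = H * W;
  NumericMatrix out(HW * N, 9 * C);
  const double* px = x.begin();
  for (int ch = 0; ch < C; ++ch) {
    for (int j = 0; j < 9; ++j) {
      const int dy = j % 3 - 1;   // offset relative to centre
      const int dx = j / 3 - 1;
      double* pc = &out(0, ch * 9 + j);
      for (int n = 0; n < N; ++n) {
        const double* plane = px + ((size_t)(ch * N + n)) * HW;
        double* prow = pc + (size_t)n * HW;
        for (int c = 0; c < W; ++c) {
          const int cs = c + dx;
          if (cs < 0 || cs >= W) continue;
          const int r0 = (0 + dy < 0) ? 1 : 0;
          const int r1 = (H - 1 + dy >= H) ? H - 1 : H;
          const double* src = plane + cs * H + dy;
          double* dst = prow + c * H;
          for (int r = r0; r < r1; ++r) dst[r] = src[r];
        }
      }
    }
  }
  return out;
}

// scatter-add inverse of im2col3: folds the gradient (H*W*N) x (9*C) back
// onto the (H, W, N, C) input
// [[Rcpp::export(name = ".col2im3")]]
NumericVector col2im3(NumericMatrix dcols, int H, int W, int N, int C) {
  const int HW = H * W;
  NumericVector dx_out((R_xlen_t)H * W * N * C);
  dx_out.attr("dim") = IntegerVector::create(H, W, N, C);
  double* pd = dx_out.begin();
  for (int ch = 0; ch < C; ++ch) {
    for (int j = 0; j < 9; ++j) {
      const int dy = j % 3 - 1;
      const int dx = j / 3 - 1;
      const double* pc = &dcols(0, ch * 9 + j);
      for (int n = 0; n < N; ++n) {
        double* plane = pd + ((size_t)(ch * N + n)) * HW;
        const double* prow = pc + (size_t)n * HW;
        for (int c = 0; c < W; ++c) {
          const int cs = c + dx;
          if (cs < 0 || cs >= W) continue;
          const int r0 = (0 + dy < 0) ? 1 : 0;
          const int r1 = (H - 1 + dy >= H) ? H - 1 : H;
          double* dst = plane + cs * H + dy;
          const double* src = prow + c * H;
          for (int r = r0; r < r1; ++r) dst[r] += src[r];
        }
      }
    }
  }
  return dx_out;
}
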