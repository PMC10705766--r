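// Depthwise convolution kernels. Dense convolutions are evaluated as
// shifted GEMMs through BLAS on the R side; depthwise stages have no GEMM
// formulation worth the overhead, so their inner loops live here.
//
// Layouts (column-major, as R stores them):
//   xp  : padded input, dim (Hp, Wp, C)
//   W   : kernels, dim (k, k, C, mult)
//   out : dim (Ho, Wo, C * mult); output channel m*C + c is the m-th
//         filtered copy of input channel c

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector dw_conv_fwd_cpp(NumericVector xp, IntegerVector xdim,
                              NumericVector W, IntegerVector wdim,
                              int stride, int Ho, int Wo) {
  const int Hp = xdim[0], Wp = xdim[1], C = xdim[2];
  const int k = wdim[0], mult = wdim[3];
  (void)Wp;
  NumericVector out((R_xlen_t)Ho * Wo * C * mult);
  for (int m = 0; m < mult; ++m) {
    for (int c = 0; c < C; ++c) {
      const double* xc = &xp[(R_xlen_t)Hp * xdim[1] * c];
      double* oc = &out[(R_xlen_t)Ho * Wo * ((R_xlen_t)m * C + c)];
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const double w = W[ki + k * (kj + k * (c + (R_xlen_t)C * m))];
          if (w == 0.0) continue;
          for (int j = 0; j < Wo; ++j) {
            const double* xcol = xc + (R_xlen_t)(j * stride + kj) * Hp + ki;
            double* ocol = oc + (R_xlen_t)j * Ho;
            for (int i = 0; i < Ho; ++i)
              ocol[i] += w * xcol[(R_xlen_t)i * stride];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List dw_conv_bwd_cpp(NumericVector xp, IntegerVector xdim,
                     NumericVector W, IntegerVector wdim,
                     NumericVector g, int stride, int Ho, int Wo) {
  const int Hp = xdim[0], C = xdim[2];
  const int k = wdim[0], mult = wdim[3];
  NumericVector gxp((R_xlen_t)xp.size());
  NumericVector gW((R_xlen_t)W.size());
  for (int m = 0; m < mult; ++m) {
    for (int c = 0; c < C; ++c) {
      const double* xc = &xp[(R_xlen_t)Hp * xdim[1] * c];
      double* gxc = &gxp[(R_xlen_t)Hp * xdim[1] * c];
      const double* gc = &g[(R_xlen_t)Ho * Wo * ((R_xlen_t)m * C + c)];
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const R_xlen_t widx = ki + k * (kj + k * (c + (R_xlen_t)C * m));
          const double w = W[widx];
          double acc = 0.0;
          for (int j = 0; j < Wo; ++j) {
            const R_xlen_t xoff = (R_xlen_t)(j * stride + kj) * Hp + ki;
            const double* gcol = gc + (R_xlen_t)j * Ho;
            const double* xcol = xc + xoff;
            double* gxcol = gxc + xoff;
            for (int i = 0; i < Ho; ++i) {
              const double gv = gcol[i];
              acc += xcol[(R_xlen_t)i * stride] * gv;
              gxcol[(R_xlen_t)i * stride] += w * gv;
            }
          }
          gW[widx] += acc;
        }
      }
    }
  }
  return List::create(_["gxp"] = gxp, _["gW"] = gW);
}
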