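// Hot inner loops of the convolution layers: the im2col gather and its
// adjoint scatter-add. Everything else (GEMM, pooling, upsampling) stays in
// R on top of BLAS / indexed assignment.

#include <Rcpp.h>
using namespace Rcpp;

// Xa: (nAll+1) x Cin feature matrix, last row = zero padding.
// P:  nAll x 9 integer matrix of 1-based row indices into Xa.
// Returns nAll x (9*Cin) matrix with column (c-1)*9 + k holding input
// channel c at spatial offset k (the layout conv weights use).
// [[Rcpp::export(name = ".cppIm2col")]]
NumericMatrix cppIm2col(const NumericMatrix& Xa, const IntegerMatrix& P) {
  const int nAll = P.nrow();
  const int Cin = Xa.ncol();
  const int nr = Xa.nrow();
  NumericMatrix out(nAll, 9 * Cin);
  const double* xa = REAL(Xa);
  const int* p = INTEGER(P);
  double* o = REAL(out);
  for (int c = 0; c < Cin; ++c) {
    const double* xcol = xa + (R_xlen_t)c * nr;
    for (int k = 0; k < 9; ++k) {
      const int* pk = p + (R_xlen_t)k * nAll;
      double* ocol = o + ((R_xlen_t)c * 9 + k) * nAll;
      for (int i = 0; i < nAll; ++i) ocol[i] = xcol[pk[i] - 1];
    }
  }
  return out;
}

// Adjoint of the gather: dcols is nAll x (9*Cin) (same column layout);
// accumulates into an nAll x Cin gradient, dropping padding reads.
// [[Rcpp::export(name = ".cppCol2im")]]
NumericMatrix cppCol2im(const NumericMatrix& dcols, const IntegerMatrix& P) {
  const int nAll = P.nrow();
  const int Cin = dcols.ncol() / 9;
  NumericMatrix out(nAll, Cin);
  const double* d = REAL(dcols);
  const int* p = INTEGER(P);
  double* o = REAL(out);
  for (int c = 0; c < Cin; ++c) {
    double* ocol = o + (R_xlen_t)c * nAll;
    for (int k = 0; k < 9; ++k) {
      const int* pk = p + (R_xlen_t)k * nAll;
      const double* dcol = d + ((R_xlen_t)c * 9 + k) * nAll;
      for (int i = 0; i < nAll; ++i) {
        const int tgt = pk[i] - 1;
        if (tgt < nAll) ocol[tgt] += dcol[i];
      }
    }
  }
  return out;
}
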