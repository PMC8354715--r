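#include <Rcpp.h>
using namespace Rcpp;

// Permutation nulls for baseline-resampled trial-mean statistics.
//
// V holds baseline values with dimensions (ntr, nb, ncf): trials x baseline
// time points x (channel*frequency cells). idx is an ntr x (K*n_perm) matrix
// of 1-based baseline time indices, one column per within-permutation draw.
// For each permutation the trial-mean statistic is evaluated at each of its K
// draws and the extremes over the K draws are returned (n_perm x ncf). The
// cf-outer loop keeps each (ntr x nb) slab cache-resident.

// [[Rcpp::export]]
List perm_null_minmax_real(NumericVector V, IntegerVector dims,
                           IntegerMatrix idx, int n_perm, int K) {
  const int ntr = dims[0], nb = dims[1], ncf = dims[2];
  NumericMatrix mx(n_perm, ncf), mn(n_perm, ncf);
  const double *v = REAL(V);
  const int ncol = n_perm * K;
  std::vector<int> offs((size_t)ntr * ncol);
  for (int col = 0; col < ncol; ++col)
    for (int r = 0; r < ntr; ++r)
      offs[(size_t)col * ntr + r] = r + ntr * (idx(r, col) - 1);
  for (int cf = 0; cf < ncf; ++cf) {
    const double *slab = v + (size_t)ntr * nb * cf;
    for (int col = 0; col < ncol; ++col) {
      const int *o = offs.data() + (size_t)col * ntr;
      double s = 0.0;
      for (int r = 0; r < ntr; ++r) s += slab[o[r]];
      s /= ntr;
      const int p = col / K;
      if (col % K == 0) { mx(p, cf) = s; mn(p, cf) = s; }
      else {
        if (s > mx(p, cf)) mx(p, cf) = s;
        if (s < mn(p, cf)) mn(p, cf) = s;
      }
    }
  }
  return List::create(_["max"] = mx, _["min"] = mn);
}

// Same construction for complex unit-phasor statistics (ITPC/ISPC): the
// statistic is the modulus of the trial-mean phasor. V is complex with
// dimensions (ntr, nb, ncf).

// [[Rcpp::export]]
List perm_null_minmax_mod(ComplexVector V, IntegerVector dims,
                          IntegerMatrix idx, int n_perm, int K) {
  const int ntr = dims[0], nb = dims[1], ncf = dims[2];
  NumericMatrix mx(n_perm, ncf), mn(n_perm, ncf);
  const Rcomplex *v = COMPLEX(V);
  const int ncol = n_perm * K;
  std::vector<int> offs((size_t)ntr * ncol);
  for (int col = 0; col < ncol; ++col)
    for (int r = 0; r < ntr; ++r)
      offs[(size_t)col * ntr + r] = r + ntr * (idx(r, col) - 1);
  for (int cf = 0; cf < ncf; ++cf) {
    const Rcomplex *slab = v + (size_t)ntr * nb * cf;
    for (int col = 0; col < ncol; ++col) {
      const int *o = offs.data() + (size_t)col * ntr;
      double sr = 0.0, si = 0.0;
      for (int r = 0; r < ntr; ++r) {
        sr += slab[o[r]].r;
        si += slab[o[r]].i;
      }
      const double m = std::sqrt(sr * sr + si * si) / ntr;
      const int p = col / K;
      if (col % K == 0) { mx(p, cf) = m; mn(p, cf) = m; }
      else {
        if (m > mx(p, cf)) mx(p, cf) = m;
        if (m < mn(p, cf)) mn(p, cf) = m;
      }
    }
  }
  return List::create(_["max"] = mx, _["min"] = mn);
}
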