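#include <Rcpp.h>
using namespace Rcpp;

// In-place accumulation step for the co-occurrence permutation null:
// running sum and sum of squares of the null correlations, plus tail
// counts (with a comparison tolerance) against the observed matrix.
// The caller owns the accumulator matrices and guarantees they are not
// shared, so in-place updates are safe and allocation-free.
// [[Rcpp::export]]
void cooc_accum(NumericMatrix s1, NumericMatrix s2,
                NumericMatrix cnt_ge, NumericMatrix cnt_le,
                NumericMatrix C, NumericMatrix obs, double eps) {
  const R_xlen_t n = C.size();
  double *p1 = s1.begin(), *p2 = s2.begin();
  double *pg = cnt_ge.begin(), *pl = cnt_le.begin();
  const double *pc = C.begin(), *po = obs.begin();
  for (R_xlen_t k = 0; k < n; ++k) {
    const double c = pc[k], o = po[k];
    p1[k] += c;
    p2[k] += c * c;
    if (c >= o - eps) pg[k] += 1.0;
    if (c <= o + eps) pl[k] += 1.0;
  }
}
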