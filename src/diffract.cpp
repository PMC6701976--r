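// Coherent-sum diffraction kernel.
//
// For each detector pixel p with scattering vector q_p the complex molecular
// transform is F(p) = sum_i f_{s(i)}(p) exp(2 pi i q_p . R_i); the caller
// multiplies |F|^2 by the per-pixel prefactor r_e^2 P(q) dOmega and the frame
// fluence.  Form factors enter as a pixels x states matrix evaluated at each
// pixel's |q|, with one state per distinct (element, core, valence)
// configuration present in the frame.
//
// The trigonometric accumulation dominates the pipeline's diffraction cost,
// so it is compiled with runtime-dispatched clones (baseline and AVX2) and
// fed from a contiguous phase buffer that the compiler can vectorise.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

#if defined(__GNUC__) && defined(__x86_64__)
__attribute__((target_clones("default", "avx2")))
#endif
static void trig_accum(const double* ph, const double* f, double* re,
                       double* im, const R_xlen_t np) {
  for (R_xlen_t p = 0; p < np; ++p) {
    re[p] += f[p] * std::cos(ph[p]);
    im[p] += f[p] * std::sin(ph[p]);
  }
}

// [[Rcpp::export(name = ".coherent_sum_cpp")]]
NumericVector coherent_sum_cpp(NumericVector qx, NumericVector qy,
                               NumericVector qz, NumericMatrix pos,
                               NumericMatrix fmat, IntegerVector state) {
  const R_xlen_t np = qx.size();
  const int m = pos.nrow();
  if (qy.size() != np || qz.size() != np) stop("q component length mismatch");
  if (fmat.nrow() != np) stop("fmat must have one row per pixel");
  if (state.size() != m) stop("state must have one entry per atom");

  std::vector<double> re(np, 0.0), im(np, 0.0), ph(np);
  const double twopi = 2.0 * M_PI;
  const double* qxp = qx.begin();
  const double* qyp = qy.begin();
  const double* qzp = qz.begin();
  for (int i = 0; i < m; ++i) {
    const double x = twopi * pos(i, 0);
    const double y = twopi * pos(i, 1);
    const double z = twopi * pos(i, 2);
    double* php = ph.data();
    for (R_xlen_t p = 0; p < np; ++p)
      php[p] = qxp[p] * x + qyp[p] * y + qzp[p] * z;
    trig_accum(php, &fmat(0, state[i] - 1), re.data(), im.data(), np);
  }
  NumericVector out(np);
  for (R_xlen_t p = 0; p < np; ++p)
    out[p] = re[p] * re[p] + im[p] * im[p];
  return out;
}
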