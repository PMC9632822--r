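#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Batch fixed-step RK4 integration of gLV dynamics
//   dN_i/dt = N_i * (theta_i - sum_j a_ij N_j)
// across n independent draws (rows of theta / n0). Abundances are clamped
// to [0, div_threshold] after each full step; a draw is flagged diverged
// when any abundance hits the upper cap (finite-time blow-up in systems
// without a globally stable equilibrium). Integration continues with the
// blown-up species saturated at the cap so that competitive exclusion of
// the remaining species still plays out over the full horizon.
//
// Draws are processed in blocks of B with the block index innermost, so the
// stage loops vectorize across independent trajectories.
// [[Rcpp::export]]
List rk4_glv_batch_cpp(NumericMatrix A, NumericMatrix theta,
                       NumericMatrix n0, double total_time, double step,
                       double div_threshold) {
  const int d = A.nrow();
  const int n = theta.nrow();
  if (A.ncol() != d || theta.ncol() != d || n0.nrow() != n || n0.ncol() != d)
    stop("dimension mismatch in rk4_glv_batch_cpp");
  const long nsteps = (long)std::llround(total_time / step);

  NumericMatrix out(n, d);
  LogicalVector diverged(n);
  std::vector<double> a(A.begin(), A.end());  // column-major d x d

  const int B = 64;
  std::vector<double> N(d * B), TH(d * B), K1(d * B), K2(d * B),
      K3(d * B), K4(d * B), TMP(d * B);
  std::vector<char> div(B);

  for (int r0 = 0; r0 < n; r0 += B) {
    const int nb = std::min(B, n - r0);

    auto deriv = [&](const double* X, double* K) {
      for (int i = 0; i < d; ++i) {
        double* ki = K + (size_t)i * B;
        const double* thi = TH.data() + (size_t)i * B;
        for (int b = 0; b < nb; ++b) ki[b] = thi[b];
        for (int j = 0; j < d; ++j) {
          const double aij = a[i + j * d];
          const double* xj = X + (size_t)j * B;
          for (int b = 0; b < nb; ++b) ki[b] -= aij * xj[b];
        }
        const double* xi = X + (size_t)i * B;
        for (int b = 0; b < nb; ++b) ki[b] *= xi[b];
      }
    };

    for (int i = 0; i < d; ++i)
      for (int b = 0; b < nb; ++b) {
        N[(size_t)i * B + b] = n0(r0 + b, i);
        TH[(size_t)i * B + b] = theta(r0 + b, i);
      }
    std::fill(div.begin(), div.end(), 0);

    for (long s = 0; s < nsteps; ++s) {
      deriv(N.data(), K1.data());
      for (size_t t = 0; t < (size_t)d * B; ++t)
        TMP[t] = N[t] + 0.5 * step * K1[t];
      deriv(TMP.data(), K2.data());
      for (size_t t = 0; t < (size_t)d * B; ++t)
        TMP[t] = N[t] + 0.5 * step * K2[t];
      deriv(TMP.data(), K3.data());
      for (size_t t = 0; t < (size_t)d * B; ++t)
        TMP[t] = N[t] + step * K3[t];
      deriv(TMP.data(), K4.data());
      for (int i = 0; i < d; ++i) {
        for (int b = 0; b < nb; ++b) {
          const size_t t = (size_t)i * B + b;
          double v = N[t] + step / 6.0 *
                              (K1[t] + 2.0 * K2[t] + 2.0 * K3[t] + K4[t]);
          if (v < 0.0) v = 0.0;
          if (!(v <= div_threshold)) {  // catches blow-up and NaN
            v = div_threshold;
            div[b] = 1;
          }
          N[t] = v;
        }
      }
    }

    for (int b = 0; b < nb; ++b) {
      diverged[r0 + b] = div[b] != 0;
      for (int i = 0; i < d; ++i) out(r0 + b, i) = N[(size_t)i * B + b];
    }
  }
  return List::create(_["final"] = out, _["diverged"] = diverged);
}
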