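#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Brute-force pairwise Coulomb sums for one pose.
//
// P (M x 3) holds body P's reference coordinates, Qp (N x 3) body Q's
// already-posed coordinates; lp / lq are the particle charges. With
// w = lp[i] * lq[j] * inv4pieps the kernel accumulates in one pass:
//   energy  sum w / d
//   force   sum (w / d^3) * (q - p)          (central 1/d^2 force)
//   moment  sum q x f                        (about the frame origin)
// Returns c(energy, fx, fy, fz, mx, my, mz); non-finite entries signal a
// coincident pair (d = 0), which the R wrapper reports by pair index.
// [[Rcpp::export]]
NumericVector bf_coulomb_all(const NumericMatrix& P, const NumericVector& lp,
                             const NumericMatrix& Qp, const NumericVector& lq,
                             double inv4pieps) {
  const int M = P.nrow(), N = Qp.nrow();
  long double e = 0.0L, fx = 0.0L, fy = 0.0L, fz = 0.0L;
  long double mx = 0.0L, my = 0.0L, mz = 0.0L;
  for (int j = 0; j < N; ++j) {
    const double qx = Qp(j, 0), qy = Qp(j, 1), qz = Qp(j, 2), cj = lq[j];
    long double fjx = 0.0L, fjy = 0.0L, fjz = 0.0L;
    for (int i = 0; i < M; ++i) {
      const double dx = qx - P(i, 0);
      const double dy = qy - P(i, 1);
      const double dz = qz - P(i, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double d = std::sqrt(d2);
      const double w = lp[i] * cj * inv4pieps;
      e += w / d;
      const double wd3 = w / (d2 * d);
      fjx += wd3 * dx;
      fjy += wd3 * dy;
      fjz += wd3 * dz;
    }
    fx += fjx; fy += fjy; fz += fjz;
    mx += qy * fjz - qz * fjy;
    my += qz * fjx - qx * fjz;
    mz += qx * fjy - qy * fjx;
  }
  return NumericVector::create((double)e, (double)fx, (double)fy, (double)fz,
                               (double)mx, (double)my, (double)mz);
}
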