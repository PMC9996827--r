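// Optical-matrix (Parratt recursion) specular reflectivity kernel.
//
// SLDs are passed in absolute units (A^-2). The wavevector in medium j is
// k_j = sqrt(k0^2 - 4*pi*(rho_j - rho_incident)) with k0 = Q/2; below the
// critical edge k_j is imaginary and the recursion returns |R|^2 = 1.

#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector abeles_kernel(NumericVector q, double sldIncident,
                            NumericVector sldLayers, NumericVector dLayers,
                            double sldBacking) {
  const int nq = q.size();
  const int nl = sldLayers.size();
  if (dLayers.size() != nl) stop("layer SLD/thickness length mismatch");
  const double fourpi = 4.0 * M_PI;
  NumericVector out(nq);
  std::vector<std::complex<double> > k(nl + 2);

  for (int i = 0; i < nq; ++i) {
    const double k0 = q[i] / 2.0;
    if (!(k0 > 0.0)) stop("q must be positive");
    k[0] = std::complex<double>(k0, 0.0);
    for (int j = 0; j < nl; ++j)
      k[j + 1] = std::sqrt(std::complex<double>(
          k0 * k0 - fourpi * (sldLayers[j] - sldIncident), 0.0));
    k[nl + 1] = std::sqrt(std::complex<double>(
        k0 * k0 - fourpi * (sldBacking - sldIncident), 0.0));

    std::complex<double> R(0.0, 0.0);
    for (int j = nl; j >= 0; --j) {
      const std::complex<double> rj = (k[j] - k[j + 1]) / (k[j] + k[j + 1]);
      if (j < nl) {  // medium j+1 is a finite layer with thickness d[j]
        const std::complex<double> ph =
            std::exp(std::complex<double>(0.0, 2.0) * k[j + 1] * dLayers[j]);
        R = (rj + R * ph) / (1.0 + rj * R * ph);
      } else {
        R = rj;  // bottom interface; backing is semi-infinite
      }
    }
    double rr = std::norm(R);
    out[i] = rr > 1.0 ? 1.0 : rr;  // clip FP overshoot at total reflection
  }
  return out;
}
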