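#include <Rcpp.h>
using namespace Rcpp;

// Edge-preserving bilateral filter: Gaussian in space (sigma_spatial, px)
// and in intensity (sigma_range, same units as img). Border handled by
// window truncation.
// [[Rcpp::export]]
NumericMatrix bilateral_filter_cpp(NumericMatrix img, double sigma_spatial,
                                   double sigma_range, int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  const int w = 2 * radius + 1;
  std::vector<double> spatial(w * w);
  for (int dr = -radius; dr <= radius; ++dr)
    for (int dc = -radius; dc <= radius; ++dc)
      spatial[(dr + radius) * w + (dc + radius)] =
          std::exp(-(dr * dr + dc * dc) /
                   (2.0 * sigma_spatial * sigma_spatial));
  const double inv2sr2 = 1.0 / (2.0 * sigma_range * sigma_range);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const double v0 = img(r, c);
      double num = 0.0, den = 0.0;
      const int r0 = std::max(0, r - radius), r1 = std::min(nr - 1, r + radius);
      const int c0 = std::max(0, c - radius), c1 = std::min(nc - 1, c + radius);
      for (int cc = c0; cc <= c1; ++cc) {
        for (int rr = r0; rr <= r1; ++rr) {
          const double v = img(rr, cc);
          const double d = v - v0;
          const double wgt =
              spatial[(rr - r + radius) * w + (cc - c + radius)] *
              std::exp(-d * d * inv2sr2);
          num += wgt * v;
          den += wgt;
        }
      }
      out(r, c) = num / den;
    }
  }
  return out;
}
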