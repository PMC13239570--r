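#include <Rcpp.h>
using namespace Rcpp;

// Masked zero-normalized cross-correlation surface.
//
// image: nr x nc matrix; patch/mask: pr x pc (mask logical support).
// row_starts/col_starts: 1-based top-left corners of candidate patch
// placements (all assumed to fit inside the image; validated in R).
// Offsets where the image patch is constant under the mask get 0.
// [[Rcpp::export]]
NumericMatrix ncc_surface_cpp(NumericMatrix image, NumericMatrix patch,
                              LogicalMatrix mask, IntegerVector row_starts,
                              IntegerVector col_starts) {
  const int pr = patch.nrow(), pc = patch.ncol();
  std::vector<int> mi, mj;
  std::vector<double> tc;  // centered template values under the mask
  double tsum = 0.0;
  int m = 0;
  for (int j = 0; j < pc; ++j)
    for (int i = 0; i < pr; ++i)
      if (mask(i, j)) {
        mi.push_back(i); mj.push_back(j);
        tsum += patch(i, j);
        ++m;
      }
  if (m == 0) stop("empty template mask");
  const double tmean = tsum / m;
  double tnorm2 = 0.0;
  tc.resize(m);
  for (int k = 0; k < m; ++k) {
    tc[k] = patch(mi[k], mj[k]) - tmean;
    tnorm2 += tc[k] * tc[k];
  }
  const int nr_off = row_starts.size(), nc_off = col_starts.size();
  NumericMatrix surf(nr_off, nc_off);
  if (tnorm2 <= 0) return surf;  // constant template: all zero
  for (int cj = 0; cj < nc_off; ++cj) {
    const int c0 = col_starts[cj] - 1;
    for (int ci = 0; ci < nr_off; ++ci) {
      const int r0 = row_starts[ci] - 1;
      double s = 0.0, s2 = 0.0;
      for (int k = 0; k < m; ++k) {
        const double v = image(r0 + mi[k], c0 + mj[k]);
        s += v; s2 += v * v;
      }
      const double imean = s / m;
      const double inorm2 = s2 - m * imean * imean;
      if (inorm2 <= 1e-12 * (s2 > 0 ? s2 : 1.0)) {
        surf(ci, cj) = 0.0;
        continue;
      }
      double cross = 0.0;
      for (int k = 0; k < m; ++k)
        cross += tc[k] * (image(r0 + mi[k], c0 + mj[k]) - imean);
      surf(ci, cj) = cross / std::sqrt(tnorm2 * inorm2);
    }
  }
  return surf;
}
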