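#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Non-local means on a 2-D image, offset-accumulation formulation.
//
// For every displacement d in the search window the patch SSD between p and
// p+d is obtained for all pixels at once from a summed-area table over the
// squared-difference image, making the cost O(|search window| * n_pixels)
// independent of patch size. Patch similarity is symmetric in (p, p+d), so
// only half the displacements are visited and each pair contributes to both
// endpoints. Borders are handled by reflective padding; the exponential
// weight is read from a dense lookup table with linear interpolation.
// [[Rcpp::export(name = ".nlm_cpp")]]
NumericMatrix nlm_cpp(NumericMatrix img, double h, int patch_radius,
                      int search_radius) {
  const int nr = img.nrow(), nc = img.ncol();
  const int f = patch_radius, s = search_radius;
  const int off = f + s;
  const int pr = nr + 2 * off, pc = nc + 2 * off;
  const double patch_n = (2.0 * f + 1.0) * (2.0 * f + 1.0);
  const double inv_h2n = 1.0 / (h * h * patch_n);

  // exp(-t) for t in [0, 32), 1/128 steps; beyond 32 the weight is ~1e-14
  const int TBL = 4096;
  static std::vector<double> tbl;
  if (tbl.empty()) {
    tbl.resize(TBL + 1);
    for (int i = 0; i <= TBL; ++i) tbl[i] = std::exp(-i / 128.0);
  }
  auto wexp = [&](double t) -> double {
    const double u = t * 128.0;
    const int i = (int)u;
    const double fr = u - i;
    return tbl[i] * (1.0 - fr) + tbl[i + 1] * fr;
  };

  // reflective padding
  std::vector<double> P((size_t)pr * pc);
  auto refl = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  for (int c = 0; c < pc; ++c) {
    const int sc = refl(c - off, nc);
    for (int r = 0; r < pr; ++r)
      P[(size_t)r + (size_t)pr * c] = img(refl(r - off, nr), sc);
  }

  // num/den accumulated on the padded frame so that the symmetric
  // contribution of border pixels lands in the margins and is dropped
  std::vector<double> num((size_t)pr * pc, 0.0), den((size_t)pr * pc, 0.0);
  std::vector<double> d2((size_t)pr * pc, 0.0),
      integ((size_t)(pr + 1) * (pc + 1), 0.0);

  for (int dc = 0; dc <= s; ++dc) {
    const int dr_lo = (dc == 0) ? 1 : -s;
    for (int dr = dr_lo; dr <= s; ++dr) {
      // squared-difference image on the overlap of the padded frame with
      // its d-shifted copy
      const int c0 = std::max(0, -dc), c1 = pc - std::max(0, dc);
      const int r0 = std::max(0, -dr), r1 = pr - std::max(0, dr);
      for (int c = c0; c < c1; ++c) {
        const size_t b0 = (size_t)pr * c, b1 = (size_t)pr * (c + dc) + dr;
        for (int r = r0; r < r1; ++r) {
          const double d = P[b0 + r] - P[b1 + r];
          d2[b0 + r] = d * d;
        }
      }
      // summed-area table (zero outside the valid overlap is harmless for
      // the pixels we read, all of whose patches lie inside it)
      for (int c = 1; c <= pc; ++c) {
        const size_t ic = (size_t)(pr + 1) * c, icm = ic - (pr + 1);
        const size_t dc0 = (size_t)pr * (c - 1);
        double colsum = 0.0;
        for (int r = 1; r <= pr; ++r) {
          colsum += d2[dc0 + r - 1];
          integ[ic + r] = integ[icm + r] + colsum;
        }
      }
      // visit every p such that p or p+d lies in the image proper
      const int pc0 = std::max(off - std::max(0, dc), f),
                pc1 = std::min(pc - off - std::min(0, dc), pc - f);
      const int prl = std::max(off - std::max(0, dr), f),
                prh = std::min(pr - off - std::min(0, dr), pr - f);
      for (int c = pc0; c < pc1; ++c) {
        const size_t iA = (size_t)(pr + 1) * (c - f), iB = (size_t)(pr + 1) * (c + f + 1);
        const size_t col_p = (size_t)pr * c, col_q = (size_t)pr * (c + dc) + dr;
        for (int r = prl; r < prh; ++r) {
          const double ssd = integ[iB + r + f + 1] - integ[iA + r + f + 1]
                           - integ[iB + r - f] + integ[iA + r - f];
          const double t = ssd * inv_h2n;
          if (t >= 16.0) continue;  // weight < 1.2e-7: negligible
          const double w = wexp(t);
          num[col_p + r] += w * P[col_q + r];
          den[col_p + r] += w;
          num[col_q + r] += w * P[col_p + r];
          den[col_q + r] += w;
        }
      }
      // clear d2 in the touched band for the next offset
      for (int c = c0; c < c1; ++c) {
        const size_t b0 = (size_t)pr * c;
        std::fill(d2.begin() + b0 + r0, d2.begin() + b0 + (r1 - r0) + r0, 0.0);
      }
    }
  }

  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    const size_t pcol = (size_t)pr * (c + off) + off;
    for (int r = 0; r < nr; ++r)
      out(r, c) = (num[pcol + r] + img(r, c)) / (den[pcol + r] + 1.0);
  }
  return out;
}
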