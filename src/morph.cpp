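#include <Rcpp.h>
#include <queue>
#include <algorithm>

using namespace Rcpp;

// Grayscale morphological reconstruction by dilation, 8-connectivity.
// Hybrid raster/anti-raster sweep followed by a FIFO queue pass
// (Vincent-style), so reconstruction reaches stability in effectively
// two image scans instead of iterating elementary dilations.
//
// marker must be <= mask pointwise; both are numeric matrices of equal size.
// [[Rcpp::export(name = ".reconstruct_dilation_cpp")]]
NumericMatrix reconstruct_dilation_cpp(NumericMatrix marker, NumericMatrix mask) {
  const int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask dimensions differ");
  NumericMatrix J = clone(marker);
  const NumericMatrix &I = mask;

  auto at = [&](int r, int c) -> double & { return J(r, c); };

  // raster scan: neighbours already visited (N+): (r-1,c-1),(r-1,c),(r-1,c+1),(r,c-1)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double m = at(r, c);
      if (r > 0) m = std::max(m, at(r - 1, c));
      if (c > 0) m = std::max(m, at(r, c - 1));
      if (r > 0 && c > 0) m = std::max(m, at(r - 1, c - 1));
      if (r < nr - 1 && c > 0) m = std::max(m, at(r + 1, c - 1));
      at(r, c) = std::min(m, I(r, c));
    }
  }

  std::queue<int> fifo;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  // anti-raster scan with queue seeding
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      double m = at(r, c);
      if (r < nr - 1) m = std::max(m, at(r + 1, c));
      if (c < nc - 1) m = std::max(m, at(r, c + 1));
      if (r < nr - 1 && c < nc - 1) m = std::max(m, at(r + 1, c + 1));
      if (r > 0 && c < nc - 1) m = std::max(m, at(r - 1, c + 1));
      at(r, c) = std::min(m, I(r, c));
      // queue if some anti-raster neighbour could still be raised
      const double v = at(r, c);
      bool push = false;
      if (r < nr - 1 && at(r + 1, c) < v && at(r + 1, c) < I(r + 1, c)) push = true;
      if (!push && c < nc - 1 && at(r, c + 1) < v && at(r, c + 1) < I(r, c + 1)) push = true;
      if (!push && r < nr - 1 && c < nc - 1 && at(r + 1, c + 1) < v &&
          at(r + 1, c + 1) < I(r + 1, c + 1)) push = true;
      if (!push && r > 0 && c < nc - 1 && at(r - 1, c + 1) < v &&
          at(r - 1, c + 1) < I(r - 1, c + 1)) push = true;
      if (push) fifo.push(r + nr * c);
    }
  }

  while (!fifo.empty()) {
    const int p = fifo.front(); fifo.pop();
    const int r = p % nr, c = p / nr;
    const double v = at(r, c);
    for (int k = 0; k < 8; ++k) {
      const int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (at(rr, cc) < v && J(rr, cc) != I(rr, cc)) {
        at(rr, cc) = std::min(v, I(rr, cc));
        fifo.push(rr + nr * cc);
      }
    }
  }
  return J;
}
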