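#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Grayscale morphological reconstruction by dilation, 8-connectivity.
// Hybrid algorithm (Vincent 1993): one forward and one backward raster
// sweep followed by FIFO propagation of pixels left unstable.
// marker must be <= mask everywhere; the result is the largest image
// J <= mask reachable from marker by geodesic dilation.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilate(NumericMatrix marker, NumericMatrix mask) {
  const int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask dimensions differ");
  NumericMatrix J(clone(marker));
  for (int i = 0; i < nr * nc; ++i)
    if (J[i] > mask[i]) J[i] = mask[i];

  // neighbour offsets split into the sets scanned before (N+) and after
  // (N-) the current pixel in raster order
  const int dr_plus[4]  = {-1, -1, -1,  0};
  const int dc_plus[4]  = {-1,  0,  1, -1};
  const int dr_minus[4] = { 1,  1,  1,  0};
  const int dc_minus[4] = {-1,  0,  1,  1};

  // forward sweep (column-major raster; orientation is immaterial as long
  // as the two sweeps are opposed and the FIFO pass finishes the job)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = J(r, c);
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr_plus[k], cc = c + dc_plus[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && J(rr, cc) > v)
          v = J(rr, cc);
      }
      if (v > mask(r, c)) v = mask(r, c);
      J(r, c) = v;
    }
  }

  std::queue<int> fifo;
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      double v = J(r, c);
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr_minus[k], cc = c + dc_minus[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && J(rr, cc) > v)
          v = J(rr, cc);
      }
      if (v > mask(r, c)) v = mask(r, c);
      J(r, c) = v;
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr_minus[k], cc = c + dc_minus[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc &&
            J(rr, cc) < J(r, c) && J(rr, cc) < mask(rr, cc)) {
          fifo.push(r + nr * c);
          break;
        }
      }
    }
  }

  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!fifo.empty()) {
    int p = fifo.front(); fifo.pop();
    int r = p % nr, c = p / nr;
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr8[k], cc = c + dc8[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (J(rr, cc) < J(r, c) && mask(rr, cc) != J(rr, cc)) {
        double v = J(r, c) < mask(rr, cc) ? J(r, c) : mask(rr, cc);
        if (v > J(rr, cc)) {
          J(rr, cc) = v;
          fifo.push(rr + nr * cc);
        }
      }
    }
  }
  return J;
}

// Connected-component labelling of a logical matrix, 8-connectivity,
// labels assigned in raster (column-major) order of first encounter.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  int next = 0;
  std::queue<int> q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!x(r, c) || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      q.push(r + nr * c);
      while (!q.empty()) {
        int p = q.front(); q.pop();
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < 8; ++k) {
          int rr = pr + dr8[k], cc = pc + dc8[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (x(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(rr + nr * cc);
          }
        }
      }
    }
  }
  return lab;
}
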