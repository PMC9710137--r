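#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Grayscale reconstruction by erosion of `marker` constrained from below by
// `mask` (requires marker >= mask everywhere), 8-connectivity. Implemented as
// alternating forward/backward raster sweeps until a fixed point; this is the
// standard sequential reconstruction algorithm and converges in a handful of
// sweeps for the images this package sees.
// [[Rcpp::export(name = ".reconstruct_erode_cpp")]]
NumericMatrix reconstruct_erode_cpp(NumericMatrix marker, NumericMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask dimensions differ");
  NumericMatrix J(clone(marker));
  bool changed = true;
  int guard = 0;
  while (changed && guard++ < 4 * (nr + nc) + 8) {
    changed = false;
    // forward sweep: neighbours already visited in raster order
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        double m = J(r, c);
        for (int dc = -1; dc <= 0; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dc == 0 && dr >= 0) continue;
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (J(rr, cc) < m) m = J(rr, cc);
          }
        }
        m = std::max(m, mask(r, c));
        if (m != J(r, c)) { J(r, c) = m; changed = true; }
      }
    }
    // backward sweep
    for (int c = nc - 1; c >= 0; --c) {
      for (int r = nr - 1; r >= 0; --r) {
        double m = J(r, c);
        for (int dc = 0; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dc == 0 && dr <= 0) continue;
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (J(rr, cc) < m) m = J(rr, cc);
          }
        }
        m = std::max(m, mask(r, c));
        if (m != J(r, c)) { J(r, c) = m; changed = true; }
      }
    }
  }
  return J;
}

// Seeded region growing of the background region. Starts from the global
// minimum pixel (ties: smallest row-major linear index), then repeatedly
// admits the 4-connected frontier pixel whose intensity is closest to the
// running region mean, updating the mean after every admission, until the
// smallest |intensity - mean| exceeds `tol` or the frontier empties.
// Returns a logical matrix: TRUE = background (the grown region).
// [[Rcpp::export(name = ".region_grow_cpp")]]
LogicalMatrix region_grow_cpp(NumericMatrix img, double tol) {
  int nr = img.nrow(), nc = img.ncol();
  int n = nr * nc;
  std::vector<char> state(n, 0); // 0 free, 1 frontier, 2 region
  LogicalMatrix bg(nr, nc);

  // seed: global minimum, tie-break on smallest row-major index
  int seed = -1;
  double vmin = R_PosInf;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double v = img(r, c);
      if (v < vmin) { vmin = v; seed = r * nc + c; }
    }
  }
  if (seed < 0) return bg;

  double sum = 0.0;
  long count = 0;
  std::vector<int> frontier; // row-major linear indices
  frontier.reserve(4 * (nr + nc));

  int cur = seed;
  const int drs[4] = {-1, 1, 0, 0};
  const int dcs[4] = {0, 0, -1, 1};
  while (true) {
    int r = cur / nc, c = cur % nc;
    state[cur] = 2;
    sum += img(r, c);
    count += 1;
    bg(r, c) = true;
    double mean = sum / count;
    for (int k = 0; k < 4; ++k) {
      int rr = r + drs[k], cc = c + dcs[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int idx = rr * nc + cc;
      if (state[idx] == 0) { state[idx] = 1; frontier.push_back(idx); }
    }
    if (frontier.empty()) break;
    // frontier pixel minimising |I - mean|; tie -> smallest row-major index
    double best = R_PosInf;
    size_t bestPos = 0;
    for (size_t i = 0; i < frontier.size(); ++i) {
      int idx = frontier[i];
      double d = std::fabs(img(idx / nc, idx % nc) - mean);
      if (d < best || (d == best && idx < frontier[bestPos])) {
        best = d; bestPos = i;
      }
    }
    if (best > tol) break;
    cur = frontier[bestPos];
    frontier[bestPos] = frontier.back();
    frontier.pop_back();
  }
  return bg;
}
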