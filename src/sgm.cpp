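// Semi-global matching core: census cost volume, 8-path aggregation with the
// standard P1/P2 recurrence, and winner-take-all with parabolic subpixel
// refinement.  Cost volumes are integer arrays with dim (D, height, width),
// disparity index fastest.  All arithmetic is integer so an independent
// re-implementation can match it exactly.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Census descriptor per pixel over a (window x window) neighbourhood with
// border replication; bit set when the neighbour is strictly darker than the
// centre.  window must be odd and window*window - 1 <= 64.
static std::vector<uint64_t> census(const NumericMatrix &img, int window) {
  int h = img.nrow(), w = img.ncol(), r = window / 2;
  std::vector<uint64_t> out((size_t)h * w, 0);
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      double c = img(y, x);
      uint64_t code = 0;
      for (int dy = -r; dy <= r; ++dy) {
        for (int dx = -r; dx <= r; ++dx) {
          if (dx == 0 && dy == 0) continue;
          double v = img(clampi(y + dy, 0, h - 1), clampi(x + dx, 0, w - 1));
          code = (code << 1) | (v < c ? 1u : 0u);
        }
      }
      out[(size_t)x * h + y] = code;
    }
  }
  return out;
}

static inline int hamming64(uint64_t a, uint64_t b) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(a ^ b);
#else
  uint64_t x = a ^ b; int n = 0;
  while (x) { x &= x - 1; ++n; }
  return n;
#endif
}

// [[Rcpp::export(name = ".sgm_cost_volume_cpp")]]
IntegerVector sgm_cost_volume_cpp(NumericMatrix left, NumericMatrix right,
                                  int dmin, int dmax, int window) {
  int h = left.nrow(), w = left.ncol(), D = dmax - dmin + 1;
  if (right.nrow() != h || right.ncol() != w)
    stop("left and right images differ in size");
  std::vector<uint64_t> cl = census(left, window), cr = census(right, window);
  IntegerVector cost((R_xlen_t)D * h * w);
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y) {
      R_xlen_t base = ((R_xlen_t)x * h + y) * D;
      uint64_t cL = cl[(size_t)x * h + y];
      for (int di = 0; di < D; ++di) {
        int xr = x - (dmin + di);
        // out-of-range candidates are cost-neutral: they tie with everything
        // and the ambiguity flag invalidates the pixel downstream
        cost[base + di] = (xr < 0 || xr >= w)
          ? 0 : hamming64(cL, cr[(size_t)xr * h + y]);
      }
    }
  cost.attr("dim") = IntegerVector::create(D, h, w);
  return cost;
}

// Cost volume for the right image derived from the left one:
// C_R(x, d) = C_L(x + d, d); columns running off the image are cost-neutral.
// [[Rcpp::export(name = ".sgm_right_cost_cpp")]]
IntegerVector sgm_right_cost_cpp(IntegerVector costL, int dmin) {
  IntegerVector dim = costL.attr("dim");
  int D = dim[0], h = dim[1], w = dim[2];
  IntegerVector out((R_xlen_t)D * h * w);
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y) {
      R_xlen_t base = ((R_xlen_t)x * h + y) * D;
      for (int di = 0; di < D; ++di) {
        int xl = x + dmin + di;
        out[base + di] = (xl >= w) ? 0
          : costL[((R_xlen_t)xl * h + y) * D + di];
      }
    }
  out.attr("dim") = IntegerVector::create(D, h, w);
  return out;
}

// Aggregate one direction (dx, dy) into S.
static void aggregate_dir(const int *C, int *S, int D, int h, int w,
                          int P1, int P2, int dx, int dy) {
  std::vector<int> Lprev;          // scratch for L_r over the whole image
  std::vector<int> L((size_t)D * h * w);
  int x0 = dx >= 0 ? 0 : w - 1, x1 = dx >= 0 ? w : -1, xs = dx >= 0 ? 1 : -1;
  int y0 = dy >= 0 ? 0 : h - 1, y1 = dy >= 0 ? h : -1, ys = dy >= 0 ? 1 : -1;
  for (int x = x0; x != x1; x += xs) {
    for (int y = y0; y != y1; y += ys) {
      size_t p = ((size_t)x * h + y) * D;
      int xp = x - dx, yp = y - dy;
      if (xp < 0 || xp >= w || yp < 0 || yp >= h) {
        for (int d = 0; d < D; ++d) L[p + d] = C[p + d];
      } else {
        size_t q = ((size_t)xp * h + yp) * D;
        int minprev = L[q];
        for (int d = 1; d < D; ++d) minprev = std::min(minprev, L[q + d]);
        for (int d = 0; d < D; ++d) {
          int best = L[q + d];
          if (d > 0)     best = std::min(best, L[q + d - 1] + P1);
          if (d < D - 1) best = std::min(best, L[q + d + 1] + P1);
          best = std::min(best, minprev + P2);
          L[p + d] = C[p + d] + best - minprev;
        }
      }
    }
  }
  for (size_t i = 0; i < (size_t)D * h * w; ++i) S[i] += L[i];
}

// [[Rcpp::export(name = ".sgm_aggregate_cpp")]]
IntegerVector sgm_aggregate_cpp(IntegerVector cost, int P1, int P2, int paths) {
  IntegerVector dim = cost.attr("dim");
  int D = dim[0], h = dim[1], w = dim[2];
  if (paths != 4 && paths != 8) stop("paths must be 4 or 8");
  IntegerVector S((R_xlen_t)D * h * w, 0);
  const int dirs[8][2] = {{1, 0}, {-1, 0}, {0, 1}, {0, -1},
                          {1, 1}, {-1, -1}, {1, -1}, {-1, 1}};
  for (int k = 0; k < paths; ++k)
    aggregate_dir(cost.begin(), S.begin(), D, h, w, P1, P2,
                  dirs[k][0], dirs[k][1]);
  S.attr("dim") = IntegerVector::create(D, h, w);
  return S;
}

// Winner-take-all over the aggregated volume.  Ties go to the smallest
// disparity; `tie` flags pixels where the minimum recurs at a disparity more
// than one step away (featureless/ambiguous match).
// [[Rcpp::export(name = ".sgm_wta_cpp")]]
List sgm_wta_cpp(IntegerVector S, int dmin, bool subpixel) {
  IntegerVector dim = S.attr("dim");
  int D = dim[0], h = dim[1], w = dim[2];
  IntegerMatrix dint(h, w);
  NumericMatrix dsub(h, w);
  LogicalMatrix tie(h, w);
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y) {
      R_xlen_t base = ((R_xlen_t)x * h + y) * D;
      int best = 0;
      for (int d = 1; d < D; ++d)
        if (S[base + d] < S[base + best]) best = d;
      int m = S[base + best];
      bool ambiguous = false;
      for (int d = 0; d < D; ++d)
        if (S[base + d] == m && std::abs(d - best) > 1) { ambiguous = true; break; }
      dint(y, x) = dmin + best;
      tie(y, x) = ambiguous;
      double dd = dmin + best;
      if (subpixel && best > 0 && best < D - 1) {
        double c0 = S[base + best - 1], c1 = S[base + best],
               c2 = S[base + best + 1];
        double denom = c0 + c2 - 2.0 * c1;
        if (denom > 0) dd += (c0 - c2) / (2.0 * denom);
      }
      dsub(y, x) = dd;
    }
  return List::create(_["d_int"] = dint, _["d_sub"] = dsub, _["tie"] = tie);
}
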