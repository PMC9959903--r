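// Semi-global block matching core: 5x5 census transform, Hamming matching
// cost box-aggregated over the block window, 8-direction semi-global cost
// aggregation with P1/P2 smoothness penalties, winner-take-all with parabolic
// subpixel refinement, uniqueness-ratio and left-right consistency checks.
// Failed pixels are returned as NaN (disparity holes).

#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// 5x5 census transform (centre excluded -> 24 bits), border replicated
static void census5x5(const NumericMatrix &img, std::vector<uint32_t> &out) {
  const int h = img.nrow(), w = img.ncol();
  out.assign((size_t)h * w, 0u);
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      const double c = img(y, x);
      uint32_t bits = 0;
      for (int dy = -2; dy <= 2; ++dy) {
        for (int dx = -2; dx <= 2; ++dx) {
          if (dy == 0 && dx == 0) continue;
          const double v = img(clampi(y + dy, 0, h - 1), clampi(x + dx, 0, w - 1));
          bits = (bits << 1) | (v < c ? 1u : 0u);
        }
      }
      out[(size_t)y * w + x] = bits;
    }
  }
}

static inline int popcount32(uint32_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcount(x);
#else
  int n = 0; while (x) { x &= x - 1; ++n; } return n;
#endif
}

// [[Rcpp::export(name = ".sgbm_core")]]
List sgbm_core(NumericMatrix left, NumericMatrix right,
               int min_disp, int max_disp, int block_size,
               double P1, double P2,
               int uniqueness_ratio, double lr_tol) {
  const int h = left.nrow(), w = left.ncol();
  const int D = max_disp - min_disp;   // candidate d = min_disp + level
  const int br = block_size / 2;
  const int MAXC = 24;                      // census bits

  std::vector<uint32_t> cl, cr;
  census5x5(left, cl);
  census5x5(right, cr);

  // raw per-pixel Hamming cost, then box aggregation over the block window
  std::vector<int32_t> cost((size_t)h * w * D);
  {
    std::vector<int32_t> raw((size_t)h * w);
    std::vector<int64_t> rowsum((size_t)h * w);
    std::vector<int32_t> agg((size_t)h * w);
    for (int d = 0; d < D; ++d) {
      for (int y = 0; y < h; ++y)
        for (int x = 0; x < w; ++x) {
          const int xr = x - (d + min_disp);
          raw[(size_t)y * w + x] = (xr < 0)
            ? MAXC
            : popcount32(cl[(size_t)y * w + x] ^ cr[(size_t)y * w + xr]);
        }
      // horizontal then vertical box sums with replicated borders
      for (int y = 0; y < h; ++y) {
        int64_t s = 0;
        for (int k = -br; k <= br; ++k) s += raw[(size_t)y * w + clampi(k, 0, w - 1)];
        rowsum[(size_t)y * w + 0] = s;
        for (int x = 1; x < w; ++x) {
          s += raw[(size_t)y * w + clampi(x + br, 0, w - 1)];
          s -= raw[(size_t)y * w + clampi(x - br - 1, 0, w - 1)];
          rowsum[(size_t)y * w + x] = s;
        }
      }
      for (int x = 0; x < w; ++x) {
        int64_t s = 0;
        for (int k = -br; k <= br; ++k) s += rowsum[(size_t)clampi(k, 0, h - 1) * w + x];
        agg[(size_t)0 * w + x] = (int32_t)s;
        for (int y = 1; y < h; ++y) {
          s += rowsum[(size_t)clampi(y + br, 0, h - 1) * w + x];
          s -= rowsum[(size_t)clampi(y - br - 1, 0, h - 1) * w + x];
          agg[(size_t)y * w + x] = (int32_t)s;
        }
      }
      for (size_t i = 0; i < (size_t)h * w; ++i)
        cost[i * D + d] = agg[i];
    }
  }

  // semi-global aggregation over 8 directions
  const int dirs[8][2] = {{0,1},{0,-1},{1,0},{-1,0},{1,1},{1,-1},{-1,1},{-1,-1}};
  std::vector<int64_t> S((size_t)h * w * D, 0);
  std::vector<int32_t> L((size_t)h * w * D);
  const int32_t p1 = (int32_t)P1, p2 = (int32_t)P2;

  for (int dir = 0; dir < 8; ++dir) {
    const int dy = dirs[dir][0], dx = dirs[dir][1];
    const int y0 = dy >= 0 ? 0 : h - 1, y1 = dy >= 0 ? h : -1, ys = dy >= 0 ? 1 : -1;
    const int x0 = dx >= 0 ? 0 : w - 1, x1 = dx >= 0 ? w : -1, xs = dx >= 0 ? 1 : -1;
    for (int y = y0; y != y1; y += ys) {
      for (int x = x0; x != x1; x += xs) {
        const size_t p = (size_t)y * w + x;
        const int py = y - dy, px = x - dx;
        const bool has_prev = py >= 0 && py < h && px >= 0 && px < w;
        if (!has_prev) {
          for (int d = 0; d < D; ++d) L[p * D + d] = cost[p * D + d];
        } else {
          const size_t q = (size_t)py * w + px;
          int32_t minprev = std::numeric_limits<int32_t>::max();
          for (int d = 0; d < D; ++d) minprev = std::min(minprev, L[q * D + d]);
          for (int d = 0; d < D; ++d) {
            int32_t best = L[q * D + d];
            if (d > 0)     best = std::min(best, L[q * D + d - 1] + p1);
            if (d < D - 1) best = std::min(best, L[q * D + d + 1] + p1);
            best = std::min(best, minprev + p2);
            L[p * D + d] = cost[p * D + d] + best - minprev;
          }
        }
        for (int d = 0; d < D; ++d) S[p * D + d] += L[p * D + d];
      }
    }
  }

  // winner-take-all on the left image with subpixel parabola
  NumericMatrix disp(h, w);
  std::vector<int> dint((size_t)h * w, -1);
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      const size_t p = (size_t)y * w + x;
      int best_d = 0; int64_t best_s = S[p * D + 0];
      for (int d = 1; d < D; ++d)
        if (S[p * D + d] < best_s) { best_s = S[p * D + d]; best_d = d; }
      // uniqueness: any cost outside d* +/- 1 within the ratio invalidates
      bool unique = true;
      if (uniqueness_ratio > 0) {
        for (int d = 0; d < D && unique; ++d) {
          if (std::abs(d - best_d) <= 1) continue;
          if ((double)S[p * D + d] * 100.0 < (double)best_s * (100.0 + uniqueness_ratio))
            unique = false;
        }
      }
      if (!unique || x - (best_d + min_disp) < 0) { disp(y, x) = NA_REAL; continue; }
      double dsub = best_d + min_disp;
      if (best_d > 0 && best_d < D - 1) {
        const double c0 = (double)S[p * D + best_d - 1];
        const double c1 = (double)S[p * D + best_d];
        const double c2 = (double)S[p * D + best_d + 1];
        const double denom = c0 - 2.0 * c1 + c2;
        if (denom > 1e-9) {
          double off = (c0 - c2) / (2.0 * denom);
          if (off > -1.0 && off < 1.0) dsub += off;
        }
      }
      disp(y, x) = dsub;
      dint[p] = best_d;
    }
  }

  // right-image WTA from the same aggregated volume, then LR consistency
  if (lr_tol >= 0) {
    std::vector<int> dr((size_t)h * w, -1);
    for (int y = 0; y < h; ++y) {
      for (int xr = 0; xr < w; ++xr) {
        int best_d = -1; int64_t best_s = std::numeric_limits<int64_t>::max();
        for (int d = 0; d < D; ++d) {
          const int xl = xr + d + min_disp;
          if (xl >= w) break;
          const int64_t s = S[((size_t)y * w + xl) * D + d];
          if (s < best_s) { best_s = s; best_d = d; }
        }
        dr[(size_t)y * w + xr] = best_d;
      }
    }
    for (int y = 0; y < h; ++y) {
      for (int x = 0; x < w; ++x) {
        const size_t p = (size_t)y * w + x;
        if (dint[p] < 0) continue;
        const int xr = x - (dint[p] + min_disp);
        const int drv = (xr >= 0) ? dr[(size_t)y * w + xr] : -1;
        if (drv < 0 || std::abs(drv - dint[p]) > lr_tol) disp(y, x) = NA_REAL;
      }
    }
  }

  return List::create(_["disparity"] = disp);
}

// brute-force nearest neighbour from each query point to the reference cloud;
// returns 1-based indices and Euclidean distances
// [[Rcpp::export(name = ".nn_bruteforce")]]
List nn_bruteforce(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  std::vector<double> rx(nr), ry(nr), rz(nr);
  for (int j = 0; j < nr; ++j) { rx[j] = ref(j,0); ry[j] = ref(j,1); rz[j] = ref(j,2); }
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i,0), qy = query(i,1), qz = query(i,2);
    double best = std::numeric_limits<double>::max();
    int bj = 0;
    for (int j = 0; j < nr; ++j) {
      const double dx = qx - rx[j], dy = qy - ry[j], dz = qz - rz[j];
      const double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
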