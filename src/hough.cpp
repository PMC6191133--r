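#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Hough gradient circle transform.
//
// The input raster is indexed L(x, y) with x along rows (width) and y along
// columns (height), matching the package's image convention, values on the
// 8-bit 0..255 scale. Edge pixels are Sobel responses whose L1 magnitude
// reaches edge_thresh (the OpenCV Canny convention of an L1 gradient norm
// against the high threshold; no hysteresis pass). Each edge pixel votes
// along its gradient line, in both directions, once per candidate radius;
// circle centres are accumulator local maxima with at least acc_thresh
// votes, thinned greedily by vote count under a minimum separation, then
// refined to sub-pixel position by the 3x3 accumulator centroid. The radius
// reported per circle is the mode of the supporting edge-pixel distances.
//
// Everything is deterministic: ties in vote count break on scan order.

struct Cand {
  int votes;
  int x, y;
};

// [[Rcpp::export]]
List hough_circles_cpp(NumericMatrix L, double edge_thresh, double acc_thresh,
                       double min_r, double max_r, double min_dist) {
  const int W = L.nrow(), H = L.ncol();
  if (W < 3 || H < 3)
    return List::create(_["centres"] = NumericMatrix(0, 2),
                        _["radii"] = NumericVector(0),
                        _["votes"] = IntegerVector(0));

  std::vector<int> acc((size_t)W * H, 0);
  std::vector<int> ex, ey;
  std::vector<double> eux, euy;
  ex.reserve(1 << 14); ey.reserve(1 << 14);

  for (int y = 1; y < H - 1; ++y) {
    for (int x = 1; x < W - 1; ++x) {
      const double gx =
          (L(x + 1, y - 1) + 2 * L(x + 1, y) + L(x + 1, y + 1)) -
          (L(x - 1, y - 1) + 2 * L(x - 1, y) + L(x - 1, y + 1));
      const double gy =
          (L(x - 1, y + 1) + 2 * L(x, y + 1) + L(x + 1, y + 1)) -
          (L(x - 1, y - 1) + 2 * L(x, y - 1) + L(x + 1, y - 1));
      if (std::fabs(gx) + std::fabs(gy) < edge_thresh) continue;
      const double m2 = std::sqrt(gx * gx + gy * gy);
      if (m2 <= 0) continue;
      ex.push_back(x); ey.push_back(y);
      eux.push_back(gx / m2); euy.push_back(gy / m2);
    }
  }

  const int nEdge = (int)ex.size();
  for (int i = 0; i < nEdge; ++i) {
    for (int sgn = -1; sgn <= 1; sgn += 2) {
      for (double r = min_r; r <= max_r + 1e-9; r += 1.0) {
        const int cx = (int)std::lround(ex[i] + sgn * eux[i] * r);
        const int cy = (int)std::lround(ey[i] + sgn * euy[i] * r);
        if (cx < 0 || cx >= W || cy < 0 || cy >= H) continue;
        ++acc[(size_t)cx + (size_t)cy * W];
      }
    }
  }

  // local maxima (strict against already-scanned neighbours so plateaus
  // yield a single, deterministic peak)
  std::vector<Cand> cands;
  for (int y = 1; y < H - 1; ++y) {
    for (int x = 1; x < W - 1; ++x) {
      const int v = acc[(size_t)x + (size_t)y * W];
      if (v < acc_thresh) continue;
      bool peak = true;
      for (int dy = -1; dy <= 1 && peak; ++dy)
        for (int dx = -1; dx <= 1 && peak; ++dx) {
          if (dx == 0 && dy == 0) continue;
          const int nv = acc[(size_t)(x + dx) + (size_t)(y + dy) * W];
          if (dy < 0 || (dy == 0 && dx < 0)) {   // scanned earlier
            if (nv >= v) peak = false;
          } else {
            if (nv > v) peak = false;
          }
        }
      if (peak) cands.push_back({v, x, y});
    }
  }

  std::sort(cands.begin(), cands.end(), [](const Cand &a, const Cand &b) {
    if (a.votes != b.votes) return a.votes > b.votes;
    if (a.y != b.y) return a.y < b.y;
    return a.x < b.x;
  });

  const double md2 = min_dist * min_dist;
  std::vector<double> accX, accY;
  std::vector<int> accV;
  for (const Cand &c : cands) {
    bool ok = true;
    for (size_t k = 0; k < accX.size(); ++k) {
      const double dx = accX[k] - c.x, dy = accY[k] - c.y;
      if (dx * dx + dy * dy < md2) { ok = false; break; }
    }
    if (!ok) continue;
    // sub-pixel refinement: vote-weighted centroid of the 3x3 window
    double sw = 0, sx = 0, sy = 0;
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const double w = acc[(size_t)(c.x + dx) + (size_t)(c.y + dy) * W];
        sw += w; sx += w * (c.x + dx); sy += w * (c.y + dy);
      }
    accX.push_back(sw > 0 ? sx / sw : c.x);
    accY.push_back(sw > 0 ? sy / sw : c.y);
    accV.push_back(c.votes);
  }

  // per-circle radius: mode (1-px bins) of supporting edge distances,
  // then centre + radius refinement by an algebraic (Kasa) circle fit to
  // the edge pixels of the winning ring
  const int n = (int)accX.size();
  NumericVector radii(n);
  const int nbin = (int)std::floor(max_r) + 2;
  for (int k = 0; k < n; ++k) {
    std::vector<int> hist(nbin + 1, 0);
    std::vector<double> sum(nbin + 1, 0.0);
    for (int i = 0; i < nEdge; ++i) {
      const double dx = ex[i] - accX[k], dy = ey[i] - accY[k];
      const double d = std::sqrt(dx * dx + dy * dy);
      if (d < min_r - 1.0 || d > max_r + 1.0) continue;
      const int b = (int)std::lround(d);
      if (b >= 0 && b <= nbin) { ++hist[b]; sum[b] += d; }
    }
    int best = 0;
    for (int b = 1; b <= nbin; ++b)
      if (hist[b] > hist[best]) best = b;
    double rEst = hist[best] > 0 ? sum[best] / hist[best] : NA_REAL;

    if (hist[best] >= 6) {
      // Kasa fit on pixels within 1.5 px of the winning ring, in
      // coordinates relative to the current centre estimate: minimise
      // sum (x^2 + y^2 + D x + E y + F)^2 over D, E, F
      for (int pass = 0; pass < 2; ++pass) {
        double Sxx = 0, Sxy = 0, Syy = 0, Sx = 0, Sy = 0, S1 = 0;
        double Sxz = 0, Syz = 0, Sz = 0;
        for (int i = 0; i < nEdge; ++i) {
          const double x = ex[i] - accX[k], y = ey[i] - accY[k];
          const double d = std::sqrt(x * x + y * y);
          if (std::fabs(d - rEst) > 1.5) continue;
          const double z = x * x + y * y;
          Sxx += x * x; Sxy += x * y; Syy += y * y;
          Sx += x; Sy += y; S1 += 1;
          Sxz += x * z; Syz += y * z; Sz += z;
        }
        if (S1 < 6) break;
        // solve [Sxx Sxy Sx; Sxy Syy Sy; Sx Sy S1] [D E F]' = -[Sxz Syz Sz]'
        const double a11 = Sxx, a12 = Sxy, a13 = Sx;
        const double a22 = Syy, a23 = Sy, a33 = S1;
        const double det = a11 * (a22 * a33 - a23 * a23) -
                           a12 * (a12 * a33 - a23 * a13) +
                           a13 * (a12 * a23 - a22 * a13);
        if (std::fabs(det) < 1e-9) break;
        const double b1 = -Sxz, b2 = -Syz, b3 = -Sz;
        const double D = (b1 * (a22 * a33 - a23 * a23) -
                          a12 * (b2 * a33 - a23 * b3) +
                          a13 * (b2 * a23 - a22 * b3)) / det;
        const double E = (a11 * (b2 * a33 - b3 * a23) -
                          b1 * (a12 * a33 - a23 * a13) +
                          a13 * (a12 * b3 - b2 * a13)) / det;
        const double F = (a11 * (a22 * b3 - b2 * a23) -
                          a12 * (a12 * b3 - b2 * a13) +
                          b1 * (a12 * a23 - a22 * a13)) / det;
        const double cx = -D / 2, cy = -E / 2;
        const double r2 = cx * cx + cy * cy - F;
        if (r2 <= 0) break;
        const double rNew = std::sqrt(r2);
        // reject degenerate fits that wander off the candidate
        if (cx * cx + cy * cy > 4.0 || rNew < min_r - 1 || rNew > max_r + 1)
          break;
        accX[k] += cx; accY[k] += cy;
        rEst = rNew;
      }
    }
    radii[k] = rEst;
  }

  NumericMatrix centres(n, 2);
  IntegerVector votes(n);
  for (int k = 0; k < n; ++k) {
    centres(k, 0) = accX[k];
    centres(k, 1) = accY[k];
    votes[k] = accV[k];
  }
  colnames(centres) = CharacterVector::create("x", "y");
  return List::create(_["centres"] = centres, _["radii"] = radii,
                      _["votes"] = votes);
}
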