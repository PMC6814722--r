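#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact k-nearest-neighbour inverse-distance-squared interpolation of the
// ground surface at query locations, used to normalize vegetation returns
// to height above ground. Ground points are bucketed on a uniform grid and
// searched in expanding rings, so the search stays exact but near-linear
// for the multi-million-point clouds a transect produces. Distance ties
// break by input order (smaller index wins) for determinism.

struct Hit {
  double d2;
  int idx;
};

static inline bool hit_less(const Hit &a, const Hit &b) {
  return a.d2 < b.d2 || (a.d2 == b.d2 && a.idx < b.idx);
}

// [[Rcpp::export]]
NumericVector knn_idw_ground(NumericVector gx, NumericVector gy,
                             NumericVector gz, NumericVector qx,
                             NumericVector qy, int k) {
  const int ng = gx.size(), nq = qx.size();
  if (ng == 0) stop("no ground points available for normalization");
  if (k < 1) stop("k must be >= 1");
  const int kk = std::min(k, ng);

  double xmin = gx[0], xmax = gx[0], ymin = gy[0], ymax = gy[0];
  for (int i = 1; i < ng; ++i) {
    xmin = std::min(xmin, gx[i]); xmax = std::max(xmax, gx[i]);
    ymin = std::min(ymin, gy[i]); ymax = std::max(ymax, gy[i]);
  }
  const double ex = xmax - xmin, ey = ymax - ymin;
  // aim for ~2 ground points per bucket
  double h = std::sqrt(std::max(ex * ey, 1e-12) * 2.0 / ng);
  if (h <= 0 || !std::isfinite(h)) h = 1.0;
  int nbx = std::max(1, (int)std::floor(ex / h) + 1);
  int nby = std::max(1, (int)std::floor(ey / h) + 1);
  // cap the bucket table so tiny clouds over huge extents stay cheap
  while ((double)nbx * nby > 4.0 * ng + 16.0) {
    h *= 2.0;
    nbx = std::max(1, (int)std::floor(ex / h) + 1);
    nby = std::max(1, (int)std::floor(ey / h) + 1);
  }

  std::vector<std::vector<int> > buckets((size_t)nbx * nby);
  for (int i = 0; i < ng; ++i) {
    int bx = std::min(nbx - 1, (int)std::floor((gx[i] - xmin) / h));
    int by = std::min(nby - 1, (int)std::floor((gy[i] - ymin) / h));
    buckets[(size_t)by * nbx + bx].push_back(i);
  }

  NumericVector out(nq);
  std::vector<Hit> best;
  best.reserve(kk + 8);
  for (int q = 0; q < nq; ++q) {
    best.clear();
    int bx = (int)std::floor((qx[q] - xmin) / h);
    int by = (int)std::floor((qy[q] - ymin) / h);
    bx = std::max(0, std::min(nbx - 1, bx));
    by = std::max(0, std::min(nby - 1, by));
    const int max_ring = std::max(nbx, nby);
    for (int ring = 0; ring <= max_ring; ++ring) {
      // once kk hits are held, a further ring cannot beat the current
      // worst unless its nearest possible point is closer
      if ((int)best.size() >= kk) {
        double dmin = (ring - 1) * h;  // lower bound for cells in this ring
        if (dmin > 0 && dmin * dmin > best[kk - 1].d2) break;
      }
      int x0 = bx - ring, x1 = bx + ring, y0 = by - ring, y1 = by + ring;
      for (int yy = y0; yy <= y1; ++yy) {
        if (yy < 0 || yy >= nby) continue;
        for (int xx = x0; xx <= x1; ++xx) {
          if (xx < 0 || xx >= nbx) continue;
          if (ring > 0 && xx != x0 && xx != x1 && yy != y0 && yy != y1)
            continue;  // interior cells already visited
          const std::vector<int> &b = buckets[(size_t)yy * nbx + xx];
          for (size_t j = 0; j < b.size(); ++j) {
            const int i = b[j];
            const double dx = gx[i] - qx[q], dy = gy[i] - qy[q];
            Hit hnew = {dx * dx + dy * dy, i};
            if ((int)best.size() < kk) {
              best.push_back(hnew);
              std::sort(best.begin(), best.end(), hit_less);
            } else if (hit_less(hnew, best[kk - 1])) {
              best[kk - 1] = hnew;
              std::sort(best.begin(), best.end(), hit_less);
            }
          }
        }
      }
    }
    if (best[0].d2 == 0.0) {
      out[q] = gz[best[0].idx];  // exact hit on a ground point
    } else {
      double sw = 0.0, swz = 0.0;
      for (int j = 0; j < (int)best.size(); ++j) {
        const double w = 1.0 / best[j].d2;
        sw += w;
        swz += w * gz[best[j].idx];
      }
      out[q] = swz / sw;
    }
  }
  return out;
}
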