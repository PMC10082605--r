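#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sliding-window median with edge replication. Window is odd-sized.
// [[Rcpp::export]]
IntegerMatrix cpp_median_filter(const IntegerMatrix& img, int window) {
  const int nr = img.nrow(), nc = img.ncol(), h = window / 2;
  IntegerMatrix out(nr, nc);
  std::vector<int> buf(window * window);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int n = 0;
      for (int dj = -h; dj <= h; ++dj) {
        int cj = std::min(std::max(j + dj, 0), nc - 1);
        for (int di = -h; di <= h; ++di) {
          int ci = std::min(std::max(i + di, 0), nr - 1);
          buf[n++] = img(ci, cj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.begin() + n);
      out(i, j) = buf[n / 2];
    }
  }
  return out;
}

static inline double seg_dist(double px, double py, double ax, double ay,
                              double bx, double by) {
  const double dx = bx - ax, dy = by - ay;
  const double len2 = dx * dx + dy * dy;
  double t = len2 > 0 ? ((px - ax) * dx + (py - ay) * dy) / len2 : 0.0;
  t = std::min(std::max(t, 0.0), 1.0);
  const double qx = ax + t * dx, qy = ay + t * dy;
  return std::sqrt((px - qx) * (px - qx) + (py - qy) * (py - qy));
}

// Rasterize one anti-aliased thick polyline onto `canvas` (modified in place).
// `pts` is an n x 2 matrix of (row, col) control points in pixel units.
// Coverage ramps linearly over one pixel at the stroke edge; the stroke is
// combined with the existing canvas by per-pixel maximum.
// [[Rcpp::export]]
void cpp_draw_polyline(NumericMatrix canvas, const NumericMatrix& pts,
                       double half_width, double intensity) {
  const int nr = canvas.nrow(), nc = canvas.ncol(), np = pts.nrow();
  if (np < 2) return;
  double rmin = R_PosInf, rmax = R_NegInf, cmin = R_PosInf, cmax = R_NegInf;
  for (int k = 0; k < np; ++k) {
    rmin = std::min(rmin, pts(k, 0)); rmax = std::max(rmax, pts(k, 0));
    cmin = std::min(cmin, pts(k, 1)); cmax = std::max(cmax, pts(k, 1));
  }
  const double pad = half_width + 1.5;
  const int r0 = std::max(0, (int)std::floor(rmin - pad));
  const int r1 = std::min(nr - 1, (int)std::ceil(rmax + pad));
  const int c0 = std::max(0, (int)std::floor(cmin - pad));
  const int c1 = std::min(nc - 1, (int)std::ceil(cmax + pad));
  for (int j = c0; j <= c1; ++j) {
    for (int i = r0; i <= r1; ++i) {
      double d = R_PosInf;
      for (int k = 0; k + 1 < np; ++k)
        d = std::min(d, seg_dist((double)i, (double)j, pts(k, 0), pts(k, 1),
                                 pts(k + 1, 0), pts(k + 1, 1)));
      const double cov = std::min(std::max(half_width + 0.5 - d, 0.0), 1.0);
      if (cov > 0) canvas(i, j) = std::max(canvas(i, j), intensity * cov);
    }
  }
}

// Zhang-Suen thinning of a binary mask to a 1-px skeleton.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<unsigned char> im(nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) im[i + j * nr] = mask(i, j) ? 1 : 0;
  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return 0;
    return im[i + j * nr];
  };
  bool changed = true;
  std::vector<int> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!at(i, j)) continue;
          // clockwise neighbours p2..p9 starting from north
          const int p2 = at(i - 1, j), p3 = at(i - 1, j + 1), p4 = at(i, j + 1),
                    p5 = at(i + 1, j + 1), p6 = at(i + 1, j),
                    p7 = at(i + 1, j - 1), p8 = at(i, j - 1),
                    p9 = at(i - 1, j - 1);
          const int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (b < 2 || b > 6) continue;
          int a = 0;
          const int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          for (int k = 0; k < 8; ++k)
            if (seq[k] == 0 && seq[k + 1] == 1) ++a;
          if (a != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(i + j * nr);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k) im[kill[k]] = 0;
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) out(i, j) = im[i + j * nr] != 0;
  return out;
}

// Trace 8-connected skeleton segments after removing branch points
// (pixels with >2 skeleton neighbours). Returns a list of m x 2 integer
// matrices of 1-based (row, col) coordinates ordered along each segment.
// [[Rcpp::export]]
List cpp_trace_segments(const LogicalMatrix& skel) {
  const int nr = skel.nrow(), nc = skel.ncol();
  std::vector<unsigned char> im(nr * nc, 0);
  auto idx = [&](int i, int j) { return i + j * nr; };
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) im[idx(i, j)] = skel(i, j) ? 1 : 0;
  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return 0;
    return im[idx(i, j)];
  };
  const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  // remove branch points
  std::vector<int> branch;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!at(i, j)) continue;
      int deg = 0;
      for (int k = 0; k < 8; ++k) deg += at(i + di[k], j + dj[k]);
      if (deg > 2) branch.push_back(idx(i, j));
    }
  for (size_t k = 0; k < branch.size(); ++k) im[branch[k]] = 0;

  std::vector<unsigned char> seen(nr * nc, 0);
  List out;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!at(i, j) || seen[idx(i, j)]) continue;
      // collect the connected component
      std::vector<int> comp;
      std::vector<int> stack(1, idx(i, j));
      seen[idx(i, j)] = 1;
      while (!stack.empty()) {
        const int cur = stack.back(); stack.pop_back();
        comp.push_back(cur);
        const int ci = cur % nr, cj = cur / nr;
        for (int k = 0; k < 8; ++k) {
          const int ni = ci + di[k], nj = cj + dj[k];
          if (at(ni, nj) && !seen[idx(ni, nj)]) {
            seen[idx(ni, nj)] = 1;
            stack.push_back(idx(ni, nj));
          }
        }
      }
      // degree within the component; pick an endpoint (degree <= 1) as start
      int start = comp[0];
      for (size_t k = 0; k < comp.size(); ++k) {
        const int ci = comp[k] % nr, cj = comp[k] / nr;
        int deg = 0;
        for (int m = 0; m < 8; ++m) deg += at(ci + di[m], cj + dj[m]);
        if (deg <= 1) { start = comp[k]; break; }
      }
      // walk along the segment
      std::vector<unsigned char> walked(comp.size(), 0);
      std::vector<int> path;
      std::vector<int> order(comp.size());
      // map pixel -> local index for walk bookkeeping
      std::vector<int> local(comp.size());
      for (size_t k = 0; k < comp.size(); ++k) local[k] = comp[k];
      auto find_local = [&](int px) -> int {
        for (size_t k = 0; k < local.size(); ++k)
          if (local[k] == px) return (int)k;
        return -1;
      };
      int cur = start;
      walked[find_local(cur)] = 1;
      path.push_back(cur);
      bool moved = true;
      while (moved) {
        moved = false;
        const int ci = cur % nr, cj = cur / nr;
        for (int k = 0; k < 8; ++k) {
          const int ni = ci + di[k], nj = cj + dj[k];
          if (!at(ni, nj)) continue;
          const int lk = find_local(idx(ni, nj));
          if (lk >= 0 && !walked[lk]) {
            walked[lk] = 1;
            cur = idx(ni, nj);
            path.push_back(cur);
            moved = true;
            break;
          }
        }
      }
      IntegerMatrix m((int)path.size(), 2);
      for (size_t k = 0; k < path.size(); ++k) {
        m(k, 0) = path[k] % nr + 1;
        m(k, 1) = path[k] / nr + 1;
      }
      out.push_back(m);
    }
  }
  return out;
}

// Symmetric gray-level co-occurrence counts. `codes` holds levels in
// [0, levels); `offsets` is k x 2 (row offset, col offset). Each offset is
// accumulated together with its opposite.
// [[Rcpp::export]]
NumericMatrix cpp_glcm_counts(const IntegerMatrix& codes, int levels,
                              const IntegerMatrix& offsets) {
  const int nr = codes.nrow(), nc = codes.ncol(), no = offsets.nrow();
  NumericMatrix counts(levels, levels);
  for (int o = 0; o < no; ++o) {
    const int oi = offsets(o, 0), oj = offsets(o, 1);
    for (int j = 0; j < nc; ++j) {
      const int j2 = j + oj;
      if (j2 < 0 || j2 >= nc) continue;
      for (int i = 0; i < nr; ++i) {
        const int i2 = i + oi;
        if (i2 < 0 || i2 >= nr) continue;
        const int a = codes(i, j), b = codes(i2, j2);
        counts(a, b) += 1.0;
        counts(b, a) += 1.0;  // opposite offset
      }
    }
  }
  return counts;
}

// One-vs-rest linear SGD with modified-huber loss and elastic-net penalty,
// constant learning rate. `order` is an (epochs x n) matrix of 1-based
// sample indices giving the visit order per epoch (generated in R so that
// determinism follows R's RNG). Returns list(weights = K x p, intercept = K).
// [[Rcpp::export]]
List cpp_sgd_fit(const NumericMatrix& X, const IntegerVector& y, int n_classes,
                 double alpha, double l1_ratio, double eta0,
                 const IntegerMatrix& order) {
  const int n = X.nrow(), p = X.ncol(), epochs = order.nrow();
  NumericMatrix W(n_classes, p);
  NumericVector b(n_classes);
  const double l2 = alpha * (1.0 - l1_ratio), l1 = alpha * l1_ratio;
  for (int k = 0; k < n_classes; ++k) {
    for (int e = 0; e < epochs; ++e) {
      for (int t = 0; t < n; ++t) {
        const int s = order(e, t) - 1;
        const double ys = (y[s] == k) ? 1.0 : -1.0;
        double f = b[k];
        for (int q = 0; q < p; ++q) f += W(k, q) * X(s, q);
        const double z = ys * f;
        double dldf = 0.0;  // dL/df for modified huber
        if (z < -1.0) dldf = -4.0 * ys;
        else if (z < 1.0) dldf = -2.0 * (1.0 - z) * ys;
        for (int q = 0; q < p; ++q) {
          const double w = W(k, q);
          const double sgn = (w > 0) - (w < 0);
          W(k, q) = w - eta0 * (dldf * X(s, q) + l2 * w + l1 * sgn);
        }
        b[k] -= eta0 * dldf;  // intercept not penalized
      }
    }
  }
  return List::create(_["weights"] = W, _["intercept"] = b);
}
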