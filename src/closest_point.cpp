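// Closest point on a triangulated surface, accelerated by a uniform grid
// over triangle bounding boxes. Exact point-to-triangle distance follows the
// standard region decomposition (Ericson, Real-Time Collision Detection).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3 operator-(const Vec3& o) const { return {x - o.x, y - o.y, z - o.z}; }
  Vec3 operator+(const Vec3& o) const { return {x + o.x, y + o.y, z + o.z}; }
  Vec3 operator*(double s) const { return {x * s, y * s, z * s}; }
};
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

// closest point on triangle (a,b,c) to p
static Vec3 closestOnTriangle(const Vec3& p, const Vec3& a, const Vec3& b,
                              const Vec3& c) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return a + ab * v;
  }
  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return a + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + ab * v + ac * w;
}

// [[Rcpp::export(name = ".closest_points_cpp")]]
List closest_points_cpp(NumericMatrix query, NumericMatrix vertices,
                        IntegerMatrix triangles) {
  const int nq = query.nrow(), nt = triangles.nrow();
  std::vector<Vec3> V(vertices.nrow());
  for (int i = 0; i < vertices.nrow(); ++i)
    V[i] = {vertices(i, 0), vertices(i, 1), vertices(i, 2)};

  // grid over the union of triangle bounding boxes
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  double mean_edge = 0.0;
  for (int t = 0; t < nt; ++t) {
    const Vec3& a = V[triangles(t, 0) - 1];
    const Vec3& b = V[triangles(t, 1) - 1];
    const Vec3& c = V[triangles(t, 2) - 1];
    double tl[3] = {std::min({a.x, b.x, c.x}), std::min({a.y, b.y, c.y}),
                    std::min({a.z, b.z, c.z})};
    double th[3] = {std::max({a.x, b.x, c.x}), std::max({a.y, b.y, c.y}),
                    std::max({a.z, b.z, c.z})};
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], tl[d]);
      hi[d] = std::max(hi[d], th[d]);
    }
    Vec3 e = b - a;
    mean_edge += std::sqrt(dot(e, e));
  }
  mean_edge /= std::max(nt, 1);
  double cell = std::max(mean_edge * 2.0, 1e-9);
  int dims[3];
  for (int d = 0; d < 3; ++d) {
    dims[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / cell) + 1);
    dims[d] = std::min(dims[d], 128);
  }
  double cw[3];
  for (int d = 0; d < 3; ++d)
    cw[d] = std::max((hi[d] - lo[d]) / dims[d], 1e-9);

  auto cellIndex = [&](double v, int d) {
    int i = (int)std::floor((v - lo[d]) / cw[d]);
    return std::min(std::max(i, 0), dims[d] - 1);
  };
  std::vector<std::vector<int>> grid((size_t)dims[0] * dims[1] * dims[2]);
  auto flat = [&](int i, int j, int k) {
    return ((size_t)k * dims[1] + j) * dims[0] + i;
  };
  for (int t = 0; t < nt; ++t) {
    const Vec3& a = V[triangles(t, 0) - 1];
    const Vec3& b = V[triangles(t, 1) - 1];
    const Vec3& c = V[triangles(t, 2) - 1];
    int i0 = cellIndex(std::min({a.x, b.x, c.x}), 0);
    int i1 = cellIndex(std::max({a.x, b.x, c.x}), 0);
    int j0 = cellIndex(std::min({a.y, b.y, c.y}), 1);
    int j1 = cellIndex(std::max({a.y, b.y, c.y}), 1);
    int k0 = cellIndex(std::min({a.z, b.z, c.z}), 2);
    int k1 = cellIndex(std::max({a.z, b.z, c.z}), 2);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          grid[flat(i, j, k)].push_back(t);
  }

  NumericMatrix out(nq, 3);
  NumericVector dist(nq);
  int maxdim = std::max({dims[0], dims[1], dims[2]});
  for (int q = 0; q < nq; ++q) {
    Vec3 p = {query(q, 0), query(q, 1), query(q, 2)};
    int ci = cellIndex(p.x, 0), cj = cellIndex(p.y, 1), ck = cellIndex(p.z, 2);
    double best = std::numeric_limits<double>::infinity();
    Vec3 bestPt = p;
    for (int ring = 0; ring <= maxdim; ++ring) {
      // search the shell of cells at Chebyshev radius `ring`
      bool any = false;
      for (int k = std::max(ck - ring, 0);
           k <= std::min(ck + ring, dims[2] - 1); ++k)
        for (int j = std::max(cj - ring, 0);
             j <= std::min(cj + ring, dims[1] - 1); ++j)
          for (int i = std::max(ci - ring, 0);
               i <= std::min(ci + ring, dims[0] - 1); ++i) {
            if (ring > 0 && std::abs(i - ci) != ring &&
                std::abs(j - cj) != ring && std::abs(k - ck) != ring)
              continue;
            for (int t : grid[flat(i, j, k)]) {
              any = true;
              Vec3 cp = closestOnTriangle(p, V[triangles(t, 0) - 1],
                                          V[triangles(t, 1) - 1],
                                          V[triangles(t, 2) - 1]);
              Vec3 dvec = p - cp;
              double d2 = dot(dvec, dvec);
              if (d2 < best) { best = d2; bestPt = cp; }
            }
          }
      // safe stop: anything in a farther shell is at least `ring` cell
      // widths away (in the smallest cell dimension)
      double guard = ring * std::min({cw[0], cw[1], cw[2]});
      if (std::isfinite(best) && best <= guard * guard) break;
      (void)any;
    }
    out(q, 0) = bestPt.x; out(q, 1) = bestPt.y; out(q, 2) = bestPt.z;
    dist[q] = std::sqrt(best);
  }
  return List::create(Named("points") = out, Named("distance") = dist);
}
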