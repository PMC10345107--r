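// Incremental 3D convex hull (quickhull-style visibility test) used to
// build the fixed Delaunay topology of the envelope from points on a
// sphere.  All input points are expected to be in convex position; points
// found inside the running hull are rejected with an error because the
// envelope contract requires every vertex to carry springs.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <map>
using namespace Rcpp;

namespace {

struct Face {
  int a, b, c;
  bool alive;
};

inline void cross3(const double* u, const double* v, double* w) {
  w[0] = u[1] * v[2] - u[2] * v[1];
  w[1] = u[2] * v[0] - u[0] * v[2];
  w[2] = u[0] * v[1] - u[1] * v[0];
}

// signed volume of tetrahedron (a,b,c,p); > 0 when p is on the outward
// normal side of triangle (a,b,c)
inline double orient(const std::vector<double>& P, int a, int b, int c,
                     const double* p) {
  double u[3], v[3], w[3], n[3];
  for (int k = 0; k < 3; ++k) {
    u[k] = P[3 * b + k] - P[3 * a + k];
    v[k] = P[3 * c + k] - P[3 * a + k];
    w[k] = p[k] - P[3 * a + k];
  }
  cross3(u, v, n);
  return n[0] * w[0] + n[1] * w[1] + n[2] * w[2];
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_convex_hull_faces(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");
  std::vector<double> P(3 * n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      P[3 * i + k] = pts(i, k);
      scale = std::max(scale, std::fabs(pts(i, k)));
    }
  if (scale == 0.0) scale = 1.0;
  const double eps = 1e-10 * scale * scale * scale;

  // seed tetrahedron: extreme point pairs, then max-area, then max-volume
  int i0 = 0, i1 = 1;
  {
    double best = -1.0;
    // farthest point from point 0 (adequate for sphere-like input)
    for (int i = 1; i < n; ++i) {
      double d = 0;
      for (int k = 0; k < 3; ++k) {
        double t = P[3 * i + k] - P[k];
        d += t * t;
      }
      if (d > best) { best = d; i1 = i; }
    }
  }
  int i2 = -1;
  {
    double best = -1.0;
    double u[3] = {P[3 * i1] - P[3 * i0], P[3 * i1 + 1] - P[3 * i0 + 1],
                   P[3 * i1 + 2] - P[3 * i0 + 2]};
    for (int i = 0; i < n; ++i) {
      if (i == i0 || i == i1) continue;
      double v[3] = {P[3 * i] - P[3 * i0], P[3 * i + 1] - P[3 * i0 + 1],
                     P[3 * i + 2] - P[3 * i0 + 2]};
      double w[3];
      cross3(u, v, w);
      double a2 = w[0] * w[0] + w[1] * w[1] + w[2] * w[2];
      if (a2 > best) { best = a2; i2 = i; }
    }
    if (i2 < 0 || best <= eps * eps) stop("degenerate (collinear) input");
  }
  int i3 = -1;
  {
    double best = 0.0;
    for (int i = 0; i < n; ++i) {
      if (i == i0 || i == i1 || i == i2) continue;
      double v = orient(P, i0, i1, i2, &P[3 * i]);
      if (std::fabs(v) > std::fabs(best)) { best = v; i3 = i; }
    }
    if (i3 < 0 || std::fabs(best) <= eps) stop("degenerate (coplanar) input");
    if (best > 0) std::swap(i1, i2);  // make (i0,i1,i2) face away from i3
  }

  std::vector<Face> faces;
  faces.push_back({i0, i1, i2, true});
  faces.push_back({i0, i2, i3, true});
  faces.push_back({i2, i1, i3, true});
  faces.push_back({i1, i0, i3, true});
  // verify outward orientation against interior point
  double cen[3] = {0, 0, 0};
  int seed[4] = {i0, i1, i2, i3};
  for (int s = 0; s < 4; ++s)
    for (int k = 0; k < 3; ++k) cen[k] += 0.25 * P[3 * seed[s] + k];
  for (auto& f : faces)
    if (orient(P, f.a, f.b, f.c, cen) > 0) std::swap(f.b, f.c);

  std::vector<bool> used(n, false);
  used[i0] = used[i1] = used[i2] = used[i3] = true;

  for (int p = 0; p < n; ++p) {
    if (used[p]) continue;
    used[p] = true;
    std::vector<int> visible;
    for (int f = 0; f < (int)faces.size(); ++f) {
      if (!faces[f].alive) continue;
      if (orient(P, faces[f].a, faces[f].b, faces[f].c, &P[3 * p]) > eps)
        visible.push_back(f);
    }
    if (visible.empty())
      stop("input point %d lies inside the hull; vertices must be in convex position",
           p + 1);
    // horizon: directed edges of visible faces whose reverse is not visible
    std::map<std::pair<int, int>, int> edge_cnt;
    for (int f : visible) {
      int v[3] = {faces[f].a, faces[f].b, faces[f].c};
      for (int e = 0; e < 3; ++e) {
        int u1 = v[e], u2 = v[(e + 1) % 3];
        edge_cnt[{u1, u2}] += 1;
      }
      faces[f].alive = false;
    }
    for (auto& kv : edge_cnt) {
      int u1 = kv.first.first, u2 = kv.first.second;
      if (edge_cnt.count({u2, u1})) continue;  // interior edge of the cap
      faces.push_back({u1, u2, p, true});
    }
  }

  int nf = 0;
  for (auto& f : faces) nf += f.alive ? 1 : 0;
  IntegerMatrix out(nf, 3);
  int r = 0;
  for (auto& f : faces) {
    if (!f.alive) continue;
    out(r, 0) = f.a + 1;
    out(r, 1) = f.b + 1;
    out(r, 2) = f.c + 1;
    ++r;
  }
  return out;
}
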