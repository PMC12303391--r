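#include <Rcpp.h>
#include <cmath>
#include <map>
#include <vector>
#include <limits>

using namespace Rcpp;

// Incremental Bowyer-Watson Delaunay triangulation in 2D and
// tetrahedralization in 3D. Coordinates are expected pre-normalized
// (centred, unit scale) by the R wrapper; a super-simplex far outside
// the data is stripped before edges are reported.

static const double INF = std::numeric_limits<double>::infinity();

struct Tet {
  int v[4];
  double cc[3];
  double r2;
  bool alive;
};

struct Tri {
  int v[3];
  double cc[2];
  double r2;
  bool alive;
};

// circumsphere of tetrahedron via 3x3 linear solve (Cramer's rule);
// returns false when the four points are (near-)coplanar
static bool circumsphere3(const std::vector<double>& X,
                          const std::vector<double>& Y,
                          const std::vector<double>& Z,
                          int a, int b, int c, int d,
                          double cc[3], double& r2) {
  double ax = X[a], ay = Y[a], az = Z[a];
  double m[3][3], rhs[3];
  int idx[3] = {b, c, d};
  for (int i = 0; i < 3; ++i) {
    int p = idx[i];
    m[i][0] = 2.0 * (X[p] - ax);
    m[i][1] = 2.0 * (Y[p] - ay);
    m[i][2] = 2.0 * (Z[p] - az);
    rhs[i] = (X[p] * X[p] - ax * ax) + (Y[p] * Y[p] - ay * ay) +
             (Z[p] * Z[p] - az * az);
  }
  double det =
      m[0][0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
      m[0][1] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
      m[0][2] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]);
  if (std::fabs(det) < 1e-12) return false;
  double inv = 1.0 / det;
  cc[0] = inv * (rhs[0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
                 m[0][1] * (rhs[1] * m[2][2] - m[1][2] * rhs[2]) +
                 m[0][2] * (rhs[1] * m[2][1] - m[1][1] * rhs[2]));
  cc[1] = inv * (m[0][0] * (rhs[1] * m[2][2] - m[1][2] * rhs[2]) -
                 rhs[0] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
                 m[0][2] * (m[1][0] * rhs[2] - rhs[1] * m[2][0]));
  cc[2] = inv * (m[0][0] * (m[1][1] * rhs[2] - rhs[1] * m[2][1]) -
                 m[0][1] * (m[1][0] * rhs[2] - rhs[1] * m[2][0]) +
                 rhs[0] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]));
  double dx = cc[0] - ax, dy = cc[1] - ay, dz = cc[2] - az;
  r2 = dx * dx + dy * dy + dz * dz;
  return true;
}

static bool circumcircle2(const std::vector<double>& X,
                          const std::vector<double>& Y,
                          int a, int b, int c, double cc[2], double& r2) {
  double ax = X[a], ay = Y[a];
  double m00 = 2.0 * (X[b] - ax), m01 = 2.0 * (Y[b] - ay);
  double m10 = 2.0 * (X[c] - ax), m11 = 2.0 * (Y[c] - ay);
  double r0 = (X[b] * X[b] - ax * ax) + (Y[b] * Y[b] - ay * ay);
  double r1 = (X[c] * X[c] - ax * ax) + (Y[c] * Y[c] - ay * ay);
  double det = m00 * m11 - m01 * m10;
  if (std::fabs(det) < 1e-14) return false;
  cc[0] = (r0 * m11 - m01 * r1) / det;
  cc[1] = (m00 * r1 - r0 * m10) / det;
  double dx = cc[0] - ax, dy = cc[1] - ay;
  r2 = dx * dx + dy * dy;
  return true;
}

// [[Rcpp::export(name = ".delaunay3_cpp")]]
IntegerMatrix delaunay3_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("need at least 4 points for 3D Delaunay");
  std::vector<double> X(n + 4), Y(n + 4), Z(n + 4);
  for (int i = 0; i < n; ++i) {
    X[i] = pts(i, 0);
    Y[i] = pts(i, 1);
    Z[i] = pts(i, 2);
  }
  // super-tetrahedron enclosing the (normalized) data
  double L = 500.0;
  X[n] = 0;      Y[n] = 0;      Z[n] = 3 * L;
  X[n + 1] = -2 * L; Y[n + 1] = -2 * L; Z[n + 1] = -L;
  X[n + 2] = 2 * L;  Y[n + 2] = -2 * L; Z[n + 2] = -L;
  X[n + 3] = 0;      Y[n + 3] = 3 * L;  Z[n + 3] = -L;

  std::vector<Tet> tets;
  tets.reserve(12 * n);
  Tet t0;
  t0.v[0] = n; t0.v[1] = n + 1; t0.v[2] = n + 2; t0.v[3] = n + 3;
  if (!circumsphere3(X, Y, Z, n, n + 1, n + 2, n + 3, t0.cc, t0.r2))
    stop("degenerate super-tetrahedron");
  t0.alive = true;
  tets.push_back(t0);

  std::vector<int> bad;
  typedef std::map<std::vector<int>, int> FaceMap;

  for (int p = 0; p < n; ++p) {
    bad.clear();
    for (size_t t = 0; t < tets.size(); ++t) {
      if (!tets[t].alive) continue;
      if (tets[t].r2 == INF) { bad.push_back((int)t); continue; }
      double dx = X[p] - tets[t].cc[0];
      double dy = Y[p] - tets[t].cc[1];
      double dz = Z[p] - tets[t].cc[2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < tets[t].r2 * (1.0 + 1e-12) + 1e-14) bad.push_back((int)t);
    }
    FaceMap faces;
    for (size_t b = 0; b < bad.size(); ++b) {
      Tet& t = tets[bad[b]];
      t.alive = false;
      static const int fi[4][3] = {{0,1,2},{0,1,3},{0,2,3},{1,2,3}};
      for (int f = 0; f < 4; ++f) {
        std::vector<int> face(3);
        face[0] = t.v[fi[f][0]];
        face[1] = t.v[fi[f][1]];
        face[2] = t.v[fi[f][2]];
        std::sort(face.begin(), face.end());
        faces[face] += 1;
      }
    }
    for (FaceMap::iterator it = faces.begin(); it != faces.end(); ++it) {
      if (it->second != 1) continue;  // interior cavity face
      Tet nt;
      nt.v[0] = it->first[0];
      nt.v[1] = it->first[1];
      nt.v[2] = it->first[2];
      nt.v[3] = p;
      nt.alive = true;
      if (!circumsphere3(X, Y, Z, nt.v[0], nt.v[1], nt.v[2], nt.v[3],
                         nt.cc, nt.r2)) {
        nt.cc[0] = nt.cc[1] = nt.cc[2] = 0.0;
        nt.r2 = INF;  // sliver: treated as always-bad, removed later
      }
      tets.push_back(nt);
    }
  }

  std::map<std::pair<int, int>, bool> edges;
  for (size_t t = 0; t < tets.size(); ++t) {
    if (!tets[t].alive) continue;
    bool touches_super = false;
    for (int k = 0; k < 4; ++k)
      if (tets[t].v[k] >= n) touches_super = true;
    if (touches_super) continue;
    for (int a = 0; a < 4; ++a)
      for (int b = a + 1; b < 4; ++b) {
        int u = tets[t].v[a], v = tets[t].v[b];
        if (u > v) std::swap(u, v);
        edges[std::make_pair(u, v)] = true;
      }
  }
  IntegerMatrix out(edges.size(), 2);
  int r = 0;
  for (std::map<std::pair<int, int>, bool>::iterator it = edges.begin();
       it != edges.end(); ++it, ++r) {
    out(r, 0) = it->first.first + 1;
    out(r, 1) = it->first.second + 1;
  }
  return out;
}

// [[Rcpp::export(name = ".delaunay2_cpp")]]
IntegerMatrix delaunay2_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 3) stop("need at least 3 points for 2D Delaunay");
  std::vector<double> X(n + 3), Y(n + 3);
  for (int i = 0; i < n; ++i) {
    X[i] = pts(i, 0);
    Y[i] = pts(i, 1);
  }
  double L = 500.0;
  X[n] = 0;       Y[n] = 3 * L;
  X[n + 1] = -3 * L; Y[n + 1] = -2 * L;
  X[n + 2] = 3 * L;  Y[n + 2] = -2 * L;

  std::vector<Tri> tris;
  tris.reserve(6 * n);
  Tri t0;
  t0.v[0] = n; t0.v[1] = n + 1; t0.v[2] = n + 2;
  circumcircle2(X, Y, n, n + 1, n + 2, t0.cc, t0.r2);
  t0.alive = true;
  tris.push_back(t0);

  std::vector<int> bad;
  typedef std::map<std::pair<int, int>, int> EdgeCount;

  for (int p = 0; p < n; ++p) {
    bad.clear();
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      if (tris[t].r2 == INF) { bad.push_back((int)t); continue; }
      double dx = X[p] - tris[t].cc[0];
      double dy = Y[p] - tris[t].cc[1];
      if (dx * dx + dy * dy < tris[t].r2 * (1.0 + 1e-12) + 1e-14)
        bad.push_back((int)t);
    }
    EdgeCount bound;
    for (size_t b = 0; b < bad.size(); ++b) {
      Tri& t = tris[bad[b]];
      t.alive = false;
      static const int ei[3][2] = {{0,1},{0,2},{1,2}};
      for (int e = 0; e < 3; ++e) {
        int u = t.v[ei[e][0]], v = t.v[ei[e][1]];
        if (u > v) std::swap(u, v);
        bound[std::make_pair(u, v)] += 1;
      }
    }
    for (EdgeCount::iterator it = bound.begin(); it != bound.end(); ++it) {
      if (it->second != 1) continue;
      Tri nt;
      nt.v[0] = it->first.first;
      nt.v[1] = it->first.second;
      nt.v[2] = p;
      nt.alive = true;
      if (!circumcircle2(X, Y, nt.v[0], nt.v[1], nt.v[2], nt.cc, nt.r2)) {
        nt.cc[0] = nt.cc[1] = 0.0;
        nt.r2 = INF;
      }
      tris.push_back(nt);
    }
  }

  std::map<std::pair<int, int>, bool> edges;
  for (size_t t = 0; t < tris.size(); ++t) {
    if (!tris[t].alive) continue;
    if (tris[t].v[0] >= n || tris[t].v[1] >= n || tris[t].v[2] >= n) continue;
    static const int ei[3][2] = {{0,1},{0,2},{1,2}};
    for (int e = 0; e < 3; ++e) {
      int u = tris[t].v[ei[e][0]], v = tris[t].v[ei[e][1]];
      if (u > v) std::swap(u, v);
      edges[std::make_pair(u, v)] = true;
    }
  }
  IntegerMatrix out(edges.size(), 2);
  int r = 0;
  for (std::map<std::pair<int, int>, bool>::iterator it = edges.begin();
       it != edges.end(); ++it, ++r) {
    out(r, 0) = it->first.first + 1;
    out(r, 1) = it->first.second + 1;
  }
  return out;
}

// number of other points within `radius` of each point (self excluded)
// [[Rcpp::export(name = ".radius_count_cpp")]]
IntegerVector radius_count_cpp(NumericMatrix pts, double radius) {
  int n = pts.nrow();
  double r2 = radius * radius;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int cnt = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = pts(i, 0) - pts(j, 0);
      if (std::fabs(dx) > radius) continue;
      double dy = pts(i, 1) - pts(j, 1);
      double dz = pts(i, 2) - pts(j, 2);
      if (dx * dx + dy * dy + dz * dz <= r2) ++cnt;
    }
    out[i] = cnt;
  }
  return out;
}
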