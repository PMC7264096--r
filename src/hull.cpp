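// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <map>
#include <utility>

using namespace Rcpp;

// Incremental 3D convex hull: volume, triangular facets and outward
// half-space representation. Intended for the small point sets arising from
// envelope end-points and evaluation trajectories (n up to a few thousand).

namespace {

struct Face {
  int a, b, c;
  arma::vec3 n;   // outward unit normal
  double d;       // n . x = d on the face plane
  bool alive;
};

void face_plane(const arma::mat& P, Face& f, const arma::vec3& interior) {
  arma::vec3 A = P.row(f.a).t(), B = P.row(f.b).t(), C = P.row(f.c).t();
  arma::vec3 n = arma::cross(B - A, C - A);
  double nn = arma::norm(n);
  if (nn < 1e-14) { f.n.zeros(); f.d = 0.0; return; }
  n /= nn;
  if (arma::dot(n, interior - A) > 0) { n = -n; std::swap(f.b, f.c); }
  f.n = n;
  f.d = arma::dot(n, A);
}

}  // namespace

// [[Rcpp::export]]
List cpp_convhull(arma::mat pts) {
  const int n = pts.n_rows;
  if (n < 4) stop("convex hull needs at least 4 points");
  const double scale = std::max(1e-12,
      (pts.max() - pts.min()));
  const double eps = 1e-9 * scale;

  // initial simplex: mutually far apart, non-degenerate
  int i0 = (int) arma::index_min(pts.col(0));
  int i1 = i0;
  double best = -1.0;
  for (int i = 0; i < n; ++i) {
    double d = arma::norm(pts.row(i) - pts.row(i0));
    if (d > best) { best = d; i1 = i; }
  }
  if (best < eps)
    return List::create(_["volume"] = 0.0, _["degenerate"] = true);
  arma::vec3 A = pts.row(i0).t(), B = pts.row(i1).t();
  arma::vec3 AB = B - A;
  int i2 = -1; best = -1.0;
  for (int i = 0; i < n; ++i) {
    arma::vec3 w = pts.row(i).t() - A;
    double d = arma::norm(arma::cross(AB, w)) / arma::norm(AB);
    if (d > best) { best = d; i2 = i; }
  }
  if (best < eps)
    return List::create(_["volume"] = 0.0, _["degenerate"] = true);
  arma::vec3 C = pts.row(i2).t();
  arma::vec3 nrm = arma::cross(AB, C - A);
  nrm /= arma::norm(nrm);
  int i3 = -1; best = -1.0;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(arma::dot(nrm, pts.row(i).t() - A));
    if (d > best) { best = d; i3 = i; }
  }
  if (best < eps)
    return List::create(_["volume"] = 0.0, _["degenerate"] = true);

  arma::vec3 interior = (pts.row(i0).t() + pts.row(i1).t() +
                         pts.row(i2).t() + pts.row(i3).t()) / 4.0;
  std::vector<Face> faces;
  auto add_face = [&](int a, int b, int c) {
    Face f{a, b, c, arma::vec3(), 0.0, true};
    face_plane(pts, f, interior);
    faces.push_back(f);
  };
  add_face(i0, i1, i2); add_face(i0, i1, i3);
  add_face(i0, i2, i3); add_face(i1, i2, i3);

  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    arma::vec3 x = pts.row(p).t();
    std::vector<int> visible;
    for (size_t f = 0; f < faces.size(); ++f)
      if (faces[f].alive && arma::dot(faces[f].n, x) - faces[f].d > eps)
        visible.push_back((int) f);
    if (visible.empty()) continue;
    // horizon: undirected edges that appear in exactly one visible face
    std::map<std::pair<int, int>, int> edge_count;
    auto key = [](int u, int v) {
      return std::make_pair(std::min(u, v), std::max(u, v));
    };
    for (int f : visible) {
      edge_count[key(faces[f].a, faces[f].b)]++;
      edge_count[key(faces[f].b, faces[f].c)]++;
      edge_count[key(faces[f].c, faces[f].a)]++;
    }
    for (int f : visible) faces[f].alive = false;
    for (auto& kv : edge_count)
      if (kv.second == 1)
        add_face(kv.first.first, kv.first.second, p);
  }

  std::vector<int> live;
  for (size_t f = 0; f < faces.size(); ++f)
    if (faces[f].alive) live.push_back((int) f);
  const int m = (int) live.size();
  arma::imat tri(m, 3);
  arma::mat normals(m, 3);
  arma::vec offsets(m);
  double vol = 0.0;
  for (int k = 0; k < m; ++k) {
    const Face& f = faces[live[k]];
    tri(k, 0) = f.a + 1; tri(k, 1) = f.b + 1; tri(k, 2) = f.c + 1;
    normals.row(k) = f.n.t();
    offsets(k) = f.d;
    arma::vec3 a = pts.row(f.a).t() - interior;
    arma::vec3 b = pts.row(f.b).t() - interior;
    arma::vec3 c = pts.row(f.c).t() - interior;
    vol += std::fabs(arma::dot(a, arma::cross(b, c))) / 6.0;
  }
  return List::create(_["volume"] = vol, _["degenerate"] = false,
                      _["faces"] = tri, _["normals"] = normals,
                      _["offsets"] = offsets);
}

// [[Rcpp::export]]
LogicalVector cpp_hull_contains(arma::mat normals, arma::vec offsets,
                                arma::mat pts, double tol) {
  const int n = pts.n_rows;
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    bool inside = true;
    for (arma::uword f = 0; f < offsets.n_elem; ++f) {
      if (arma::dot(normals.row(f), pts.row(i)) - offsets(f) > tol) {
        inside = false; break;
      }
    }
    out[i] = inside;
  }
  return out;
}
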