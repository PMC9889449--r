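// Bounding-volume-hierarchy ray casting for triangle meshes.
// Median-split AABB tree over triangle centroids; Moller-Trumbore
// ray/triangle intersection. Used for HRPR grid projection, where
// thousands of parallel rays are cast against meshes that may carry
// hundreds of thousands of triangles (CT isosurfaces).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <limits>
#include <cmath>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 vsub(const Vec3 &a, const Vec3 &b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double vdot(const Vec3 &a, const Vec3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }

struct Node {
  double lo[3], hi[3];
  int left;   // child index, or -1 for leaf
  int right;
  int start;  // leaf: range into tri index array
  int count;
};

struct BVH {
  std::vector<Vec3> v0, e1, e2;  // per-triangle precomputed edges
  std::vector<Node> nodes;
  std::vector<int> tri;          // triangle order after splitting
};

void node_bounds(BVH &b, const std::vector<Vec3> &clo, const std::vector<Vec3> &chi,
                 int start, int count, double lo[3], double hi[3]) {
  for (int a = 0; a < 3; ++a) {
    lo[a] = std::numeric_limits<double>::infinity();
    hi[a] = -std::numeric_limits<double>::infinity();
  }
  for (int i = start; i < start + count; ++i) {
    int t = b.tri[i];
    const double l[3] = {clo[t].x, clo[t].y, clo[t].z};
    const double h[3] = {chi[t].x, chi[t].y, chi[t].z};
    for (int a = 0; a < 3; ++a) {
      lo[a] = std::min(lo[a], l[a]);
      hi[a] = std::max(hi[a], h[a]);
    }
  }
}

int build_node(BVH &b, const std::vector<Vec3> &clo, const std::vector<Vec3> &chi,
               const std::vector<Vec3> &cen, int start, int count) {
  Node nd;
  node_bounds(b, clo, chi, start, count, nd.lo, nd.hi);
  int idx = (int)b.nodes.size();
  b.nodes.push_back(nd);
  if (count <= 8) {
    b.nodes[idx].left = b.nodes[idx].right = -1;
    b.nodes[idx].start = start;
    b.nodes[idx].count = count;
    return idx;
  }
  // split along the widest axis of the centroid bounds
  double clo_[3] = {1e300, 1e300, 1e300}, chi_[3] = {-1e300, -1e300, -1e300};
  for (int i = start; i < start + count; ++i) {
    int t = b.tri[i];
    const double c[3] = {cen[t].x, cen[t].y, cen[t].z};
    for (int a = 0; a < 3; ++a) {
      clo_[a] = std::min(clo_[a], c[a]);
      chi_[a] = std::max(chi_[a], c[a]);
    }
  }
  int axis = 0;
  double w = chi_[0] - clo_[0];
  for (int a = 1; a < 3; ++a)
    if (chi_[a] - clo_[a] > w) { w = chi_[a] - clo_[a]; axis = a; }
  int mid = start + count / 2;
  std::nth_element(b.tri.begin() + start, b.tri.begin() + mid, b.tri.begin() + start + count,
                   [&](int ta, int tb) {
                     const double ca = axis == 0 ? cen[ta].x : (axis == 1 ? cen[ta].y : cen[ta].z);
                     const double cb = axis == 0 ? cen[tb].x : (axis == 1 ? cen[tb].y : cen[tb].z);
                     return ca < cb;
                   });
  if (mid == start || mid == start + count) mid = start + count / 2;  // degenerate guard
  int l = build_node(b, clo, chi, cen, start, mid - start);
  int r = build_node(b, clo, chi, cen, mid, start + count - mid);
  b.nodes[idx].left = l;
  b.nodes[idx].right = r;
  b.nodes[idx].start = -1;
  b.nodes[idx].count = 0;
  return idx;
}

inline bool box_hit(const Node &nd, const Vec3 &o, const Vec3 &inv, double tmax) {
  double t0 = 0.0, t1 = tmax;
  const double olist[3] = {o.x, o.y, o.z};
  const double ilist[3] = {inv.x, inv.y, inv.z};
  for (int a = 0; a < 3; ++a) {
    double ta = (nd.lo[a] - olist[a]) * ilist[a];
    double tb = (nd.hi[a] - olist[a]) * ilist[a];
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta);
    t1 = std::min(t1, tb);
    if (t0 > t1) return false;
  }
  return true;
}

// Moller-Trumbore; returns ray parameter or -1 when missed.
inline double tri_hit(const Vec3 &o, const Vec3 &d, const Vec3 &v0, const Vec3 &e1,
                      const Vec3 &e2) {
  Vec3 p = vcross(d, e2);
  double det = vdot(e1, p);
  if (std::fabs(det) < 1e-14) return -1.0;
  double inv = 1.0 / det;
  Vec3 s = vsub(o, v0);
  double u = vdot(s, p) * inv;
  if (u < 0.0 || u > 1.0) return -1.0;
  Vec3 q = vcross(s, e1);
  double v = vdot(d, q) * inv;
  if (v < 0.0 || u + v > 1.0) return -1.0;
  return vdot(e2, q) * inv;
}

// Squared distance from a point to a triangle (Ericson's closest-point
// classification over barycentric regions).
inline double tri_dist2(const Vec3 &q, const Vec3 &a, const Vec3 &ab, const Vec3 &ac) {
  Vec3 ap = vsub(q, a);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  double u, v;
  if (d1 <= 0 && d2 <= 0) {
    u = 0; v = 0;
  } else {
    Vec3 bp = {ap.x - ab.x, ap.y - ab.y, ap.z - ab.z};
    double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
    if (d3 >= 0 && d4 <= d3) {
      u = 1; v = 0;
    } else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        u = d1 / (d1 - d3); v = 0;
      } else {
        Vec3 cp = {ap.x - ac.x, ap.y - ac.y, ap.z - ac.z};
        double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
        if (d6 >= 0 && d5 <= d6) {
          u = 0; v = 1;
        } else {
          double vb = d5 * d2 - d1 * d6;
          if (vb <= 0 && d2 >= 0 && d6 <= 0) {
            u = 0; v = d2 / (d2 - d6);
          } else {
            double va = d3 * d6 - d5 * d4;
            if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              u = 1 - w; v = w;
            } else {
              double denom = 1.0 / (va + vb + vc);
              u = vb * denom;
              v = vc * denom;
            }
          }
        }
      }
    }
  }
  double dx = ap.x - u * ab.x - v * ac.x;
  double dy = ap.y - u * ab.y - v * ac.y;
  double dz = ap.z - u * ab.z - v * ac.z;
  return dx * dx + dy * dy + dz * dz;
}

inline double box_dist2(const Node &nd, const Vec3 &q) {
  double d2 = 0.0;
  const double qq[3] = {q.x, q.y, q.z};
  for (int a = 0; a < 3; ++a) {
    double d = qq[a] < nd.lo[a] ? nd.lo[a] - qq[a] : (qq[a] > nd.hi[a] ? qq[a] - nd.hi[a] : 0.0);
    d2 += d * d;
  }
  return d2;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_bvh_build")]]
SEXP cpp_bvh_build(NumericMatrix V, IntegerMatrix F) {
  int nf = F.nrow();
  if (nf == 0) stop("mesh has no faces");
  XPtr<BVH> ptr(new BVH(), true);
  BVH &b = *ptr;
  b.v0.resize(nf);
  b.e1.resize(nf);
  b.e2.resize(nf);
  std::vector<Vec3> clo(nf), chi(nf), cen(nf);
  for (int i = 0; i < nf; ++i) {
    int a = F(i, 0) - 1, c = F(i, 1) - 1, d = F(i, 2) - 1;
    Vec3 p0 = {V(a, 0), V(a, 1), V(a, 2)};
    Vec3 p1 = {V(c, 0), V(c, 1), V(c, 2)};
    Vec3 p2 = {V(d, 0), V(d, 1), V(d, 2)};
    b.v0[i] = p0;
    b.e1[i] = vsub(p1, p0);
    b.e2[i] = vsub(p2, p0);
    clo[i] = {std::min({p0.x, p1.x, p2.x}), std::min({p0.y, p1.y, p2.y}),
              std::min({p0.z, p1.z, p2.z})};
    chi[i] = {std::max({p0.x, p1.x, p2.x}), std::max({p0.y, p1.y, p2.y}),
              std::max({p0.z, p1.z, p2.z})};
    cen[i] = {(clo[i].x + chi[i].x) / 2, (clo[i].y + chi[i].y) / 2, (clo[i].z + chi[i].z) / 2};
  }
  b.tri.resize(nf);
  for (int i = 0; i < nf; ++i) b.tri[i] = i;
  b.nodes.reserve(2 * nf / 8 + 8);
  build_node(b, clo, chi, cen, 0, nf);
  return ptr;
}

// Cast one ray per row of `origins` along the matching row of `dirs`
// (unnormalized directions allowed; the returned t is in units of the
// supplied direction). Keeps the nearest intersection with t >= eps.
//' @noRd
// [[Rcpp::export(name = ".cpp_bvh_raycast")]]
List cpp_bvh_raycast(SEXP bvh, NumericMatrix origins, NumericMatrix dirs, double eps) {
  XPtr<BVH> ptr(bvh);
  BVH &b = *ptr;
  int n = origins.nrow();
  LogicalVector hit(n);
  NumericVector tpar(n);
  IntegerVector tri(n);
  NumericMatrix pts(n, 3);
  std::vector<int> stack;
  stack.reserve(64);
  for (int i = 0; i < n; ++i) {
    Vec3 o = {origins(i, 0), origins(i, 1), origins(i, 2)};
    Vec3 d = {dirs(i, 0), dirs(i, 1), dirs(i, 2)};
    Vec3 inv = {1.0 / d.x, 1.0 / d.y, 1.0 / d.z};
    double best = std::numeric_limits<double>::infinity();
    int best_tri = -1;
    stack.clear();
    stack.push_back(0);
    while (!stack.empty()) {
      int ni = stack.back();
      stack.pop_back();
      const Node &nd = b.nodes[ni];
      if (!box_hit(nd, o, inv, best)) continue;
      if (nd.left < 0) {
        for (int k = nd.start; k < nd.start + nd.count; ++k) {
          int t = b.tri[k];
          double tp = tri_hit(o, d, b.v0[t], b.e1[t], b.e2[t]);
          if (tp >= eps && tp < best) {
            best = tp;
            best_tri = t;
          }
        }
      } else {
        stack.push_back(nd.left);
        stack.push_back(nd.right);
      }
    }
    if (best_tri >= 0) {
      hit[i] = true;
      tpar[i] = best;
      tri[i] = best_tri + 1;
      pts(i, 0) = o.x + best * d.x;
      pts(i, 1) = o.y + best * d.y;
      pts(i, 2) = o.z + best * d.z;
    } else {
      hit[i] = false;
      tpar[i] = NA_REAL;
      tri[i] = NA_INTEGER;
      pts(i, 0) = pts(i, 1) = pts(i, 2) = NA_REAL;
    }
  }
  return List::create(_["hit"] = hit, _["t"] = tpar, _["triangle"] = tri, _["points"] = pts);
}

// Distance from each query point to the closest point on the mesh surface.
//' @noRd
// [[Rcpp::export(name = ".cpp_bvh_surface_dist")]]
NumericVector cpp_bvh_surface_dist(SEXP bvh, NumericMatrix Q) {
  XPtr<BVH> ptr(bvh);
  BVH &b = *ptr;
  int n = Q.nrow();
  NumericVector out(n);
  std::vector<int> stack;
  stack.reserve(64);
  for (int i = 0; i < n; ++i) {
    Vec3 q = {Q(i, 0), Q(i, 1), Q(i, 2)};
    double best = std::numeric_limits<double>::infinity();
    stack.clear();
    stack.push_back(0);
    while (!stack.empty()) {
      int ni = stack.back();
      stack.pop_back();
      const Node &nd = b.nodes[ni];
      if (box_dist2(nd, q) >= best) continue;
      if (nd.left < 0) {
        for (int k = nd.start; k < nd.start + nd.count; ++k) {
          int t = b.tri[k];
          double d2 = tri_dist2(q, b.v0[t], b.e1[t], b.e2[t]);
          if (d2 < best) best = d2;
        }
      } else {
        // visit the nearer child first for tighter pruning
        double dl = box_dist2(b.nodes[nd.left], q);
        double dr = box_dist2(b.nodes[nd.right], q);
        if (dl < dr) {
          stack.push_back(nd.right);
          stack.push_back(nd.left);
        } else {
          stack.push_back(nd.left);
          stack.push_back(nd.right);
        }
      }
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_xptr_valid")]]
bool cpp_xptr_valid(SEXP p) {
  return TYPEOF(p) == EXTPTRSXP && R_ExternalPtrAddr(p) != NULL;
}
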