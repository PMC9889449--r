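// 3-d kd-tree nearest-neighbour search with deterministic tie-breaking
// (equal distances resolve to the lowest point index), plus brute-force
// point-to-triangle distances for the optional point-to-surface metric.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct KDTree {
  std::vector<double> px, py, pz;  // original order
  std::vector<int> idx;            // point order within the tree
  std::vector<int> split_axis;     // per node; -1 marks a leaf
  std::vector<double> split_val;   // recorded at build time, before children reorder idx
  std::vector<int> lo, hi;         // node ranges; simple recursive median build
  std::vector<int> left, right;
};

int kd_build(KDTree &t, int lo, int hi) {  // [lo, hi)
  int node = (int)t.lo.size();
  t.lo.push_back(lo);
  t.hi.push_back(hi);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.split_axis.push_back(-1);
  t.split_val.push_back(0.0);
  if (hi - lo <= 16) return node;
  double mn[3] = {1e300, 1e300, 1e300}, mx[3] = {-1e300, -1e300, -1e300};
  for (int i = lo; i < hi; ++i) {
    int p = t.idx[i];
    double c[3] = {t.px[p], t.py[p], t.pz[p]};
    for (int a = 0; a < 3; ++a) {
      mn[a] = std::min(mn[a], c[a]);
      mx[a] = std::max(mx[a], c[a]);
    }
  }
  int axis = 0;
  double w = mx[0] - mn[0];
  for (int a = 1; a < 3; ++a)
    if (mx[a] - mn[a] > w) { w = mx[a] - mn[a]; axis = a; }
  int mid = (lo + hi) / 2;
  std::nth_element(t.idx.begin() + lo, t.idx.begin() + mid, t.idx.begin() + hi,
                   [&](int a, int b) {
                     double ca = axis == 0 ? t.px[a] : (axis == 1 ? t.py[a] : t.pz[a]);
                     double cb = axis == 0 ? t.px[b] : (axis == 1 ? t.py[b] : t.pz[b]);
                     return ca < cb;
                   });
  t.split_axis[node] = axis;
  {
    int pm = t.idx[mid];
    t.split_val[node] = axis == 0 ? t.px[pm] : (axis == 1 ? t.py[pm] : t.pz[pm]);
  }
  int l = kd_build(t, lo, mid);
  int r = kd_build(t, mid, hi);
  t.left[node] = l;
  t.right[node] = r;
  return node;
}

void kd_query(const KDTree &t, int node, double qx, double qy, double qz, double &best_d2,
              int &best_i) {
  if (t.left[node] < 0) {
    for (int i = t.lo[node]; i < t.hi[node]; ++i) {
      int p = t.idx[i];
      double dx = t.px[p] - qx, dy = t.py[p] - qy, dz = t.pz[p] - qz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best_d2 || (d2 == best_d2 && p < best_i)) {
        best_d2 = d2;
        best_i = p;
      }
    }
    return;
  }
  int axis = t.split_axis[node];
  double sv = t.split_val[node];
  double q = axis == 0 ? qx : (axis == 1 ? qy : qz);
  int near = q < sv ? t.left[node] : t.right[node];
  int far = q < sv ? t.right[node] : t.left[node];
  kd_query(t, near, qx, qy, qz, best_d2, best_i);
  double off = q - sv;
  if (off * off <= best_d2) kd_query(t, far, qx, qy, qz, best_d2, best_i);
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_kdtree_build")]]
SEXP cpp_kdtree_build(NumericMatrix P) {
  int n = P.nrow();
  if (n == 0) stop("empty point set");
  XPtr<KDTree> ptr(new KDTree(), true);
  KDTree &t = *ptr;
  t.px.resize(n);
  t.py.resize(n);
  t.pz.resize(n);
  t.idx.resize(n);
  for (int i = 0; i < n; ++i) {
    t.px[i] = P(i, 0);
    t.py[i] = P(i, 1);
    t.pz[i] = P(i, 2);
    t.idx[i] = i;
  }
  kd_build(t, 0, n);
  return ptr;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_kdtree_query")]]
List cpp_kdtree_query(SEXP tree, NumericMatrix Q) {
  XPtr<KDTree> ptr(tree);
  const KDTree &t = *ptr;
  int n = Q.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int bi = (int)t.px.size();  // larger than any valid index so ties resolve downward
    kd_query(t, 0, Q(i, 0), Q(i, 1), Q(i, 2), best, bi);
    idx[i] = bi + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// Distance from each query point to the closest point on any mesh triangle.
// Brute force over triangles; intended for moderate mesh sizes where the
// point-to-surface (rather than point-to-vertex) metric is requested.
//' @noRd
// [[Rcpp::export(name = ".cpp_point_triangle_dist")]]
NumericVector cpp_point_triangle_dist(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  int nf = F.nrow(), nq = Q.nrow();
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double qx = Q(i, 0), qy = Q(i, 1), qz = Q(i, 2);
    double best = std::numeric_limits<double>::infinity();
    for (int f = 0; f < nf; ++f) {
      int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
      double ax = V(a, 0), ay = V(a, 1), az = V(a, 2);
      double abx = V(b, 0) - ax, aby = V(b, 1) - ay, abz = V(b, 2) - az;
      double acx = V(c, 0) - ax, acy = V(c, 1) - ay, acz = V(c, 2) - az;
      double apx = qx - ax, apy = qy - ay, apz = qz - az;
      // Ericson's closest-point-on-triangle
      double d1 = abx * apx + aby * apy + abz * apz;
      double d2 = acx * apx + acy * apy + acz * apz;
      double u, v;
      if (d1 <= 0 && d2 <= 0) {
        u = 0; v = 0;
      } else {
        double bpx = qx - V(b, 0), bpy = qy - V(b, 1), bpz = qz - V(b, 2);
        double d3 = abx * bpx + aby * bpy + abz * bpz;
        double d4 = acx * bpx + acy * bpy + acz * bpz;
        if (d3 >= 0 && d4 <= d3) {
          u = 1; v = 0;
        } else {
          double vc = d1 * d4 - d3 * d2;
          if (vc <= 0 && d1 >= 0 && d3 <= 0) {
            u = d1 / (d1 - d3); v = 0;
          } else {
            double cpx = qx - V(c, 0), cpy = qy - V(c, 1), cpz = qz - V(c, 2);
            double d5 = abx * cpx + aby * cpy + abz * cpz;
            double d6 = acx * cpx + acy * cpy + acz * cpz;
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
      double px = ax + u * abx + v * acx, py = ay + u * aby + v * acy, pz = az + u * abz + v * acz;
      double dx = qx - px, dy = qy - py, dz = qz - pz;
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
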