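#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact minimal-area triangle enclosing a convex polygon.
//
// Uses the classical optimality structure: at least one side of the
// optimal triangle is flush with a polygon edge, and every non-flush
// side touches the polygon at the side's midpoint.  Consequently the
// optimum is attained (in area) by a configuration in which either
// (a) three sides are flush with polygon edges, or
// (b) two sides are flush and the third passes through a polygon
//     vertex that bisects it.
// (A one-flush/two-midpoint optimum is a one-parameter family of equal
// area whose boundary members are of type (b), so enumerating (a) and
// (b) suffices.)  Candidates are validated by containment and the
// minimum valid area is returned.

struct Line {
  double a, b, c; // a*x + b*y = c; hull satisfies a*x + b*y <= c
};

static inline bool line_intersect(const Line &l1, const Line &l2,
                                  double &x, double &y) {
  double det = l1.a * l2.b - l2.a * l1.b;
  if (std::fabs(det) < 1e-300) return false;
  x = (l1.c * l2.b - l2.c * l1.b) / det;
  y = (l1.a * l2.c - l2.a * l1.c) / det;
  if (!std::isfinite(x) || !std::isfinite(y)) return false;
  return true;
}

static inline double cross2(double ox, double oy, double ax, double ay,
                            double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

// Evaluate a candidate triangle given three lines; returns area or -1
// if invalid (degenerate, unbounded, or not containing the hull).
static double eval_candidate(const Line &l1, const Line &l2, const Line &l3,
                             const std::vector<double> &hx,
                             const std::vector<double> &hy,
                             double tol2, double vx[3], double vy[3]) {
  // vertex i is opposite line i
  if (!line_intersect(l2, l3, vx[0], vy[0])) return -1.0;
  if (!line_intersect(l1, l3, vx[1], vy[1])) return -1.0;
  if (!line_intersect(l1, l2, vx[2], vy[2])) return -1.0;

  double area2 = cross2(vx[0], vy[0], vx[1], vy[1], vx[2], vy[2]);
  double orient = (area2 >= 0.0) ? 1.0 : -1.0;
  double area = 0.5 * std::fabs(area2);
  if (!(area > 0.0) || !std::isfinite(area)) return -1.0;

  // containment: every hull point on the inner side of each triangle edge
  size_t h = hx.size();
  for (size_t p = 0; p < h; ++p) {
    for (int e = 0; e < 3; ++e) {
      int u = e, v = (e + 1) % 3;
      double s = orient * cross2(vx[u], vy[u], vx[v], vy[v], hx[p], hy[p]);
      if (s < -tol2) return -1.0;
    }
  }
  return area;
}

// [[Rcpp::export(name = ".min_enclosing_triangle_cpp")]]
List min_enclosing_triangle_cpp(NumericMatrix hull) {
  int h = hull.nrow();
  if (h < 3) stop("hull must have at least 3 vertices");
  std::vector<double> hx(h), hy(h);
  for (int i = 0; i < h; ++i) { hx[i] = hull(i, 0); hy[i] = hull(i, 1); }

  // scale for tolerances (cross products scale as length^2)
  double xmin = hx[0], xmax = hx[0], ymin = hy[0], ymax = hy[0];
  for (int i = 1; i < h; ++i) {
    xmin = std::min(xmin, hx[i]); xmax = std::max(xmax, hx[i]);
    ymin = std::min(ymin, hy[i]); ymax = std::max(ymax, hy[i]);
  }
  double diam = std::hypot(xmax - xmin, ymax - ymin);
  if (!(diam > 0.0)) stop("degenerate hull: all points coincide");
  double tol2 = 1e-9 * diam * diam;

  // edge support lines (hull assumed CCW; normal (dy, -dx) points outward)
  std::vector<Line> edges(h);
  for (int i = 0; i < h; ++i) {
    int j = (i + 1) % h;
    double dx = hx[j] - hx[i], dy = hy[j] - hy[i];
    double len = std::hypot(dx, dy);
    if (len < 1e-14 * diam) { edges[i].a = 0; edges[i].b = 0; edges[i].c = 1; continue; }
    Line L; L.a = dy / len; L.b = -dx / len; L.c = L.a * hx[i] + L.b * hy[i];
    edges[i] = L;
  }

  double best = std::numeric_limits<double>::infinity();
  double bx[3] = {0, 0, 0}, by[3] = {0, 0, 0};
  double vx[3], vy[3];

  // (a) three flush sides
  for (int i = 0; i < h - 2; ++i)
    for (int j = i + 1; j < h - 1; ++j)
      for (int k = j + 1; k < h; ++k) {
        double area = eval_candidate(edges[i], edges[j], edges[k],
                                     hx, hy, tol2, vx, vy);
        if (area > 0.0 && area < best) {
          best = area;
          for (int m = 0; m < 3; ++m) { bx[m] = vx[m]; by[m] = vy[m]; }
        }
      }

  // (b) two flush sides + one side bisected by a hull vertex
  for (int i = 0; i < h - 1; ++i)
    for (int j = i + 1; j < h; ++j) {
      for (int v = 0; v < h; ++v) {
        // third side meets edge line i at A and edge line j at B = 2v - A,
        // so A lies on line i and on the reflection of line j about v
        Line lj_ref;
        lj_ref.a = edges[j].a; lj_ref.b = edges[j].b;
        lj_ref.c = 2.0 * (edges[j].a * hx[v] + edges[j].b * hy[v]) - edges[j].c;
        double Axp, Ayp;
        if (!line_intersect(edges[i], lj_ref, Axp, Ayp)) continue;
        double Bxp = 2.0 * hx[v] - Axp, Byp = 2.0 * hy[v] - Ayp;
        double dx = Bxp - Axp, dy = Byp - Ayp;
        double len = std::hypot(dx, dy);
        if (len < 1e-12 * diam) continue;
        Line l3; l3.a = dy / len; l3.b = -dx / len;
        l3.c = l3.a * Axp + l3.b * Ayp;
        double area = eval_candidate(edges[i], edges[j], l3,
                                     hx, hy, tol2, vx, vy);
        if (area > 0.0 && area < best) {
          best = area;
          for (int m = 0; m < 3; ++m) { bx[m] = vx[m]; by[m] = vy[m]; }
        }
      }
    }

  if (!std::isfinite(best))
    stop("no valid enclosing triangle found (degenerate hull?)");

  // order vertices counter-clockwise
  double cx = (bx[0] + bx[1] + bx[2]) / 3.0, cy = (by[0] + by[1] + by[2]) / 3.0;
  int idx[3] = {0, 1, 2};
  double ang[3];
  for (int m = 0; m < 3; ++m) ang[m] = std::atan2(by[m] - cy, bx[m] - cx);
  for (int a = 0; a < 2; ++a)
    for (int b = a + 1; b < 3; ++b)
      if (ang[idx[b]] < ang[idx[a]]) std::swap(idx[a], idx[b]);

  NumericMatrix V(3, 2);
  for (int m = 0; m < 3; ++m) { V(m, 0) = bx[idx[m]]; V(m, 1) = by[idx[m]]; }
  return List::create(_["vertices"] = V, _["area"] = best);
}
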