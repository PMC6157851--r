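#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Planar geometry kernels. Polygons are represented as a list of rings,
// each ring an n x 2 coordinate matrix with no repeated closing vertex.
// Interior membership uses the even-odd (crossing number) rule across all
// rings, which handles holes and multipolygons uniformly.

struct Ring {
  std::vector<double> x, y;
};

static std::vector<Ring> as_rings(const List& rings) {
  std::vector<Ring> out;
  out.reserve(rings.size());
  for (int k = 0; k < rings.size(); ++k) {
    NumericMatrix m = rings[k];
    Ring r;
    int n = m.nrow();
    r.x.resize(n);
    r.y.resize(n);
    for (int i = 0; i < n; ++i) {
      r.x[i] = m(i, 0);
      r.y[i] = m(i, 1);
    }
    out.push_back(std::move(r));
  }
  return out;
}

static bool pip(double px, double py, const std::vector<Ring>& rings) {
  bool inside = false;
  for (const Ring& r : rings) {
    int n = (int)r.x.size();
    if (n < 3) continue;
    for (int i = 0, j = n - 1; i < n; j = i++) {
      const double xi = r.x[i], yi = r.y[i], xj = r.x[j], yj = r.y[j];
      if (((yi > py) != (yj > py)) &&
          (px < (xj - xi) * (py - yi) / (yj - yi) + xi))
        inside = !inside;
    }
  }
  return inside;
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_rings(NumericVector px, NumericVector py, List rings) {
  std::vector<Ring> rs = as_rings(rings);
  int n = px.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pip(px[i], py[i], rs);
  return out;
}

// Sutherland-Hodgman clip of one ring against the half-plane
// { p : dot(p - a, nrm) <= 0 }.
// [[Rcpp::export]]
NumericMatrix cpp_clip_halfplane(NumericMatrix ring, double ax, double ay,
                                 double nx, double ny) {
  int n = ring.nrow();
  std::vector<double> ox, oy;
  ox.reserve(n + 4);
  oy.reserve(n + 4);
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    double x1 = ring(i, 0), y1 = ring(i, 1);
    double x2 = ring(j, 0), y2 = ring(j, 1);
    double d1 = (x1 - ax) * nx + (y1 - ay) * ny;
    double d2 = (x2 - ax) * nx + (y2 - ay) * ny;
    bool in1 = d1 <= 0.0, in2 = d2 <= 0.0;
    if (in1) {
      ox.push_back(x1);
      oy.push_back(y1);
    }
    if (in1 != in2) {
      double t = d1 / (d1 - d2);
      ox.push_back(x1 + t * (x2 - x1));
      oy.push_back(y1 + t * (y2 - y1));
    }
  }
  NumericMatrix out((int)ox.size(), 2);
  for (size_t i = 0; i < ox.size(); ++i) {
    out(i, 0) = ox[i];
    out(i, 1) = oy[i];
  }
  return out;
}

// Clip a single polyline part (m x 2) to the interior of a ring set.
// Returns a list of parts (matrices) lying inside; consecutive inside
// pieces are stitched. Each segment is split at every crossing with a ring
// edge and sub-segments are kept when their midpoints test inside.
// [[Rcpp::export]]
List cpp_clip_polyline(NumericMatrix part, List rings) {
  std::vector<Ring> rs = as_rings(rings);
  int m = part.nrow();
  std::vector<std::vector<double> > parts_x, parts_y;
  std::vector<double> cx, cy; // current open part
  const double eps = 1e-12;

  for (int s = 0; s + 1 < m; ++s) {
    double x1 = part(s, 0), y1 = part(s, 1);
    double x2 = part(s + 1, 0), y2 = part(s + 1, 1);
    double dx = x2 - x1, dy = y2 - y1;
    double seglen = std::sqrt(dx * dx + dy * dy);
    if (seglen <= 0) continue;

    std::vector<double> ts;
    ts.push_back(0.0);
    ts.push_back(1.0);
    for (const Ring& r : rs) {
      int n = (int)r.x.size();
      for (int i = 0, j = n - 1; i < n; j = i++) {
        double ex = r.x[i] - r.x[j], ey = r.y[i] - r.y[j];
        double den = dx * ey - dy * ex;
        if (std::fabs(den) < 1e-300) continue;
        double wx = r.x[j] - x1, wy = r.y[j] - y1;
        double t = (wx * ey - wy * ex) / den;
        double u = (wx * dy - wy * dx) / den;
        if (t > eps && t < 1.0 - eps && u >= -eps && u <= 1.0 + eps)
          ts.push_back(t);
      }
    }
    std::sort(ts.begin(), ts.end());

    for (size_t k = 0; k + 1 < ts.size(); ++k) {
      double t0 = ts[k], t1 = ts[k + 1];
      if ((t1 - t0) * seglen < 1e-9) continue;
      double tm = 0.5 * (t0 + t1);
      if (!pip(x1 + tm * dx, y1 + tm * dy, rs)) {
        if (cx.size() >= 2) {
          parts_x.push_back(cx);
          parts_y.push_back(cy);
        }
        cx.clear();
        cy.clear();
        continue;
      }
      double px0 = x1 + t0 * dx, py0 = y1 + t0 * dy;
      double px1 = x1 + t1 * dx, py1 = y1 + t1 * dy;
      if (!cx.empty() &&
          std::fabs(cx.back() - px0) < 1e-9 &&
          std::fabs(cy.back() - py0) < 1e-9) {
        cx.push_back(px1);
        cy.push_back(py1);
      } else {
        if (cx.size() >= 2) {
          parts_x.push_back(cx);
          parts_y.push_back(cy);
        }
        cx.clear();
        cy.clear();
        cx.push_back(px0);
        cy.push_back(py0);
        cx.push_back(px1);
        cy.push_back(py1);
      }
    }
  }
  if (cx.size() >= 2) {
    parts_x.push_back(cx);
    parts_y.push_back(cy);
  }

  List out(parts_x.size());
  for (size_t p = 0; p < parts_x.size(); ++p) {
    NumericMatrix mm((int)parts_x[p].size(), 2);
    for (size_t i = 0; i < parts_x[p].size(); ++i) {
      mm(i, 0) = parts_x[p][i];
      mm(i, 1) = parts_y[p][i];
    }
    out[p] = mm;
  }
  return out;
}

// Minimum euclidean distance from each point to the ring boundary edges.
// [[Rcpp::export]]
NumericVector cpp_dist_to_rings(NumericVector px, NumericVector py, List rings) {
  std::vector<Ring> rs = as_rings(rings);
  int n = px.size();
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    double best = R_PosInf;
    for (const Ring& r : rs) {
      int m = (int)r.x.size();
      for (int i = 0, j = m - 1; i < m; j = i++) {
        double ax = r.x[j], ay = r.y[j], bx = r.x[i], by = r.y[i];
        double vx = bx - ax, vy = by - ay;
        double L2 = vx * vx + vy * vy;
        double t = 0.0;
        if (L2 > 0) {
          t = ((px[q] - ax) * vx + (py[q] - ay) * vy) / L2;
          t = std::max(0.0, std::min(1.0, t));
        }
        double dx = px[q] - (ax + t * vx), dy = py[q] - (ay + t * vy);
        double d = std::sqrt(dx * dx + dy * dy);
        if (d < best) best = d;
      }
    }
    out[q] = best;
  }
  return out;
}
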