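#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Orientation of c relative to the directed line a->b.
// mag receives the magnitude scale of the two products, used for a
// relative degeneracy threshold.
static inline double orient2d(double ax, double ay, double bx, double by,
                              double cx, double cy, double &mag) {
  double t1 = (bx - ax) * (cy - ay);
  double t2 = (by - ay) * (cx - ax);
  mag = std::fabs(t1) + std::fabs(t2);
  return t1 - t2;
}

static const double REL_EPS = 1e-12;

static inline bool near_zero(double d, double mag) {
  return std::fabs(d) <= REL_EPS * mag;
}

// [[Rcpp::export]]
List cpp_edge_crossings(NumericVector ax, NumericVector ay,
                        NumericVector bx, NumericVector by) {
  int na = ax.size(), nb = bx.size();
  std::vector<int> ei, ej;
  std::vector<double> tt, uu, px, py;
  bool degenerate = false;

  // per-edge bounding boxes
  std::vector<double> axlo(na), axhi(na), aylo(na), ayhi(na);
  for (int i = 0; i < na; ++i) {
    int i2 = (i + 1) % na;
    axlo[i] = std::min(ax[i], ax[i2]); axhi[i] = std::max(ax[i], ax[i2]);
    aylo[i] = std::min(ay[i], ay[i2]); ayhi[i] = std::max(ay[i], ay[i2]);
  }

  for (int j = 0; j < nb && !degenerate; ++j) {
    int j2 = (j + 1) % nb;
    double bxlo = std::min(bx[j], bx[j2]), bxhi = std::max(bx[j], bx[j2]);
    double bylo = std::min(by[j], by[j2]), byhi = std::max(by[j], by[j2]);
    for (int i = 0; i < na; ++i) {
      if (axlo[i] > bxhi || axhi[i] < bxlo || aylo[i] > byhi || ayhi[i] < bylo)
        continue;
      int i2 = (i + 1) % na;
      double m1, m2, m3, m4;
      double d1 = orient2d(bx[j], by[j], bx[j2], by[j2], ax[i], ay[i], m1);
      double d2 = orient2d(bx[j], by[j], bx[j2], by[j2], ax[i2], ay[i2], m2);
      double d3 = orient2d(ax[i], ay[i], ax[i2], ay[i2], bx[j], by[j], m3);
      double d4 = orient2d(ax[i], ay[i], ax[i2], ay[i2], bx[j2], by[j2], m4);
      if (near_zero(d1, m1) || near_zero(d2, m2) ||
          near_zero(d3, m3) || near_zero(d4, m4)) {
        degenerate = true;
        break;
      }
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) {
        double t = d1 / (d1 - d2);   // parameter along edge i of A
        double u = d3 / (d3 - d4);   // parameter along edge j of B
        ei.push_back(i + 1);
        ej.push_back(j + 1);
        tt.push_back(t);
        uu.push_back(u);
        px.push_back(ax[i] + t * (ax[i2] - ax[i]));
        py.push_back(ay[i] + t * (ay[i2] - ay[i]));
      }
    }
  }
  return List::create(_["i"] = wrap(ei), _["j"] = wrap(ej),
                      _["t"] = wrap(tt), _["u"] = wrap(uu),
                      _["x"] = wrap(px), _["y"] = wrap(py),
                      _["degenerate"] = degenerate);
}

// Even-odd point-in-polygon test; points on the boundary are classified
// arbitrarily (callers guarantee generic position).
// [[Rcpp::export]]
LogicalVector cpp_point_in_poly(NumericVector px, NumericVector py,
                                NumericVector vx, NumericVector vy) {
  int np = px.size(), nv = vx.size();
  LogicalVector out(np);
  for (int p = 0; p < np; ++p) {
    bool inside = false;
    for (int i = 0, j = nv - 1; i < nv; j = i++) {
      if ((vy[i] > py[p]) != (vy[j] > py[p])) {
        double xint = vx[i] + (py[p] - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i]);
        if (px[p] < xint) inside = !inside;
      }
    }
    out[p] = inside;
  }
  return out;
}

static inline bool on_segment_collinear(double ax, double ay, double bx,
                                        double by, double cx, double cy) {
  // assumes c collinear with a-b; true if c within the segment bbox
  return std::min(ax, bx) <= cx && cx <= std::max(ax, bx) &&
         std::min(ay, by) <= cy && cy <= std::max(ay, by);
}

// TRUE when the closed polygon is simple: no coincident consecutive
// vertices, no backtracking spikes, no non-adjacent edge contact.
// [[Rcpp::export]]
bool cpp_is_simple(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 3) return false;
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    if (x[i] == x[i2] && y[i] == y[i2]) return false;
  }
  // spikes: consecutive triple collinear with reversal
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n, i3 = (i + 2) % n;
    double m;
    double d = orient2d(x[i], y[i], x[i2], y[i2], x[i3], y[i3], m);
    if (near_zero(d, m)) {
      double dot = (x[i2] - x[i]) * (x[i3] - x[i2]) +
                   (y[i2] - y[i]) * (y[i3] - y[i2]);
      if (dot < 0) return false;
    }
  }
  // non-adjacent edge pairs
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    double xlo = std::min(x[i], x[i2]), xhi = std::max(x[i], x[i2]);
    double ylo = std::min(y[i], y[i2]), yhi = std::max(y[i], y[i2]);
    for (int j = i + 1; j < n; ++j) {
      if (j == i || j == i2 || (j + 1) % n == i) continue; // adjacent
      int j2 = (j + 1) % n;
      if (std::min(x[j], x[j2]) > xhi || std::max(x[j], x[j2]) < xlo ||
          std::min(y[j], y[j2]) > yhi || std::max(y[j], y[j2]) < ylo)
        continue;
      double m1, m2, m3, m4;
      double d1 = orient2d(x[j], y[j], x[j2], y[j2], x[i], y[i], m1);
      double d2 = orient2d(x[j], y[j], x[j2], y[j2], x[i2], y[i2], m2);
      double d3 = orient2d(x[i], y[i], x[i2], y[i2], x[j], y[j], m3);
      double d4 = orient2d(x[i], y[i], x[i2], y[i2], x[j2], y[j2], m4);
      bool z1 = near_zero(d1, m1), z2 = near_zero(d2, m2);
      bool z3 = near_zero(d3, m3), z4 = near_zero(d4, m4);
      if (!z1 && !z2 && !z3 && !z4) {
        if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return false;
      } else {
        if (z1 && on_segment_collinear(x[j], y[j], x[j2], y[j2], x[i], y[i]))
          return false;
        if (z2 && on_segment_collinear(x[j], y[j], x[j2], y[j2], x[i2], y[i2]))
          return false;
        if (z3 && on_segment_collinear(x[i], y[i], x[i2], y[i2], x[j], y[j]))
          return false;
        if (z4 && on_segment_collinear(x[i], y[i], x[i2], y[i2], x[j2], y[j2]))
          return false;
      }
    }
  }
  return true;
}

// Signed shoelace area (positive when vertex order is counterclockwise
// in a standard right-handed frame).
// [[Rcpp::export]]
double cpp_signed_area(NumericVector x, NumericVector y) {
  int n = x.size();
  double s = 0.0;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    s += x[j] * y[i] - x[i] * y[j];
  }
  return 0.5 * s;
}
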