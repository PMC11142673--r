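#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Lattice Dijkstra over a conductance raster stored row-major (0-based cell
// index = row * ncol + col, row 0 at the top). Edge weight between neighbor
// cells i,j is d(i,j) / ((c_i + c_j)/2); cells with conductance <= 0 are hard
// barriers and carry no edges. Ties between equal-cost relaxations keep the
// lexicographically smallest (row-major) predecessor so that extracted paths
// are reproducible across runs and platforms.
// [[Rcpp::export]]
List cpp_dijkstra(NumericVector cond, int nrow, int ncol, int connectivity,
                  double cellsize, int src0) {
  const int n = nrow * ncol;
  if (src0 < 0 || src0 >= n) stop("source cell index out of range");
  std::vector<double> dist(n, std::numeric_limits<double>::infinity());
  std::vector<int> parent(n, -1);

  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4b[4] = {-1, 1, 0, 0};
  const int dc4b[4] = {0, 0, -1, 1};

  typedef std::pair<double, int> QE;  // (dist, node); smaller node wins ties
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;

  if (cond[src0] <= 0) stop("source cell has zero conductance");
  dist[src0] = 0.0;
  pq.push(QE(0.0, src0));
  const double sqrt2 = std::sqrt(2.0);

  while (!pq.empty()) {
    QE top = pq.top();
    pq.pop();
    double du = top.first;
    int u = top.second;
    if (du > dist[u]) continue;
    int ur = u / ncol, uc = u % ncol;
    double cu = cond[u];
    int nnb = (connectivity == 8) ? 8 : 4;
    for (int k = 0; k < nnb; ++k) {
      int vr, vc;
      if (connectivity == 8) {
        vr = ur + dr8[k]; vc = uc + dc8[k];
      } else {
        vr = ur + dr4b[k]; vc = uc + dc4b[k];
      }
      if (vr < 0 || vr >= nrow || vc < 0 || vc >= ncol) continue;
      int v = vr * ncol + vc;
      double cv = cond[v];
      if (cv <= 0) continue;
      double d = (vr != ur && vc != uc) ? cellsize * sqrt2 : cellsize;
      double w = d / ((cu + cv) / 2.0);
      double nd = du + w;
      if (nd < dist[v]) {
        dist[v] = nd;
        parent[v] = u;
        pq.push(QE(nd, v));
      } else if (nd == dist[v] && parent[v] >= 0 && u < parent[v]) {
        parent[v] = u;
      }
    }
  }
  return List::create(_["dist"] = NumericVector(dist.begin(), dist.end()),
                      _["parent"] = IntegerVector(parent.begin(), parent.end()));
}

// Minimum Euclidean distance from each point to a set of line segments.
// If cutoff >= 0, scanning stops for a point once a distance <= cutoff is
// found (the returned value is then that distance, sufficient for
// containment tests against a buffer half-width).
// [[Rcpp::export]]
NumericVector cpp_min_dist_segments(NumericVector px, NumericVector py,
                                    NumericVector x0, NumericVector y0,
                                    NumericVector x1, NumericVector y1,
                                    double cutoff) {
  int np = px.size(), ns = x0.size();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double best2 = std::numeric_limits<double>::infinity();
    double cx = px[i], cy = py[i];
    for (int j = 0; j < ns; ++j) {
      double ax = x0[j], ay = y0[j], bx = x1[j], by = y1[j];
      double dx = bx - ax, dy = by - ay;
      double len2 = dx * dx + dy * dy;
      double qx, qy;
      if (len2 <= 0) {
        qx = ax; qy = ay;
      } else {
        double t = ((cx - ax) * dx + (cy - ay) * dy) / len2;
        if (t < 0) t = 0; else if (t > 1) t = 1;
        qx = ax + t * dx; qy = ay + t * dy;
      }
      double d2 = (cx - qx) * (cx - qx) + (cy - qy) * (cy - qy);
      if (d2 < best2) {
        best2 = d2;
        if (cutoff >= 0 && best2 <= cutoff * cutoff) break;
      }
    }
    out[i] = std::sqrt(best2);
  }
  return out;
}

// Connected-component labelling of a logical mask (row-major). Labels are
// assigned 1..K in row-major order of each component's first cell, so the
// labelling is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, int nrow, int ncol,
                                   int connectivity) {
  const int n = nrow * ncol;
  IntegerVector lab(n, 0);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  int nnb = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      int ur = u / ncol, uc = u % ncol;
      for (int k = 0; k < nnb; ++k) {
        int vr = ur + ((connectivity == 8) ? dr8[k] : dr4[k]);
        int vc = uc + ((connectivity == 8) ? dc8[k] : dc4[k]);
        if (vr < 0 || vr >= nrow || vc < 0 || vc >= ncol) continue;
        int v = vr * ncol + vc;
        if (mask[v] && lab[v] == 0) {
          lab[v] = next;
          stack.push_back(v);
        }
      }
    }
  }
  return lab;
}

// Even-odd (ray casting) point-in-ring test; the ring is an open coordinate
// sequence (last vertex implicitly joins the first). Points exactly on an
// edge follow the half-open crossing convention.
// [[Rcpp::export]]
LogicalVector cpp_points_in_ring(NumericVector px, NumericVector py,
                                 NumericVector rx, NumericVector ry) {
  int np = px.size(), nv = rx.size();
  LogicalVector out(np);
  for (int p = 0; p < np; ++p) {
    bool inside = false;
    double x = px[p], y = py[p];
    for (int i = 0, j = nv - 1; i < nv; j = i++) {
      if (((ry[i] > y) != (ry[j] > y)) &&
          (x < (rx[j] - rx[i]) * (y - ry[i]) / (ry[j] - ry[i]) + rx[i]))
        inside = !inside;
    }
    out[p] = inside;
  }
  return out;
}
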