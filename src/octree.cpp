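// Octree spatial index over 3-D points, with radius search, DBSCAN built on
// top of it, nearest-neighbour queries for ICP, and a stem occlusion filter
// for the scan simulator. Indices crossing the R boundary are 1-based.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <limits>
#include <queue>
using namespace Rcpp;

namespace {

struct Node {
  double cx, cy, cz;   // center
  double half;         // half edge length
  std::vector<int> pts;        // point ids (leaves only)
  std::array<int, 8> child;    // node ids, -1 if absent
  bool leaf;
  Node() : cx(0), cy(0), cz(0), half(0), leaf(true) { child.fill(-1); }
};

struct Octree {
  std::vector<Node> nodes;
  std::vector<double> x, y, z;
  double leaf_size;
  size_t n() const { return x.size(); }
};

int octant(const Node& nd, double px, double py, double pz) {
  return (px >= nd.cx ? 1 : 0) | (py >= nd.cy ? 2 : 0) | (pz >= nd.cz ? 4 : 0);
}

const int MAX_LEAF_PTS = 32;

void split(Octree& t, int ni);

void insert(Octree& t, int ni, int pid) {
  Node* nd = &t.nodes[ni];
  if (nd->leaf) {
    nd->pts.push_back(pid);
    if ((int)nd->pts.size() > MAX_LEAF_PTS && nd->half > t.leaf_size / 2.0) {
      split(t, ni);
    }
    return;
  }
  int oc = octant(*nd, t.x[pid], t.y[pid], t.z[pid]);
  if (nd->child[oc] < 0) {
    Node ch;
    double q = nd->half / 2.0;
    ch.cx = nd->cx + ((oc & 1) ? q : -q);
    ch.cy = nd->cy + ((oc & 2) ? q : -q);
    ch.cz = nd->cz + ((oc & 4) ? q : -q);
    ch.half = q;
    t.nodes.push_back(ch);
    // re-fetch: push_back may reallocate
    t.nodes[ni].child[oc] = (int)t.nodes.size() - 1;
  }
  insert(t, t.nodes[ni].child[oc], pid);
}

void split(Octree& t, int ni) {
  std::vector<int> pts;
  pts.swap(t.nodes[ni].pts);
  t.nodes[ni].leaf = false;
  for (int pid : pts) insert(t, ni, pid);
}

// squared distance from point to node box; 0 if inside
double box_dist2(const Node& nd, double px, double py, double pz) {
  double dx = std::max(std::fabs(px - nd.cx) - nd.half, 0.0);
  double dy = std::max(std::fabs(py - nd.cy) - nd.half, 0.0);
  double dz = std::max(std::fabs(pz - nd.cz) - nd.half, 0.0);
  return dx * dx + dy * dy + dz * dz;
}

void radius_collect(const Octree& t, int ni, double px, double py, double pz,
                    double r2, std::vector<int>& out) {
  const Node& nd = t.nodes[ni];
  if (box_dist2(nd, px, py, pz) > r2) return;
  if (nd.leaf) {
    for (int pid : nd.pts) {
      double dx = t.x[pid] - px, dy = t.y[pid] - py, dz = t.z[pid] - pz;
      if (dx * dx + dy * dy + dz * dz <= r2) out.push_back(pid);
    }
    return;
  }
  for (int c : nd.child)
    if (c >= 0) radius_collect(t, c, px, py, pz, r2, out);
}

Octree* build_tree(const NumericMatrix& pts, double leaf_size) {
  Octree* t = new Octree();
  size_t n = pts.nrow();
  t->leaf_size = leaf_size;
  t->x.resize(n); t->y.resize(n); t->z.resize(n);
  double lo[3] = {0, 0, 0}, hi[3] = {0, 0, 0};
  for (size_t i = 0; i < n; ++i) {
    t->x[i] = pts(i, 0); t->y[i] = pts(i, 1); t->z[i] = pts(i, 2);
    for (int d = 0; d < 3; ++d) {
      double v = pts(i, d);
      if (i == 0 || v < lo[d]) lo[d] = v;
      if (i == 0 || v > hi[d]) hi[d] = v;
    }
  }
  Node root;
  root.cx = (lo[0] + hi[0]) / 2.0;
  root.cy = (lo[1] + hi[1]) / 2.0;
  root.cz = (lo[2] + hi[2]) / 2.0;
  double span = 0.0;
  for (int d = 0; d < 3; ++d) span = std::max(span, hi[d] - lo[d]);
  root.half = std::max(span / 2.0, leaf_size) * 1.0000001 + 1e-12;
  t->nodes.push_back(root);
  for (size_t i = 0; i < n; ++i) insert(*t, 0, (int)i);
  return t;
}

}  // namespace

// [[Rcpp::export]]
SEXP octreeBuildCpp(NumericMatrix pts, double leaf_size) {
  XPtr<Octree> p(build_tree(pts, leaf_size), true);
  return p;
}

// [[Rcpp::export]]
IntegerVector octreeRadiusQueryCpp(SEXP ptr, NumericVector center,
                                   double radius) {
  if (R_ExternalPtrAddr(ptr) == nullptr)
    stop("octree pointer is no longer valid; rebuild the index");
  XPtr<Octree> t(ptr);
  std::vector<int> out;
  if (t->n() > 0)
    radius_collect(*t, 0, center[0], center[1], center[2], radius * radius,
                   out);
  IntegerVector res(out.size());
  for (size_t i = 0; i < out.size(); ++i) res[i] = out[i] + 1;
  return res;
}

// [[Rcpp::export]]
int octreeSizeCpp(SEXP ptr) {
  if (R_ExternalPtrAddr(ptr) == nullptr) return -1;
  XPtr<Octree> t(ptr);
  return (int)t->n();
}

// DBSCAN over an octree index. labels: 0 = noise, clusters 1..k in order of
// discovery. types: 0 = core, 1 = border, 2 = noise. Border points reachable
// from several clusters keep the first-discovered cluster.
// [[Rcpp::export]]
List dbscanCpp(NumericMatrix pts, double eps, int min_pts) {
  int n = pts.nrow();
  IntegerVector labels(n, 0), types(n, 2);
  if (n == 0) return List::create(_["labels"] = labels, _["types"] = types);
  Octree* t = build_tree(pts, eps / 2.0);
  double r2 = eps * eps;
  std::vector<bool> visited(n, false);
  std::vector<int> nb;
  int cl = 0;
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = true;
    nb.clear();
    radius_collect(*t, 0, t->x[i], t->y[i], t->z[i], r2, nb);
    if ((int)nb.size() < min_pts) continue;  // not core (may become border)
    ++cl;
    types[i] = 0;
    labels[i] = cl;
    std::queue<int> q;
    for (int j : nb) q.push(j);
    while (!q.empty()) {
      int j = q.front(); q.pop();
      if (labels[j] == 0) {          // unclaimed: join this cluster
        labels[j] = cl;
        if (types[j] == 2) types[j] = 1;  // provisional border
      }
      if (visited[j]) continue;
      visited[j] = true;
      std::vector<int> nb2;
      radius_collect(*t, 0, t->x[j], t->y[j], t->z[j], r2, nb2);
      if ((int)nb2.size() >= min_pts) {
        types[j] = 0;
        for (int k : nb2) {
          if (labels[k] == 0) {
            labels[k] = cl;
            if (types[k] == 2) types[k] = 1;
          }
          if (!visited[k]) q.push(k);
        }
      }
    }
  }
  delete t;
  return List::create(_["labels"] = labels, _["types"] = types);
}

// For each query point, index (1-based) and distance of nearest ref point.
// [[Rcpp::export]]
List nearestNeighborCpp(NumericMatrix query, NumericMatrix ref) {
  int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = std::numeric_limits<double>::infinity();
    int bj = 0;
    for (int j = 0; j < nr; ++j) {
      double dx = ref(j, 0) - qx, dy = ref(j, 1) - qy, dz = ref(j, 2) - qz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// Line-of-sight occlusion by vertical stems, sensor at the origin.
// stems: columns x, y, z_base, z_top, radius (sensor frame). A point is
// dropped when the ray from the origin passes within `radius` (horizontally)
// of a stem axis at least 0.1 m before the point, at a height between the
// stem base and top.
// [[Rcpp::export]]
LogicalVector occludeCpp(NumericMatrix pts, NumericMatrix stems) {
  int n = pts.nrow(), ns = stems.nrow();
  LogicalVector keep(n, true);
  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double hlen2 = px * px + py * py;
    if (hlen2 < 1e-12) continue;
    double hlen = std::sqrt(hlen2);
    for (int s = 0; s < ns; ++s) {
      double sx = stems(s, 0), sy = stems(s, 1);
      double tpar = (sx * px + sy * py) / hlen2;  // along-ray parameter
      if (tpar <= 0.0 || tpar * hlen >= hlen - 0.1) continue;
      double dx = sx - tpar * px, dy = sy - tpar * py;
      double r = stems(s, 4);
      if (dx * dx + dy * dy > r * r) continue;
      double zray = tpar * pz;
      if (zray >= stems(s, 2) && zray <= stems(s, 3)) {
        keep[i] = false;
        break;
      }
    }
  }
  return keep;
}
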