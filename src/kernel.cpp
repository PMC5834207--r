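// Compiled core: triangle-mesh nearest-point index, segment spatial hash,
// deterministic RNG, and the network stepping kernel.
//
// All geometry is in micrometres. A tubulin ring is a unit vector of
// physical length ell (8 nm = 0.008 um); a microtubule is a chain of such
// vectors from minus end to plus end.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <deque>
#include <unordered_map>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Small vector algebra
// ---------------------------------------------------------------------------

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
};

static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }
static inline Vec3 normalize(const Vec3& a) {
  double n = norm(a);
  return (n > 0) ? a * (1.0 / n) : Vec3(0, 0, 0);
}

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded by splitmix64; platform-independent stream
// ---------------------------------------------------------------------------

struct RNG {
  uint64_t s[4];
  bool has_spare;
  double spare;

  static uint64_t splitmix64(uint64_t& x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t sd) {
    uint64_t x = sd;
    for (int i = 0; i < 4; i++) s[i] = splitmix64(x);
    has_spare = false;
    spare = 0.0;
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0, 1)
  double unif() {
    double u;
    do { u = (next() >> 11) * 0x1.0p-53; } while (u <= 0.0);
    return u;
  }
  // standard normal, Box-Muller with spare caching (deterministic)
  double norm1() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
  // exactly isotropic unit vector (normalised 3D Gaussian)
  Vec3 unit_vec() {
    for (;;) {
      Vec3 v(norm1(), norm1(), norm1());
      double n = norm(v);
      if (n > 1e-8) return v * (1.0 / n);
    }
  }
  int poisson(double lambda) {
    if (lambda <= 0) return 0;
    double L = std::exp(-lambda), p = 1.0;
    int k = 0;
    do { k++; p *= unif(); } while (p > L);
    return k - 1;
  }
};

// ---------------------------------------------------------------------------
// Closest point on a triangle (Ericson, Real-Time Collision Detection)
// ---------------------------------------------------------------------------

static Vec3 closest_point_triangle(const Vec3& p, const Vec3& a, const Vec3& b,
                                   const Vec3& c, double& u, double& v, double& w) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { u = 1; v = 0; w = 0; return a; }

  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { u = 0; v = 1; w = 0; return b; }

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double t = d1 / (d1 - d3);
    u = 1 - t; v = t; w = 0;
    return a + ab * t;
  }

  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { u = 0; v = 0; w = 1; return c; }

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double t = d2 / (d2 - d6);
    u = 1 - t; v = 0; w = t;
    return a + ac * t;
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    u = 0; v = 1 - t; w = t;
    return b + (c - b) * t;
  }

  double denom = 1.0 / (va + vb + vc);
  double vv = vb * denom, ww = vc * denom;
  u = 1 - vv - ww; v = vv; w = ww;
  return a + ab * vv + ac * ww;
}

// ---------------------------------------------------------------------------
// MeshIndex: triangle grid for nearest-surface queries + area-weighted sampling
// ---------------------------------------------------------------------------

struct SurfaceHit {
  Vec3 cp;       // nearest point on the surface
  Vec3 nrm;      // outward unit normal (barycentric-interpolated)
  double dist;   // unsigned distance
  double sgn;    // (p - cp) . n : > 0 outside
  int tri;
};

struct MeshIndex {
  int nv, nf;
  std::vector<Vec3> V, VN;
  std::vector<int> F;               // 3 * nf
  std::vector<double> cum_area;
  double total_area;
  // uniform grid over triangle AABBs
  double cell;
  Vec3 gmin, gmax;
  int nx, ny, nz;
  std::vector<std::vector<int>> cells;
  mutable std::vector<int> stamp;   // triangle de-dup marks
  mutable int stamp_cur;

  int cell_index(int i, int j, int k) const { return (k * ny + j) * nx + i; }

  void build(const NumericMatrix& Vm, const IntegerMatrix& Fm,
             const NumericMatrix& VNm) {
    nv = Vm.nrow(); nf = Fm.nrow();
    V.resize(nv); VN.resize(nv); F.resize(3 * nf);
    for (int i = 0; i < nv; i++) {
      V[i] = Vec3(Vm(i, 0), Vm(i, 1), Vm(i, 2));
      VN[i] = normalize(Vec3(VNm(i, 0), VNm(i, 1), VNm(i, 2)));
    }
    double max_edge = 0;
    cum_area.resize(nf);
    total_area = 0;
    gmin = Vec3(1e30, 1e30, 1e30); gmax = Vec3(-1e30, -1e30, -1e30);
    for (int t = 0; t < nf; t++) {
      int a = Fm(t, 0) - 1, b = Fm(t, 1) - 1, c = Fm(t, 2) - 1;
      F[3 * t] = a; F[3 * t + 1] = b; F[3 * t + 2] = c;
      total_area += 0.5 * norm(cross(V[b] - V[a], V[c] - V[a]));
      cum_area[t] = total_area;
      max_edge = std::max(max_edge, norm(V[b] - V[a]));
      max_edge = std::max(max_edge, norm(V[c] - V[b]));
      max_edge = std::max(max_edge, norm(V[a] - V[c]));
    }
    for (int i = 0; i < nv; i++) {
      gmin.x = std::min(gmin.x, V[i].x); gmax.x = std::max(gmax.x, V[i].x);
      gmin.y = std::min(gmin.y, V[i].y); gmax.y = std::max(gmax.y, V[i].y);
      gmin.z = std::min(gmin.z, V[i].z); gmax.z = std::max(gmax.z, V[i].z);
    }
    cell = std::max(1.25 * max_edge, 1e-6);
    nx = std::max(1, (int)std::ceil((gmax.x - gmin.x) / cell));
    ny = std::max(1, (int)std::ceil((gmax.y - gmin.y) / cell));
    nz = std::max(1, (int)std::ceil((gmax.z - gmin.z) / cell));
    cells.assign((size_t)nx * ny * nz, {});
    for (int t = 0; t < nf; t++) {
      const Vec3& a = V[F[3 * t]]; const Vec3& b = V[F[3 * t + 1]];
      const Vec3& c = V[F[3 * t + 2]];
      double lox = std::min({a.x, b.x, c.x}), hix = std::max({a.x, b.x, c.x});
      double loy = std::min({a.y, b.y, c.y}), hiy = std::max({a.y, b.y, c.y});
      double loz = std::min({a.z, b.z, c.z}), hiz = std::max({a.z, b.z, c.z});
      int i0 = clampi((int)((lox - gmin.x) / cell), nx);
      int i1 = clampi((int)((hix - gmin.x) / cell), nx);
      int j0 = clampi((int)((loy - gmin.y) / cell), ny);
      int j1 = clampi((int)((hiy - gmin.y) / cell), ny);
      int k0 = clampi((int)((loz - gmin.z) / cell), nz);
      int k1 = clampi((int)((hiz - gmin.z) / cell), nz);
      for (int k = k0; k <= k1; k++)
        for (int j = j0; j <= j1; j++)
          for (int i = i0; i <= i1; i++)
            cells[cell_index(i, j, k)].push_back(t);
    }
    stamp.assign(nf, -1);
    stamp_cur = 0;
  }

  static int clampi(int v, int n) { return std::max(0, std::min(n - 1, v)); }

  double cell_min_dist(const Vec3& p, int i, int j, int k) const {
    double lox = gmin.x + i * cell, hix = lox + cell;
    double loy = gmin.y + j * cell, hiy = loy + cell;
    double loz = gmin.z + k * cell, hiz = loz + cell;
    double dx = std::max({lox - p.x, 0.0, p.x - hix});
    double dy = std::max({loy - p.y, 0.0, p.y - hiy});
    double dz = std::max({loz - p.z, 0.0, p.z - hiz});
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  }

  void consider(const Vec3& p, int t, SurfaceHit& best) const {
    if (stamp[t] == stamp_cur) return;
    stamp[t] = stamp_cur;
    int a = F[3 * t], b = F[3 * t + 1], c = F[3 * t + 2];
    double u, v, w;
    Vec3 cp = closest_point_triangle(p, V[a], V[b], V[c], u, v, w);
    Vec3 d = p - cp;
    double dist = norm(d);
    if (dist < best.dist) {
      best.dist = dist;
      best.cp = cp;
      best.tri = t;
      best.nrm = normalize(VN[a] * u + VN[b] * v + VN[c] * w);
      best.sgn = dot(d, best.nrm);
    }
  }

  // hint_tri: optional warm start (previous nearest triangle), -1 for none
  SurfaceHit nearest(const Vec3& p, int hint_tri = -1) const {
    stamp_cur++;
    SurfaceHit best;
    best.dist = std::numeric_limits<double>::infinity();
    best.tri = -1;
    if (hint_tri >= 0 && hint_tri < nf) consider(p, hint_tri, best);

    int ci = clampi((int)((p.x - gmin.x) / cell), nx);
    int cj = clampi((int)((p.y - gmin.y) / cell), ny);
    int ck = clampi((int)((p.z - gmin.z) / cell), nz);
    double delta = cell_min_dist(p, ci, cj, ck);  // 0 when p inside the grid

    int max_shell = std::max({nx, ny, nz});
    for (int s = 0; s <= max_shell; s++) {
      // cells at Chebyshev index distance s from (ci, cj, ck)
      int i0 = ci - s, i1 = ci + s, j0 = cj - s, j1 = cj + s;
      int k0 = ck - s, k1 = ck + s;
      for (int k = std::max(0, k0); k <= std::min(nz - 1, k1); k++)
        for (int j = std::max(0, j0); j <= std::min(ny - 1, j1); j++)
          for (int i = std::max(0, i0); i <= std::min(nx - 1, i1); i++) {
            if (s > 0 && i != i0 && i != i1 && j != j0 && j != j1 &&
                k != k0 && k != k1) continue;  // interior of the shell
            const std::vector<int>& lst = cells[cell_index(i, j, k)];
            if (lst.empty()) continue;
            if (cell_min_dist(p, i, j, k) >= best.dist) continue;
            for (int t : lst) consider(p, t, best);
          }
      // shell s+1 lies at distance >= s*cell - delta from p
      if (best.tri >= 0 && best.dist <= s * cell - delta) break;
    }
    return best;
  }

  bool inside(const Vec3& p, double tol = 1e-9) const {
    SurfaceHit h = nearest(p);
    return h.sgn < tol;
  }

  // area-weighted uniform surface sample
  void sample(RNG& rng, Vec3& pt, Vec3& nrm, int& tri) const {
    double x = rng.unif() * total_area;
    int lo = 0, hi = nf - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum_area[mid] < x) lo = mid + 1; else hi = mid;
    }
    tri = lo;
    int a = F[3 * tri], b = F[3 * tri + 1], c = F[3 * tri + 2];
    double s = std::sqrt(rng.unif());
    double t = rng.unif();
    double u = 1 - s, v = s * (1 - t), w = s * t;
    pt = V[a] * u + V[b] * v + V[c] * w;
    nrm = normalize(VN[a] * u + VN[b] * v + VN[c] * w);
  }
};

// [[Rcpp::export]]
SEXP mesh_index_build(NumericMatrix vertices, IntegerMatrix faces,
                      NumericMatrix normals) {
  MeshIndex* m = new MeshIndex();
  m->build(vertices, faces, normals);
  XPtr<MeshIndex> p(m, true);
  return p;
}

// [[Rcpp::export]]
double mesh_index_area(SEXP xp) {
  XPtr<MeshIndex> m(xp);
  return m->total_area;
}

// [[Rcpp::export]]
List mesh_index_nearest(SEXP xp, NumericMatrix points) {
  XPtr<MeshIndex> m(xp);
  int n = points.nrow();
  NumericMatrix cp(n, 3), nr(n, 3);
  NumericVector d(n), sg(n);
  LogicalVector ins(n);
  for (int i = 0; i < n; i++) {
    Vec3 p(points(i, 0), points(i, 1), points(i, 2));
    SurfaceHit h = m->nearest(p);
    cp(i, 0) = h.cp.x; cp(i, 1) = h.cp.y; cp(i, 2) = h.cp.z;
    nr(i, 0) = h.nrm.x; nr(i, 1) = h.nrm.y; nr(i, 2) = h.nrm.z;
    d[i] = h.dist;
    sg[i] = h.sgn;
    ins[i] = h.sgn < 1e-9;
  }
  return List::create(_["nearest"] = cp, _["normal"] = nr, _["distance"] = d,
                      _["signed"] = sg, _["inside"] = ins);
}

// [[Rcpp::export]]
List mesh_index_sample(SEXP xp, int n, double seed) {
  XPtr<MeshIndex> m(xp);
  RNG rng;
  rng.seed((uint64_t)seed);
  NumericMatrix pts(n, 3), nrm(n, 3);
  IntegerVector tri(n);
  for (int i = 0; i < n; i++) {
    Vec3 p, nv; int t;
    m->sample(rng, p, nv, t);
    pts(i, 0) = p.x; pts(i, 1) = p.y; pts(i, 2) = p.z;
    nrm(i, 0) = nv.x; nrm(i, 1) = nv.y; nrm(i, 2) = nv.z;
    tri[i] = t + 1;
  }
  return List::create(_["points"] = pts, _["normals"] = nrm, _["triangle"] = tri);
}

// ---------------------------------------------------------------------------
// Segment spatial hash (locality-sensitive bucketing on endpoint position)
// ---------------------------------------------------------------------------

struct SegRef {
  int mt;
  long gidx;    // global segment index within its microtubule
  Vec3 pos;     // endpoint
  Vec3 dir;
};

struct SegGrid {
  double bucket;
  std::unordered_map<int64_t, std::vector<SegRef>> map;

  static int64_t key(int ix, int iy, int iz) {
    return ((int64_t)(ix + 1048576) << 42) | ((int64_t)(iy + 1048576) << 21) |
           (int64_t)(iz + 1048576);
  }
  int64_t key_of(const Vec3& p) const {
    return key((int)std::floor(p.x / bucket), (int)std::floor(p.y / bucket),
               (int)std::floor(p.z / bucket));
  }
  void insert(const SegRef& r) { map[key_of(r.pos)].push_back(r); }
  void remove(int mt, long gidx, const Vec3& pos) {
    auto it = map.find(key_of(pos));
    if (it == map.end()) return;
    std::vector<SegRef>& v = it->second;
    for (size_t i = 0; i < v.size(); i++) {
      if (v[i].mt == mt && v[i].gidx == gidx) {
        v[i] = v.back();
        v.pop_back();
        return;
      }
    }
  }
  // visit every segment in buckets overlapping the ball of given radius
  // (radius <= bucket gives at most 8 bucket lookups)
  template <typename Fn>
  void visit(const Vec3& p, double radius, Fn fn) const {
    int x0 = (int)std::floor((p.x - radius) / bucket);
    int x1 = (int)std::floor((p.x + radius) / bucket);
    int y0 = (int)std::floor((p.y - radius) / bucket);
    int y1 = (int)std::floor((p.y + radius) / bucket);
    int z0 = (int)std::floor((p.z - radius) / bucket);
    int z1 = (int)std::floor((p.z + radius) / bucket);
    for (int iz = z0; iz <= z1; iz++)
      for (int iy = y0; iy <= y1; iy++)
        for (int ix = x0; ix <= x1; ix++) {
          auto it = map.find(key(ix, iy, iz));
          if (it == map.end()) continue;
          for (const SegRef& r : it->second) fn(r);
        }
  }
};

// standalone point grid for query_neighbors() and its brute-force oracle test
struct PointGrid {
  SegGrid grid;
  int n;
};

// [[Rcpp::export]]
SEXP point_grid_build(NumericMatrix pts, double bucket) {
  PointGrid* g = new PointGrid();
  g->grid.bucket = bucket;
  g->n = pts.nrow();
  for (int i = 0; i < g->n; i++) {
    SegRef r;
    r.mt = i; r.gidx = i;
    r.pos = Vec3(pts(i, 0), pts(i, 1), pts(i, 2));
    r.dir = Vec3(0, 0, 1);
    g->grid.insert(r);
  }
  XPtr<PointGrid> p(g, true);
  return p;
}

// [[Rcpp::export]]
IntegerVector point_grid_query(SEXP xp, NumericVector point, double radius) {
  XPtr<PointGrid> g(xp);
  if (radius > g->grid.bucket)
    stop("query radius exceeds the bucket size of the index");
  Vec3 p(point[0], point[1], point[2]);
  std::vector<int> out;
  double r2 = radius * radius;
  g->grid.visit(p, radius, [&](const SegRef& r) {
    Vec3 d = r.pos - p;
    if (dot(d, d) <= r2) out.push_back(r.mt + 1);
  });
  std::sort(out.begin(), out.end());
  return wrap(out);
}

// ---------------------------------------------------------------------------
// Bundle classification: segment has a companion of another microtubule
// within dist and with line angle <= angle threshold
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector bundle_flags_cpp(NumericMatrix pos, NumericMatrix dir,
                               IntegerVector mt, double dist_thresh,
                               double cos_min) {
  int n = pos.nrow();
  SegGrid grid;
  grid.bucket = std::max(dist_thresh, 1e-6);
  for (int i = 0; i < n; i++) {
    SegRef r;
    r.mt = mt[i]; r.gidx = i;
    r.pos = Vec3(pos(i, 0), pos(i, 1), pos(i, 2));
    r.dir = Vec3(dir(i, 0), dir(i, 1), dir(i, 2));
    grid.insert(r);
  }
  LogicalVector out(n);
  double r2 = dist_thresh * dist_thresh;
  for (int i = 0; i < n; i++) {
    Vec3 p(pos(i, 0), pos(i, 1), pos(i, 2));
    Vec3 d(dir(i, 0), dir(i, 1), dir(i, 2));
    bool found = false;
    grid.visit(p, dist_thresh, [&](const SegRef& r) {
      if (found || r.mt == mt[i]) return;
      Vec3 dd = r.pos - p;
      if (dot(dd, dd) > r2) return;
      if (std::fabs(dot(d, r.dir)) >= cos_min - 1e-12) found = true;
    });
    out[i] = found;
  }
  return out;
}

// ---------------------------------------------------------------------------
// The simulation
// ---------------------------------------------------------------------------

struct MT {
  int id;
  bool minus_shrinking, plus_cat;
  long base_index;            // global index of first stored segment
  Vec3 origin;                // minus-end origin of the first segment
  std::deque<Vec3> dir, pos;  // unit directions / endpoints, minus -> plus
  int mem_tri;                // warm-start triangle for membrane queries
  double mem_clear;           // lower bound on the tip-membrane distance
  MT() : minus_shrinking(false), plus_cat(false), base_index(0), mem_tri(-1),
         mem_clear(0) {}
  size_t size() const { return dir.size(); }
  long tip_gidx() const { return base_index + (long)dir.size() - 1; }
};

struct SimParamsC {
  double n_p, n_s, r_d, b_d, alpha_deg, ell;
  double interaction_radius, membrane_radius;
  double events_per_step;     // < 0 -> derive from n_p * area / ell^2
  int anchoring;              // 0 weak, 1 strong
  int cue;                    // 0 none, 1 circumferential
  Vec3 cue_axis, cue_center;
  int retry_budget, self_exclusion;
  int nucleation_dir;         // 0 isotropic (inward), 1 tangential
};

struct Simulation {
  XPtr<MeshIndex> mesh;
  SimParamsC par;
  RNG rng;
  SegGrid grid;
  std::vector<MT> mts;
  long step_count, next_id;
  double lambda;              // nucleation events per step
  double cos_alpha, sin_alpha;
  // per-step trace
  std::vector<long> tr_step, tr_nmt, tr_nseg, tr_added, tr_removed,
      tr_nucleated, tr_zipper, tr_cat_mt, tr_cat_mem, tr_fallback;
  long total_segments;

  Simulation(SEXP mesh_xp, const SimParamsC& p, uint64_t seed)
      : mesh(mesh_xp), par(p), step_count(0), next_id(0), total_segments(0) {
    rng.seed(seed);
    grid.bucket = 2.0 * par.interaction_radius;
    lambda = (par.events_per_step >= 0)
                 ? par.events_per_step
                 : par.n_p * mesh->total_area / (par.ell * par.ell);
    cos_alpha = std::cos(par.alpha_deg * M_PI / 180.0);
    sin_alpha = std::sin(par.alpha_deg * M_PI / 180.0);
  }

  void append_segment(MT& m, const Vec3& d) {
    Vec3 tip = m.size() ? m.pos.back() : m.origin;
    Vec3 ep = tip + d * par.ell;
    m.dir.push_back(d);
    m.pos.push_back(ep);
    SegRef r; r.mt = m.id; r.gidx = m.tip_gidx(); r.pos = ep; r.dir = d;
    grid.insert(r);
    total_segments++;
  }

  void remove_minus(MT& m) {
    grid.remove(m.id, m.base_index, m.pos.front());
    m.origin = m.pos.front();
    m.dir.pop_front();
    m.pos.pop_front();
    m.base_index++;
    total_segments--;
  }

  void remove_plus(MT& m) {
    grid.remove(m.id, m.tip_gidx(), m.pos.back());
    m.dir.pop_back();
    m.pos.pop_back();
    total_segments--;
  }

  Vec3 tangential_unit(const Vec3& n) {
    for (int k = 0; k < 64; k++) {
      Vec3 u = rng.unit_vec();
      Vec3 t = u - n * dot(u, n);
      double tn = norm(t);
      if (tn > 1e-8) return t * (1.0 / tn);
    }
    // deterministic fallback basis
    Vec3 a = std::fabs(n.x) < 0.9 ? Vec3(1, 0, 0) : Vec3(0, 1, 0);
    return normalize(cross(n, a));
  }

  void nucleate_one() {
    Vec3 p, n; int tri;
    mesh->sample(rng, p, n, tri);
    Vec3 d;
    if (par.anchoring == 1 || par.nucleation_dir == 1) {
      d = tangential_unit(n);
    } else {
      // isotropic, resampled until the first endpoint lies inside the cell
      // (the dot-product test alone is insufficient near rounded corners
      // where interpolated vertex normals deviate from the facet planes)
      bool ok = false;
      for (int k = 0; k < 256 && !ok; k++) {
        d = rng.unit_vec();
        if (dot(d, n) > 1e-12) continue;
        SurfaceHit he = mesh->nearest(p + d * par.ell, tri);
        ok = (he.sgn < 1e-9);
      }
      if (!ok) d = n * (-1.0);  // straight inward
    }
    MT m;
    m.id = (int)next_id++;
    m.origin = p;
    m.mem_tri = tri;
    mts.push_back(std::move(m));
    append_segment(mts.back(), d);
  }

  // Eq 1 / Eq 2 proposal from current tip direction
  Vec3 propose(const Vec3& tdir, const Vec3& tip) {
    double bd = 0.0;
    Vec3 b(0, 0, 0);
    if (par.cue == 1 && par.b_d > 0) {
      Vec3 rel = tip - par.cue_center;
      Vec3 rad = rel - par.cue_axis * dot(rel, par.cue_axis);
      double rn = norm(rad);
      if (rn > 1e-9) {
        b = normalize(cross(par.cue_axis, rad * (1.0 / rn)));
        if (dot(b, tdir) < 0) b = b * (-1.0);  // nematic sign choice
        bd = par.b_d;
      }
    }
    for (int k = 0; k < 64; k++) {
      Vec3 u = rng.unit_vec();
      Vec3 v = tdir * (1.0 - par.r_d - bd) + u * par.r_d + b * bd;
      double vn = norm(v);
      if (vn > 1e-12) return v * (1.0 / vn);
    }
    return tdir;
  }

  // strong anchoring: project the candidate direction onto the local
  // tangent plane, then re-target the surface so the tip tracks it without
  // secular drift (the appended segment keeps exact length ell)
  void strong_append(MT& m, const Vec3& tdir, Vec3 cnd, const SurfaceHit& h,
                     long& fallback) {
    Vec3 tip = m.pos.back();
    Vec3 t = cnd - h.nrm * dot(cnd, h.nrm);
    int k = 0;
    while (norm(t) < 1e-8 && k++ < par.retry_budget) {
      cnd = propose(tdir, tip);
      t = cnd - h.nrm * dot(cnd, h.nrm);
    }
    if (norm(t) < 1e-8) { t = tangential_unit(h.nrm); fallback++; }
    t = normalize(t);
    Vec3 target = tip + t * par.ell;
    SurfaceHit h2 = mesh->nearest(target, h.tri);
    Vec3 nd = h2.cp - tip;
    nd = (norm(nd) > 1e-9) ? normalize(nd) : t;
    m.mem_tri = h2.tri;
    append_segment(m, nd);
  }

  // weak anchoring: append the candidate direction if its endpoint stays in
  // the cell; otherwise redraw the noise vector (bounded retries), then fall
  // back to a step pressed against the membrane (aimed slightly inside the
  // surface, which also pulls back a tip that numerically crossed it)
  void weak_append(MT& m, const Vec3& tdir, Vec3 nd, const SurfaceHit& h,
                   long& fallback) {
    Vec3 tip = m.pos.back();
    if (h.sgn < -(par.ell + 1e-9)) {  // membrane out of reach of one step
      append_segment(m, nd);
      return;
    }
    for (int k = 0; k <= par.retry_budget; k++) {
      Vec3 ep = tip + nd * par.ell;
      SurfaceHit he = mesh->nearest(ep, h.tri);
      if (he.sgn < 1e-9) {
        append_segment(m, nd);
        return;
      }
      nd = propose(tdir, tip);
    }
    Vec3 t = nd - h.nrm * dot(nd, h.nrm);
    if (norm(t) < 1e-8) t = tangential_unit(h.nrm);
    t = normalize(t);
    Vec3 target = h.cp + t * par.ell - h.nrm * 0.002;
    Vec3 d2 = target - tip;
    nd = (norm(d2) > 1e-9) ? normalize(d2) : t;
    fallback++;
    append_segment(m, nd);
  }

  void step_once() {
    long added = 0, removed = 0, zipped = 0, cat_mt = 0, cat_mem = 0,
         fallback = 0;
    // (1) nucleation; new microtubules are collidable immediately but only
    // start minus-end roulette and plus-end growth on the following step
    long first_new = next_id;
    int n_nuc = rng.poisson(lambda);
    for (int i = 0; i < n_nuc; i++) nucleate_one();
    added += n_nuc;

    // (2) minus-end updates, id order
    for (MT& m : mts) {
      if (m.size() == 0 || m.id >= first_new) continue;
      if (!m.minus_shrinking) {
        if (rng.unif() < par.n_s) m.minus_shrinking = true;
      } else {
        remove_minus(m);
        removed++;
      }
    }

    // (3) plus-end updates, id order
    size_t n_now = mts.size();
    double ir2 = par.interaction_radius * par.interaction_radius;
    for (size_t im = 0; im < n_now; im++) {
      MT& m = mts[im];
      if (m.size() == 0 || m.id >= first_new) continue;
      if (m.plus_cat) {
        remove_plus(m);
        removed++;
        continue;
      }
      Vec3 tip = m.pos.back();
      Vec3 tdir = m.dir.back();
      Vec3 prop = propose(tdir, tip);

      // membrane probe at the tip (needed for containment regardless of the
      // encounter outcome: microtubules never leave the cell). Since the tip
      // moves at most ell per step, the probe is skipped while the last
      // measured distance guarantees clearance.
      SurfaceHit h;
      m.mem_clear -= par.ell;
      if (par.anchoring == 1 || m.mem_clear <= par.membrane_radius + 1e-4) {
        h = mesh->nearest(tip, m.mem_tri);
        m.mem_tri = h.tri;
        m.mem_clear = h.dist;
      } else {
        h.dist = m.mem_clear;  // conservative lower bound; far from surface
        h.sgn = -m.mem_clear;
        h.nrm = Vec3(0, 0, 1);
        h.cp = tip;
        h.tri = m.mem_tri;
      }

      // (a) microtubule encounter within the interaction radius
      bool have_c = false;
      double cbest = 0;
      SegRef cand;
      long own_tip = m.tip_gidx();
      grid.visit(tip, par.interaction_radius, [&](const SegRef& r) {
        if (r.mt == m.id && r.gidx > own_tip - (long)par.self_exclusion)
          return;  // own last few segments
        Vec3 d = r.pos - tip;
        double d2 = dot(d, d);
        if (d2 > ir2) return;
        if (!have_c || d2 < cbest ||
            (d2 == cbest &&
             (r.mt < cand.mt || (r.mt == cand.mt && r.gidx < cand.gidx)))) {
          have_c = true;
          cbest = d2;
          cand = r;
        }
      });
      if (have_c) {
        double c = dot(tdir, cand.dir);
        if (std::fabs(c) > cos_alpha) {  // line angle < alpha -> zipper
          Vec3 nd = (c >= 0) ? cand.dir : cand.dir * (-1.0);
          // directional noise is intrinsic to every growth step: the
          // zippered direction replaces the previous vector and the usual
          // noisy update applies on top (bundles therefore stay tight but
          // are not frozen in lock-step)
          nd = propose(nd, tip);
          if (par.anchoring == 1) {
            strong_append(m, tdir, nd, h, fallback);
            added++;
            zipped++;
          } else {
            // containment guard: a zippered direction that would exit the
            // cell is handled by the membrane rule instead
            bool exits = false;
            if (h.sgn > -(par.ell + 1e-9)) {
              Vec3 ep = tip + nd * par.ell;
              SurfaceHit he = mesh->nearest(ep, h.tri);
              exits = (he.sgn >= 1e-9);
            }
            if (!exits) {
              append_segment(m, nd);
              added++;
              zipped++;
            } else if (std::fabs(dot(nd, h.nrm)) > sin_alpha) {
              m.plus_cat = true;
              cat_mem++;
            } else {
              weak_append(m, tdir, propose(tdir, tip), h, fallback);
              added++;
              zipped++;
            }
          }
        } else {
          m.plus_cat = true;
          cat_mt++;
        }
        continue;
      }

      // (b) membrane interaction
      if (par.anchoring == 1) {
        strong_append(m, tdir, prop, h, fallback);
        added++;
        continue;
      }
      if (h.dist <= par.membrane_radius &&
          std::fabs(dot(tdir, h.nrm)) > sin_alpha) {
        // steep membrane encounter: catastrophe
        m.plus_cat = true;
        cat_mem++;
        continue;
      }
      weak_append(m, tdir, prop, h, fallback);
      added++;
    }

    // (4) drop empty microtubules (ids stay ordered)
    mts.erase(std::remove_if(mts.begin(), mts.end(),
                             [](const MT& m) { return m.size() == 0; }),
              mts.end());

    // (5) trace
    step_count++;
    tr_step.push_back(step_count);
    tr_nmt.push_back((long)mts.size());
    tr_nseg.push_back(total_segments);
    tr_added.push_back(added);
    tr_removed.push_back(removed);
    tr_nucleated.push_back(n_nuc);
    tr_zipper.push_back(zipped);
    tr_cat_mt.push_back(cat_mt);
    tr_cat_mem.push_back(cat_mem);
    tr_fallback.push_back(fallback);
  }
};

static SimParamsC params_from_list(List p) {
  SimParamsC q;
  q.n_p = as<double>(p["n_p"]);
  q.n_s = as<double>(p["n_s"]);
  q.r_d = as<double>(p["r_d"]);
  q.b_d = as<double>(p["b_d"]);
  q.alpha_deg = as<double>(p["alpha_deg"]);
  q.ell = as<double>(p["ell"]);
  q.interaction_radius = as<double>(p["interaction_radius"]);
  q.membrane_radius = as<double>(p["membrane_radius"]);
  q.events_per_step = as<double>(p["events_per_step"]);
  std::string anch = as<std::string>(p["anchoring"]);
  q.anchoring = (anch == "strong") ? 1 : 0;
  std::string cue = as<std::string>(p["cue"]);
  q.cue = (cue == "circumferential") ? 1 : 0;
  NumericVector ax = p["cue_axis"], ce = p["cue_center"];
  q.cue_axis = normalize(Vec3(ax[0], ax[1], ax[2]));
  q.cue_center = Vec3(ce[0], ce[1], ce[2]);
  q.retry_budget = as<int>(p["retry_budget"]);
  q.self_exclusion = as<int>(p["self_exclusion"]);
  std::string nd = as<std::string>(p["nucleation_direction"]);
  q.nucleation_dir = (nd == "tangential") ? 1 : 0;
  return q;
}

// [[Rcpp::export]]
SEXP sim_create_cpp(SEXP mesh_xp, List params, double seed) {
  SimParamsC q = params_from_list(params);
  Simulation* s = new Simulation(mesh_xp, q, (uint64_t)seed);
  XPtr<Simulation> p(s, true);
  return p;
}

// [[Rcpp::export]]
void sim_step_cpp(SEXP xp, int n) {
  XPtr<Simulation> s(xp);
  for (int i = 0; i < n; i++) {
    s->step_once();
    if ((i & 1023) == 1023) Rcpp::checkUserInterrupt();
  }
}

// [[Rcpp::export]]
List sim_snapshot_cpp(SEXP xp) {
  XPtr<Simulation> s(xp);
  long n = s->total_segments;
  IntegerVector mt_id(n), seg_index(n);
  NumericMatrix pos(n, 3), dir(n, 3);
  long k = 0;
  for (const MT& m : s->mts) {
    for (size_t i = 0; i < m.size(); i++) {
      mt_id[k] = m.id;
      seg_index[k] = (int)(m.base_index + (long)i);
      pos(k, 0) = m.pos[i].x; pos(k, 1) = m.pos[i].y; pos(k, 2) = m.pos[i].z;
      dir(k, 0) = m.dir[i].x; dir(k, 1) = m.dir[i].y; dir(k, 2) = m.dir[i].z;
      k++;
    }
  }
  return List::create(_["step"] = (double)s->step_count, _["mt_id"] = mt_id,
                      _["seg_index"] = seg_index, _["pos"] = pos,
                      _["dir"] = dir);
}

// [[Rcpp::export]]
List sim_trace_cpp(SEXP xp) {
  XPtr<Simulation> s(xp);
  return List::create(
      _["step"] = wrap(s->tr_step), _["n_mt"] = wrap(s->tr_nmt),
      _["n_segments"] = wrap(s->tr_nseg), _["added"] = wrap(s->tr_added),
      _["removed"] = wrap(s->tr_removed),
      _["nucleated"] = wrap(s->tr_nucleated),
      _["zipper_events"] = wrap(s->tr_zipper),
      _["catastrophe_mt"] = wrap(s->tr_cat_mt),
      _["catastrophe_membrane"] = wrap(s->tr_cat_mem),
      _["anchoring_fallbacks"] = wrap(s->tr_fallback));
}

// [[Rcpp::export]]
List sim_info_cpp(SEXP xp) {
  XPtr<Simulation> s(xp);
  return List::create(_["step"] = (double)s->step_count,
                      _["n_mt"] = (int)s->mts.size(),
                      _["n_segments"] = (double)s->total_segments,
                      _["nucleation_rate"] = s->lambda);
}

// [[Rcpp::export]]
void sim_add_mt_cpp(SEXP xp, NumericVector origin, NumericMatrix dirs,
                    bool minus_shrinking, bool plus_cat) {
  XPtr<Simulation> s(xp);
  MT m;
  m.id = (int)s->next_id++;
  m.origin = Vec3(origin[0], origin[1], origin[2]);
  m.minus_shrinking = minus_shrinking;
  m.plus_cat = plus_cat;
  s->mts.push_back(std::move(m));
  MT& ref = s->mts.back();
  for (int i = 0; i < dirs.nrow(); i++) {
    Vec3 d = normalize(Vec3(dirs(i, 0), dirs(i, 1), dirs(i, 2)));
    s->append_segment(ref, d);
  }
}
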