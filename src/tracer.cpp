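// Monte Carlo ray tracer for diffuse sky light in a periodic canopy domain.
//
// Geometry: two-sided triangles grouped into organs; a horizontal ground
// plane at z = 0; a launch/escape plane at z = z_top. The domain is periodic
// (toroidal) in x and y so a finite plot behaves like an infinite replicated
// stand. Rays are launched from the top plane at positions uniform over the
// domain with directions drawn from a weighted sky dome; at every surface
// interaction the event (reflect / transmit / absorb) is sampled with the
// organ's optical probabilities, which conserves energy exactly per ray.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec3 operator-(Vec3 a, Vec3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 operator*(Vec3 a, double s) { return {a.x * s, a.y * s, a.z * s}; }
inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(Vec3 a, Vec3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double norm(Vec3 a) { return std::sqrt(dot(a, a)); }
inline Vec3 normalize(Vec3 a) {
  double n = norm(a);
  return {a.x / n, a.y / n, a.z / n};
}

// Moller-Trumbore, two-sided. Returns t > 0 on hit, -1 otherwise.
inline double intersect_tri(const Vec3& orig, const Vec3& dir,
                            const Vec3& v0, const Vec3& v1, const Vec3& v2) {
  const double EPS = 1e-12;
  Vec3 e1 = v1 - v0;
  Vec3 e2 = v2 - v0;
  Vec3 p = cross(dir, e2);
  double det = dot(e1, p);
  if (std::fabs(det) < EPS) return -1.0;
  double inv = 1.0 / det;
  Vec3 tvec = orig - v0;
  double u = dot(tvec, p) * inv;
  if (u < -1e-9 || u > 1.0 + 1e-9) return -1.0;
  Vec3 q = cross(tvec, e1);
  double v = dot(dir, q) * inv;
  if (v < -1e-9 || u + v > 1.0 + 1e-9) return -1.0;
  double t = dot(e2, q) * inv;
  if (t <= 1e-9) return -1.0;
  return t;
}

struct Grid {
  double x0, y0, z0, x1, y1, z1;
  int nx, ny, nz;
  double dx, dy, dz;
  std::vector<std::vector<int>> cells;
  bool empty;

  int idx(int ix, int iy, int iz) const { return (iz * ny + iy) * nx + ix; }
};

void build_grid(Grid& g, const NumericMatrix& tri, double lx, double ly) {
  int n = tri.nrow();
  g.empty = (n == 0);
  if (g.empty) return;
  double zmin = 1e300, zmax = -1e300;
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) {
      double z = tri(i, 3 * k + 2);
      zmin = std::min(zmin, z);
      zmax = std::max(zmax, z);
    }
  }
  g.x0 = 0.0; g.x1 = lx;
  g.y0 = 0.0; g.y1 = ly;
  g.z0 = zmin - 1e-6; g.z1 = zmax + 1e-6;
  double ext_z = std::max(g.z1 - g.z0, 1e-4);
  // aim for ~2 triangles per occupied cell; clamp dims
  double target = std::cbrt(std::max(1.0, (double)n / 2.0));
  double vol = lx * ly * ext_z;
  double cell = std::cbrt(vol) / target;
  g.nx = std::min(128, std::max(1, (int)std::floor(lx / cell)));
  g.ny = std::min(128, std::max(1, (int)std::floor(ly / cell)));
  g.nz = std::min(128, std::max(1, (int)std::floor(ext_z / cell)));
  g.dx = lx / g.nx; g.dy = ly / g.ny; g.dz = ext_z / g.nz;
  g.z1 = g.z0 + ext_z;
  g.cells.assign((size_t)g.nx * g.ny * g.nz, {});
  for (int i = 0; i < n; ++i) {
    double bx0 = 1e300, bx1 = -1e300, by0 = 1e300, by1 = -1e300,
           bz0 = 1e300, bz1 = -1e300;
    for (int k = 0; k < 3; ++k) {
      bx0 = std::min(bx0, tri(i, 3 * k));     bx1 = std::max(bx1, tri(i, 3 * k));
      by0 = std::min(by0, tri(i, 3 * k + 1)); by1 = std::max(by1, tri(i, 3 * k + 1));
      bz0 = std::min(bz0, tri(i, 3 * k + 2)); bz1 = std::max(bz1, tri(i, 3 * k + 2));
    }
    int ix0 = std::max(0, (int)std::floor((bx0 - g.x0) / g.dx));
    int ix1 = std::min(g.nx - 1, (int)std::floor((bx1 - g.x0) / g.dx));
    int iy0 = std::max(0, (int)std::floor((by0 - g.y0) / g.dy));
    int iy1 = std::min(g.ny - 1, (int)std::floor((by1 - g.y0) / g.dy));
    int iz0 = std::max(0, (int)std::floor((bz0 - g.z0) / g.dz));
    int iz1 = std::min(g.nz - 1, (int)std::floor((bz1 - g.z0) / g.dz));
    for (int iz = iz0; iz <= iz1; ++iz)
      for (int iy = iy0; iy <= iy1; ++iy)
        for (int ix = ix0; ix <= ix1; ++ix)
          g.cells[g.idx(ix, iy, iz)].push_back(i);
  }
}

// Nearest triangle hit with t in (0, t_max]; ray stays inside the x/y domain
// for the whole segment (wrapping handled by the caller). Returns index or -1.
int grid_hit(const Grid& g, const NumericMatrix& tri,
             const Vec3& orig, const Vec3& dir, double t_max, double& t_hit) {
  if (g.empty) return -1;
  // clip segment to grid z-slab
  double t0 = 0.0, t1 = t_max;
  if (std::fabs(dir.z) > 1e-15) {
    double ta = (g.z0 - orig.z) / dir.z;
    double tb = (g.z1 - orig.z) / dir.z;
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta);
    t1 = std::min(t1, tb);
  } else if (orig.z < g.z0 || orig.z > g.z1) {
    return -1;
  }
  if (t0 > t1) return -1;
  Vec3 p = orig + dir * t0;
  // entry cell (clamped)
  int ix = std::min(g.nx - 1, std::max(0, (int)std::floor((p.x - g.x0) / g.dx)));
  int iy = std::min(g.ny - 1, std::max(0, (int)std::floor((p.y - g.y0) / g.dy)));
  int iz = std::min(g.nz - 1, std::max(0, (int)std::floor((p.z - g.z0) / g.dz)));
  int sx = dir.x > 0 ? 1 : -1, sy = dir.y > 0 ? 1 : -1, sz = dir.z > 0 ? 1 : -1;
  double inf = 1e300;
  double tdx = std::fabs(dir.x) > 1e-15 ? g.dx / std::fabs(dir.x) : inf;
  double tdy = std::fabs(dir.y) > 1e-15 ? g.dy / std::fabs(dir.y) : inf;
  double tdz = std::fabs(dir.z) > 1e-15 ? g.dz / std::fabs(dir.z) : inf;
  double nx_bound = g.x0 + (ix + (sx > 0 ? 1 : 0)) * g.dx;
  double ny_bound = g.y0 + (iy + (sy > 0 ? 1 : 0)) * g.dy;
  double nz_bound = g.z0 + (iz + (sz > 0 ? 1 : 0)) * g.dz;
  double tmx = std::fabs(dir.x) > 1e-15 ? t0 + (nx_bound - p.x) / dir.x : inf;
  double tmy = std::fabs(dir.y) > 1e-15 ? t0 + (ny_bound - p.y) / dir.y : inf;
  double tmz = std::fabs(dir.z) > 1e-15 ? t0 + (nz_bound - p.z) / dir.z : inf;

  double best_t = inf;
  int best = -1;
  double t_cell_exit;
  while (true) {
    t_cell_exit = std::min({tmx, tmy, tmz, t1});
    const std::vector<int>& lst = g.cells[g.idx(ix, iy, iz)];
    for (int id : lst) {
      Vec3 v0{tri(id, 0), tri(id, 1), tri(id, 2)};
      Vec3 v1{tri(id, 3), tri(id, 4), tri(id, 5)};
      Vec3 v2{tri(id, 6), tri(id, 7), tri(id, 8)};
      double t = intersect_tri(orig, dir, v0, v1, v2);
      if (t > 0 && t <= t_max && t < best_t && t <= t_cell_exit + 1e-9) {
        best_t = t;
        best = id;
      }
    }
    if (best >= 0 && best_t <= t_cell_exit + 1e-9) break;
    if (t_cell_exit >= t1) break;
    if (tmx <= tmy && tmx <= tmz) {
      ix += sx; tmx += tdx;
      if (ix < 0 || ix >= g.nx) break;  // caller wraps before this happens
    } else if (tmy <= tmz) {
      iy += sy; tmy += tdy;
      if (iy < 0 || iy >= g.ny) break;
    } else {
      iz += sz; tmz += tdz;
      if (iz < 0 || iz >= g.nz) break;
    }
  }
  if (best >= 0) {
    t_hit = best_t;
    return best;
  }
  return -1;
}

inline Vec3 cosine_hemisphere(const Vec3& n, double u1, double u2) {
  double r = std::sqrt(u1);
  double phi = 2.0 * M_PI * u2;
  double lx = r * std::cos(phi), ly = r * std::sin(phi);
  double lz = std::sqrt(std::max(0.0, 1.0 - u1));
  // orthonormal basis around n
  Vec3 a = std::fabs(n.x) < 0.9 ? Vec3{1, 0, 0} : Vec3{0, 1, 0};
  Vec3 t = normalize(cross(n, a));
  Vec3 b = cross(n, t);
  return normalize(t * lx + b * ly + n * lz);
}

}  // namespace

// [[Rcpp::export]]
List trace_rays_cpp(NumericMatrix tri, IntegerVector tri_organ,
                    NumericVector organ_refl, NumericVector organ_trans,
                    double lx, double ly, double z_top, double ground_refl,
                    NumericMatrix dome_dir, NumericVector dome_wt,
                    NumericMatrix sensors, double incoming_par, int n_rays,
                    double seed) {
  int n_tri = tri.nrow();
  int n_org = organ_refl.size();
  int n_dir = dome_dir.nrow();
  int n_sens = sensors.nrow();

  Grid grid;
  build_grid(grid, tri, lx, ly);

  std::vector<double> cum(n_dir);
  double acc = 0.0;
  for (int i = 0; i < n_dir; ++i) {
    acc += dome_wt[i];
    cum[i] = acc;
  }

  std::vector<double> absorbed(n_org, 0.0), incident(n_org, 0.0);
  std::vector<double> sens_flux(n_sens, 0.0);
  double ground_abs = 0.0, escaped = 0.0;

  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);

  double w = incoming_par * lx * ly / (double)n_rays;  // umol s^-1 per ray
  const int MAX_EVENTS = 200;

  for (int r = 0; r < n_rays; ++r) {
    Vec3 p{U(rng) * lx, U(rng) * ly, z_top};
    double u = U(rng) * acc;
    int di = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (di >= n_dir) di = n_dir - 1;
    Vec3 d{dome_dir(di, 0), dome_dir(di, 1), dome_dir(di, 2)};

    bool alive = true;
    int events = 0, wraps = 0;
    while (alive) {
      // segment limits: domain walls, ground, top
      double inf = 1e300;
      double t_wall = inf;
      int wall = 0;  // 1 +x, 2 -x, 3 +y, 4 -y
      if (d.x > 1e-15) { double t = (lx - p.x) / d.x; if (t < t_wall) { t_wall = t; wall = 1; } }
      if (d.x < -1e-15) { double t = (0.0 - p.x) / d.x; if (t < t_wall) { t_wall = t; wall = 2; } }
      if (d.y > 1e-15) { double t = (ly - p.y) / d.y; if (t < t_wall) { t_wall = t; wall = 3; } }
      if (d.y < -1e-15) { double t = (0.0 - p.y) / d.y; if (t < t_wall) { t_wall = t; wall = 4; } }
      double t_ground = d.z < -1e-15 ? (0.0 - p.z) / d.z : inf;
      double t_top = d.z > 1e-15 ? (z_top - p.z) / d.z : inf;
      double t_lim = std::min({t_wall, t_ground, t_top});
      if (t_lim <= 0) t_lim = 1e-9;

      double t_hit;
      int hit = grid_hit(grid, tri, p, d, t_lim, t_hit);
      double t_seg = (hit >= 0) ? t_hit : t_lim;

      // sensor tallies along [0, t_seg): downward crossings only
      if (n_sens > 0 && d.z < -1e-15) {
        for (int s = 0; s < n_sens; ++s) {
          double ts = (sensors(s, 4) - p.z) / d.z;
          if (ts > 1e-12 && ts < t_seg) {
            double sxp = p.x + d.x * ts, syp = p.y + d.y * ts;
            if (sxp >= sensors(s, 0) && sxp <= sensors(s, 1) &&
                syp >= sensors(s, 2) && syp <= sensors(s, 3))
              sens_flux[s] += w;
          }
        }
      }

      if (hit >= 0) {
        int org = tri_organ[hit] - 1;
        incident[org] += w;
        double rho = organ_refl[org], tau = organ_trans[org];
        double e = U(rng);
        if (e < rho + tau) {
          // scatter (Lambertian) off the hit side (reflection) or the far
          // side (transmission)
          Vec3 v0{tri(hit, 0), tri(hit, 1), tri(hit, 2)};
          Vec3 v1{tri(hit, 3), tri(hit, 4), tri(hit, 5)};
          Vec3 v2{tri(hit, 6), tri(hit, 7), tri(hit, 8)};
          Vec3 nrm = normalize(cross(v1 - v0, v2 - v0));
          if (dot(nrm, d) > 0) nrm = nrm * -1.0;  // face the incoming ray
          Vec3 axis = (e < rho) ? nrm : nrm * -1.0;
          Vec3 hitp = p + d * t_hit;
          d = cosine_hemisphere(axis, U(rng), U(rng));
          p = hitp + d * 1e-7;
          // keep inside domain after offset
          if (p.x < 0) p.x += lx; else if (p.x >= lx) p.x -= lx;
          if (p.y < 0) p.y += ly; else if (p.y >= ly) p.y -= ly;
          if (p.z >= z_top) { escaped += w; alive = false; }
          if (++events > MAX_EVENTS) { absorbed[org] += w; alive = false; }
        } else {
          absorbed[org] += w;
          alive = false;
        }
      } else if (t_lim == t_ground) {
        Vec3 hitp = p + d * t_ground;
        if (U(rng) < ground_refl) {
          d = cosine_hemisphere(Vec3{0, 0, 1}, U(rng), U(rng));
          p = Vec3{hitp.x, hitp.y, 1e-7};
          if (p.x < 0) p.x += lx; else if (p.x >= lx) p.x -= lx;
          if (p.y < 0) p.y += ly; else if (p.y >= ly) p.y -= ly;
          if (++events > MAX_EVENTS) { ground_abs += w; alive = false; }
        } else {
          ground_abs += w;
          alive = false;
        }
      } else if (t_lim == t_top) {
        escaped += w;
        alive = false;
      } else {
        // wrap at a periodic wall
        if (++wraps > 10000) { escaped += w; alive = false; continue; }
        p = p + d * t_wall;
        if (wall == 1) p.x -= lx;
        else if (wall == 2) p.x += lx;
        else if (wall == 3) p.y -= ly;
        else if (wall == 4) p.y += ly;
        // nudge to avoid re-hitting the wall at t = 0
        p = p + d * 1e-9;
        if (p.x < 0) p.x += lx; else if (p.x >= lx) p.x -= lx;
        if (p.y < 0) p.y += ly; else if (p.y >= ly) p.y -= ly;
      }
    }
  }

  return List::create(
      _["organ_absorbed"] = NumericVector(absorbed.begin(), absorbed.end()),
      _["organ_incident"] = NumericVector(incident.begin(), incident.end()),
      _["ground_absorbed"] = ground_abs, _["escaped"] = escaped,
      _["sensor_flux"] = NumericVector(sens_flux.begin(), sens_flux.end()),
      _["total_emitted"] = w * (double)n_rays, _["n_rays"] = n_rays);
}
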