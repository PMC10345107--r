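// Compiled core: force field, neighbor lists, and BAOAB Langevin
// integrator for the chain + envelope system.
//
// Unit system: sigma = 1 (monomer diameter), eps = 1 (k_B T at the
// reference temperature), m = 1, tau = sigma*sqrt(m/eps).
//
// Particle layout: indices [0, nm) are chain monomers, [nm, N) are
// envelope vertices.  Topology (chain connectivity, envelope edge set)
// is fixed for the lifetime of a run.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
using namespace Rcpp;

namespace {

// ---------------------------------------------------------------- RNG --
// xoshiro256++ with splitmix64 seeding; Marsaglia polar gaussians.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
    init_ziggurat();
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  inline uint32_t u32() { return (uint32_t)(next() >> 32); }

  // Marsaglia-Tsang ziggurat tables for the standard normal
  uint32_t kn[128];
  double wn[128], fn[128];
  void init_ziggurat() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    const double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  double gauss_tail(int32_t hz, uint32_t iz) {
    const double r = 3.442619855899;
    double x, y;
    for (;;) {
      x = hz * wn[iz];
      if (iz == 0) {
        do {
          x = -std::log(unif()) * (1.0 / r);
          y = -std::log(unif());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -r - x;
      }
      if (fn[iz] + unif() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
      hz = (int32_t)u32();
      iz = (uint32_t)(hz & 127);
      if ((uint32_t)std::abs(hz) < kn[iz]) return hz * wn[iz];
    }
  }
  inline double gauss() {
    int32_t hz = (int32_t)u32();
    uint32_t iz = (uint32_t)(hz & 127);
    return ((uint32_t)std::abs(hz) < kn[iz]) ? hz * wn[iz]
                                             : gauss_tail(hz, iz);
  }
};

inline long long pkey(int i, int j) {
  if (i > j) std::swap(i, j);
  return (long long)i * 2000003LL + j;
}

// grid-based candidate pairs within rc between two index sets (or within
// one set when `same` is true); linked-cell lists with reusable buffers
void grid_pairs(const std::vector<double>& x, const std::vector<double>& y,
                const std::vector<double>& z, const std::vector<int>& A,
                const std::vector<int>& B, bool same, double rc,
                std::vector<std::pair<int, int>>& out) {
  out.clear();
  if (A.empty() || B.empty() || rc <= 0) return;
  const double rc2 = rc * rc;
  double xmin = 1e300, ymin = 1e300, zmin = 1e300;
  double xmax = -1e300, ymax = -1e300, zmax = -1e300;
  for (int i : B) {
    xmin = std::min(xmin, x[i]);
    ymin = std::min(ymin, y[i]);
    zmin = std::min(zmin, z[i]);
    xmax = std::max(xmax, x[i]);
    ymax = std::max(ymax, y[i]);
    zmax = std::max(zmax, z[i]);
  }
  const double h = rc;
  const int nx = (int)((xmax - xmin) / h) + 1;
  const int ny = (int)((ymax - ymin) / h) + 1;
  const int nz = (int)((zmax - zmin) / h) + 1;
  static thread_local std::vector<int> head, nxt;
  head.assign((size_t)nx * ny * nz, -1);
  nxt.resize(x.size());
  auto cell_of = [&](int i, int& cx, int& cy, int& cz) {
    cx = std::min(nx - 1, std::max(0, (int)((x[i] - xmin) / h)));
    cy = std::min(ny - 1, std::max(0, (int)((y[i] - ymin) / h)));
    cz = std::min(nz - 1, std::max(0, (int)((z[i] - zmin) / h)));
  };
  for (int i : B) {
    int cx, cy, cz;
    cell_of(i, cx, cy, cz);
    size_t c = ((size_t)cz * ny + cy) * nx + cx;
    nxt[i] = head[c];
    head[c] = i;
  }
  for (int i : A) {
    int cx, cy, cz;
    cell_of(i, cx, cy, cz);
    const double xi = x[i], yi = y[i], zi = z[i];
    for (int dz = -1; dz <= 1; ++dz) {
      int czz = cz + dz;
      if (czz < 0 || czz >= nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int cyy = cy + dy;
        if (cyy < 0 || cyy >= ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int cxx = cx + dx;
          if (cxx < 0 || cxx >= nx) continue;
          for (int j = head[((size_t)czz * ny + cyy) * nx + cxx]; j >= 0;
               j = nxt[j]) {
            if (same && j <= i) continue;
            double ddx = xi - x[j], ddy = yi - y[j], ddz = zi - z[j];
            if (ddx * ddx + ddy * ddy + ddz * ddz < rc2)
              out.push_back({i, j});
          }
        }
      }
    }
  }
}

// ---------------------------------------------------------------- Sim --
struct Sim {
  int N = 0, nm = 0, nv = 0;
  std::vector<double> x, y, z, vx, vy, vz, fx, fy, fz;
  std::vector<int> chain;                       // per-monomer chain id
  std::vector<double> tripk;                    // bending k per center monomer
  std::vector<std::pair<int, int>> edges;       // envelope springs (global idx)
  std::vector<double> erest;                    // per-edge rest lengths
  std::vector<std::pair<int, int>> xbonds;      // extra chain bonds (global idx)
  std::unordered_set<long long> excl_mm, excl_vv;
  double k_chrom = 15, eps_chrom = 5, k_memb = 2500, r0 = 1, Sigma = 2,
         eps = 1;
  std::vector<double> extf;  // 3N constant external forces
  double skin = 0.4, cap_frac = 0.05;
  long n_capped = 0;

  std::vector<std::pair<int, int>> nl_mm, nl_vv, nl_mv;
  std::vector<double> bx, by, bz;  // positions at last neighbor build
  std::vector<int> idx_m, idx_v;
  bool use_cell = true;

  double rc_mm() const { return 1.0; }
  double rc_vv() const { return std::pow(2.0, 1.0 / 6.0) * r0; }
  double rc_mv() const { return std::pow(2.0, 1.0 / 6.0) * Sigma; }

  void build_lists() {
    if (use_cell) {
      std::vector<std::pair<int, int>> cand;
      grid_pairs(x, y, z, idx_m, idx_m, true, rc_mm() + skin, cand);
      nl_mm.clear();
      for (auto& p : cand)
        if (!excl_mm.count(pkey(p.first, p.second))) nl_mm.push_back(p);
      grid_pairs(x, y, z, idx_v, idx_v, true, rc_vv() + skin, cand);
      nl_vv.clear();
      for (auto& p : cand)
        if (!excl_vv.count(pkey(p.first, p.second))) nl_vv.push_back(p);
      grid_pairs(x, y, z, idx_m, idx_v, false, rc_mv() + skin, nl_mv);
    } else {
      nl_mm.clear();
      nl_vv.clear();
      nl_mv.clear();
      for (int i = 0; i < nm; ++i)
        for (int j = i + 1; j < nm; ++j)
          if (!excl_mm.count(pkey(i, j))) nl_mm.push_back({i, j});
      for (int i = nm; i < N; ++i)
        for (int j = i + 1; j < N; ++j)
          if (!excl_vv.count(pkey(i, j))) nl_vv.push_back({i, j});
      for (int i = 0; i < nm; ++i)
        for (int j = nm; j < N; ++j) nl_mv.push_back({i, j});
    }
    bx = x;
    by = y;
    bz = z;
  }

  bool lists_stale() const {
    if (!use_cell) return false;
    const double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < N; ++i) {
      double dx = x[i] - bx[i], dy = y[i] - by[i], dz = z[i] - bz[i];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }

  inline void add_pair_force(int i, int j, double fmag_over_r, double dx,
                             double dy, double dz) {
    fx[i] += fmag_over_r * dx;
    fy[i] += fmag_over_r * dy;
    fz[i] += fmag_over_r * dz;
    fx[j] -= fmag_over_r * dx;
    fy[j] -= fmag_over_r * dy;
    fz[j] -= fmag_over_r * dz;
  }

  // truncated-shifted LJ: radius a, depth e; returns F/r (repulsive > 0)
  inline double lj_f_over_r(double r2, double a, double e) {
    double rc = std::pow(2.0, 1.0 / 6.0) * a;
    if (r2 >= rc * rc) return 0.0;
    double rmin = cap_frac * a;
    double r2e = r2;
    bool capped = false;
    if (r2 < rmin * rmin) {
      r2e = rmin * rmin;
      capped = true;
      ++n_capped;
    }
    double inv2 = a * a / r2e;
    double inv6 = inv2 * inv2 * inv2;
    // F = 24 e (2 s^12 - s^6)/r ; F/r = 24 e (2 s^12 - s^6)/r^2
    double fr = 24.0 * e * (2.0 * inv6 * inv6 - inv6) / r2e;
    if (capped) {
      // keep capped magnitude, rescale to actual direction length
      fr *= std::sqrt(r2e / std::max(r2, 1e-24));
    }
    return fr;
  }

  // soft repulsion (range 1, barrier eps_chrom): F/r
  inline double soft_f_over_r(double r2) {
    if (r2 >= 1.0) return 0.0;
    double s2 = r2;
    double s11_r = std::pow(s2, 5.0);  // s^10
    // U = ec [1 + 6 s^14 - 7 s^12]; dU/dr = ec(84 s^13 - 84 s^11)
    // F = -dU/dr = 84 ec s^11 (1 - s^2); F/r = 84 ec s^10 (1 - s^2)
    return 84.0 * eps_chrom * s11_r * (1.0 - s2);
  }

  double max_spring_stretch() const {
    double m = 0.0;
    for (auto& e : edges) {
      double dx = x[e.first] - x[e.second], dy = y[e.first] - y[e.second],
             dz = z[e.first] - z[e.second];
      m = std::max(m, std::sqrt(dx * dx + dy * dy + dz * dz));
    }
    return m;
  }

  void forces() {
    for (int i = 0; i < N; ++i) {
      fx[i] = extf[3 * i];
      fy[i] = extf[3 * i + 1];
      fz[i] = extf[3 * i + 2];
    }
    // chain bonds (rest length 1)
    for (int i = 0; i + 1 < nm; ++i) {
      if (chain[i] != chain[i + 1]) continue;
      double dx = x[i] - x[i + 1], dy = y[i] - y[i + 1], dz = z[i] - z[i + 1];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) continue;
      double fr = -k_chrom * (r - 1.0) / r;
      add_pair_force(i, i + 1, fr, dx, dy, dz);
    }
    for (auto& b : xbonds) {
      double dx = x[b.first] - x[b.second], dy = y[b.first] - y[b.second],
             dz = z[b.first] - z[b.second];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) continue;
      double fr = -k_chrom * (r - 1.0) / r;
      add_pair_force(b.first, b.second, fr, dx, dy, dz);
    }
    // envelope springs
    for (size_t k = 0; k < edges.size(); ++k) {
      auto& e = edges[k];
      double dx = x[e.first] - x[e.second], dy = y[e.first] - y[e.second],
             dz = z[e.first] - z[e.second];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) continue;
      double fr = -k_memb * (r - erest[k]) / r;
      add_pair_force(e.first, e.second, fr, dx, dy, dz);
    }
    // bending: U = k (1 - cos theta), theta = 0 for straight chain
    for (int i = 1; i + 1 < nm; ++i) {
      double k = tripk[i];
      if (k <= 0.0) continue;
      if (chain[i - 1] != chain[i] || chain[i] != chain[i + 1]) continue;
      double ux = x[i] - x[i - 1], uy = y[i] - y[i - 1], uz = z[i] - z[i - 1];
      double wx = x[i + 1] - x[i], wy = y[i + 1] - y[i], wz = z[i + 1] - z[i];
      double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
      double nw = std::sqrt(wx * wx + wy * wy + wz * wz);
      if (nu < 1e-12 || nw < 1e-12) continue;
      double c = (ux * wx + uy * wy + uz * wz) / (nu * nw);
      if (c > 1.0) c = 1.0;
      if (c < -1.0) c = -1.0;
      // U = k(1 - cos); dU/d(u) etc. via grad of cos
      // d cos/du = w/(|u||w|) - cos * u/|u|^2
      double gux = wx / (nu * nw) - c * ux / (nu * nu);
      double guy = wy / (nu * nw) - c * uy / (nu * nu);
      double guz = wz / (nu * nw) - c * uz / (nu * nu);
      double gwx = ux / (nu * nw) - c * wx / (nw * nw);
      double gwy = uy / (nu * nw) - c * wy / (nw * nw);
      double gwz = uz / (nu * nw) - c * wz / (nw * nw);
      // F_{i-1} = -dU/dr_{i-1} = k * dcos/dr_{i-1} = -k * gu
      fx[i - 1] -= k * gux;
      fy[i - 1] -= k * guy;
      fz[i - 1] -= k * guz;
      // F_{i+1} = k * dcos/dr_{i+1} = k * gw
      fx[i + 1] += k * gwx;
      fy[i + 1] += k * gwy;
      fz[i + 1] += k * gwz;
      // middle particle balances
      fx[i] += k * (gux - gwx);
      fy[i] += k * (guy - gwy);
      fz[i] += k * (guz - gwz);
    }
    // pair terms
    for (auto& p : nl_mm) {
      double dx = x[p.first] - x[p.second], dy = y[p.first] - y[p.second],
             dz = z[p.first] - z[p.second];
      double r2 = dx * dx + dy * dy + dz * dz;
      double fr = soft_f_over_r(r2);
      if (fr != 0.0) add_pair_force(p.first, p.second, fr, dx, dy, dz);
    }
    for (auto& p : nl_vv) {
      double dx = x[p.first] - x[p.second], dy = y[p.first] - y[p.second],
             dz = z[p.first] - z[p.second];
      double r2 = dx * dx + dy * dy + dz * dz;
      double fr = lj_f_over_r(r2, r0, eps);
      if (fr != 0.0) add_pair_force(p.first, p.second, fr, dx, dy, dz);
    }
    for (auto& p : nl_mv) {
      double dx = x[p.first] - x[p.second], dy = y[p.first] - y[p.second],
             dz = z[p.first] - z[p.second];
      double r2 = dx * dx + dy * dy + dz * dz;
      double fr = lj_f_over_r(r2, Sigma, eps);
      if (fr != 0.0) add_pair_force(p.first, p.second, fr, dx, dy, dz);
    }
  }

  double lj_energy(double r2, double a, double e) const {
    double rc = std::pow(2.0, 1.0 / 6.0) * a;
    if (r2 >= rc * rc) return 0.0;
    double rmin = cap_frac * a;
    if (r2 < rmin * rmin) r2 = rmin * rmin;
    double inv2 = a * a / r2;
    double inv6 = inv2 * inv2 * inv2;
    return 4.0 * e * (inv6 * inv6 - inv6 + 0.25);
  }

  double potential_energy() const {
    double u = 0.0;
    for (int i = 0; i + 1 < nm; ++i) {
      if (chain[i] != chain[i + 1]) continue;
      double dx = x[i] - x[i + 1], dy = y[i] - y[i + 1], dz = z[i] - z[i + 1];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      u += 0.5 * k_chrom * (r - 1.0) * (r - 1.0);
    }
    for (auto& b : xbonds) {
      double dx = x[b.first] - x[b.second], dy = y[b.first] - y[b.second],
             dz = z[b.first] - z[b.second];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      u += 0.5 * k_chrom * (r - 1.0) * (r - 1.0);
    }
    for (size_t k = 0; k < edges.size(); ++k) {
      auto& e = edges[k];
      double dx = x[e.first] - x[e.second], dy = y[e.first] - y[e.second],
             dz = z[e.first] - z[e.second];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      u += 0.5 * k_memb * (r - erest[k]) * (r - erest[k]);
    }
    for (int i = 1; i + 1 < nm; ++i) {
      double k = tripk[i];
      if (k <= 0.0) continue;
      if (chain[i - 1] != chain[i] || chain[i] != chain[i + 1]) continue;
      double ux = x[i] - x[i - 1], uy = y[i] - y[i - 1], uz = z[i] - z[i - 1];
      double wx = x[i + 1] - x[i], wy = y[i + 1] - y[i], wz = z[i + 1] - z[i];
      double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
      double nw = std::sqrt(wx * wx + wy * wy + wz * wz);
      if (nu < 1e-12 || nw < 1e-12) continue;
      double c = (ux * wx + uy * wy + uz * wz) / (nu * nw);
      u += k * (1.0 - std::min(1.0, std::max(-1.0, c)));
    }
    for (auto& p : nl_mm) {
      double dx = x[p.first] - x[p.second], dy = y[p.first] - y[p.second],
             dz = z[p.first] - z[p.second];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < 1.0) {
        double s12 = std::pow(r2, 6.0);
        u += eps_chrom * (1.0 + s12 * (6.0 * r2 - 7.0));
      }
    }
    for (auto& p : nl_vv) {
      double dx = x[p.first] - x[p.second], dy = y[p.first] - y[p.second],
             dz = z[p.first] - z[p.second];
      u += lj_energy(dx * dx + dy * dy + dz * dz, r0, eps);
    }
    for (auto& p : nl_mv) {
      double dx = x[p.first] - x[p.second], dy = y[p.first] - y[p.second],
             dz = z[p.first] - z[p.second];
      u += lj_energy(dx * dx + dy * dy + dz * dz, Sigma, eps);
    }
    // external forces: U_ext = -F.x (defined up to a constant)
    for (int i = 0; i < N; ++i)
      u -= extf[3 * i] * x[i] + extf[3 * i + 1] * y[i] + extf[3 * i + 2] * z[i];
    return u;
  }

  double kinetic_energy() const {
    double k = 0.0;
    for (int i = 0; i < N; ++i)
      k += 0.5 * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    return k;
  }
};

Sim make_sim(NumericMatrix pos, NumericMatrix vel, int nm,
             IntegerVector chain_id, NumericVector tripk,
             IntegerMatrix edges, NumericVector edge_rest,
             IntegerMatrix extra_bonds, double k_chrom,
             double eps_chrom, double k_memb, double r0, double Sigma,
             double eps, NumericMatrix ext_force, bool use_cell) {
  Sim S;
  S.N = pos.nrow();
  S.nm = nm;
  S.nv = S.N - nm;
  S.use_cell = use_cell;
  S.x.resize(S.N);
  S.y.resize(S.N);
  S.z.resize(S.N);
  S.vx.assign(S.N, 0.0);
  S.vy.assign(S.N, 0.0);
  S.vz.assign(S.N, 0.0);
  S.fx.assign(S.N, 0.0);
  S.fy.assign(S.N, 0.0);
  S.fz.assign(S.N, 0.0);
  for (int i = 0; i < S.N; ++i) {
    S.x[i] = pos(i, 0);
    S.y[i] = pos(i, 1);
    S.z[i] = pos(i, 2);
  }
  if (vel.nrow() == S.N)
    for (int i = 0; i < S.N; ++i) {
      S.vx[i] = vel(i, 0);
      S.vy[i] = vel(i, 1);
      S.vz[i] = vel(i, 2);
    }
  S.chain.assign(nm, 0);
  for (int i = 0; i < nm && i < chain_id.size(); ++i) S.chain[i] = chain_id[i];
  S.tripk.assign(nm, 0.0);
  for (int i = 0; i < nm && i < tripk.size(); ++i) S.tripk[i] = tripk[i];
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = nm + edges(e, 0) - 1, b = nm + edges(e, 1) - 1;
    S.edges.push_back({a, b});
    S.erest.push_back(e < edge_rest.size() ? edge_rest[e] : r0);
    S.excl_vv.insert(pkey(a, b));
  }
  for (int e = 0; e < extra_bonds.nrow(); ++e) {
    int a = extra_bonds(e, 0) - 1, b = extra_bonds(e, 1) - 1;
    S.xbonds.push_back({a, b});
    S.excl_mm.insert(pkey(a, b));
  }
  for (int i = 0; i + 1 < nm; ++i)
    if (S.chain[i] == S.chain[i + 1]) S.excl_mm.insert(pkey(i, i + 1));
  S.k_chrom = k_chrom;
  S.eps_chrom = eps_chrom;
  S.k_memb = k_memb;
  S.r0 = r0;
  S.Sigma = Sigma;
  S.eps = eps;
  S.extf.assign(3 * S.N, 0.0);
  if (ext_force.nrow() == S.N)
    for (int i = 0; i < S.N; ++i) {
      S.extf[3 * i] = ext_force(i, 0);
      S.extf[3 * i + 1] = ext_force(i, 1);
      S.extf[3 * i + 2] = ext_force(i, 2);
    }
  S.idx_m.resize(nm);
  for (int i = 0; i < nm; ++i) S.idx_m[i] = i;
  S.idx_v.resize(S.nv);
  for (int i = 0; i < S.nv; ++i) S.idx_v[i] = nm + i;
  return S;
}

}  // namespace

// [[Rcpp::export]]
List cpp_system_forces(NumericMatrix pos, int nm, IntegerVector chain_id,
                       NumericVector tripk, IntegerMatrix edges,
                       NumericVector edge_rest,
                       IntegerMatrix extra_bonds, double k_chrom,
                       double eps_chrom, double k_memb, double r0,
                       double Sigma, double eps, NumericMatrix ext_force,
                       bool use_cell) {
  NumericMatrix vel(0, 3);
  Sim S = make_sim(pos, vel, nm, chain_id, tripk, edges, edge_rest,
                   extra_bonds, k_chrom,
                   eps_chrom, k_memb, r0, Sigma, eps, ext_force, use_cell);
  S.build_lists();
  S.forces();
  NumericMatrix F(S.N, 3);
  for (int i = 0; i < S.N; ++i) {
    F(i, 0) = S.fx[i];
    F(i, 1) = S.fy[i];
    F(i, 2) = S.fz[i];
  }
  return List::create(_["forces"] = F, _["n_capped"] = (double)S.n_capped,
                      _["potential"] = S.potential_energy());
}

// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos, NumericMatrix vel, int nm,
                IntegerVector chain_id, NumericVector tripk,
                IntegerMatrix edges, NumericVector edge_rest,
                IntegerMatrix extra_bonds,
                double k_chrom, double eps_chrom, double k_memb, double r0,
                double Sigma, double eps, NumericMatrix ext_force,
                int n_steps, double dt, double gamma, double kT,
                double seed, int frame_stride, int trace_stride,
                double max_step_disp, double max_spring_stretch,
                bool use_cell, double skin, double v_clamp) {
  Sim S = make_sim(pos, vel, nm, chain_id, tripk, edges, edge_rest,
                   extra_bonds, k_chrom,
                   eps_chrom, k_memb, r0, Sigma, eps, ext_force, use_cell);
  S.skin = skin;
  const double vc2 = v_clamp * v_clamp;
  long n_vclamp = 0;
  Xoshiro rng((uint64_t)seed);
  const double c1 = (gamma > 0) ? std::exp(-gamma * dt) : 1.0;
  const double c2 = (gamma > 0 && kT > 0)
                        ? std::sqrt(kT * (1.0 - c1 * c1))
                        : 0.0;
  S.build_lists();
  S.forces();

  std::vector<double> frames;
  std::vector<double> tr_step, tr_pe, tr_ke, tr_stretch;
  int n_frames = 0;
  bool aborted = false;
  std::string abort_reason = "";
  int steps_done = 0;
  std::vector<double> px(S.N), py(S.N), pz(S.N);

  for (int step = 0; step < n_steps; ++step) {
    for (int i = 0; i < S.N; ++i) {
      px[i] = S.x[i];
      py[i] = S.y[i];
      pz[i] = S.z[i];
    }
    const double hdt = 0.5 * dt;
    for (int i = 0; i < S.N; ++i) {
      S.vx[i] += hdt * S.fx[i];
      S.vy[i] += hdt * S.fy[i];
      S.vz[i] += hdt * S.fz[i];
      if (std::isfinite(vc2)) {
        double v2 = S.vx[i] * S.vx[i] + S.vy[i] * S.vy[i] +
                    S.vz[i] * S.vz[i];
        if (v2 > vc2) {
          double sc = std::sqrt(vc2 / v2);
          S.vx[i] *= sc;
          S.vy[i] *= sc;
          S.vz[i] *= sc;
          ++n_vclamp;
        }
      }
      S.x[i] += hdt * S.vx[i];
      S.y[i] += hdt * S.vy[i];
      S.z[i] += hdt * S.vz[i];
    }
    if (gamma > 0) {
      for (int i = 0; i < S.N; ++i) {
        S.vx[i] = c1 * S.vx[i] + c2 * rng.gauss();
        S.vy[i] = c1 * S.vy[i] + c2 * rng.gauss();
        S.vz[i] = c1 * S.vz[i] + c2 * rng.gauss();
      }
    }
    for (int i = 0; i < S.N; ++i) {
      S.x[i] += hdt * S.vx[i];
      S.y[i] += hdt * S.vy[i];
      S.z[i] += hdt * S.vz[i];
    }
    if (S.lists_stale()) S.build_lists();
    S.forces();
    for (int i = 0; i < S.N; ++i) {
      S.vx[i] += hdt * S.fx[i];
      S.vy[i] += hdt * S.fy[i];
      S.vz[i] += hdt * S.fz[i];
      if (std::isfinite(vc2)) {
        double v2 = S.vx[i] * S.vx[i] + S.vy[i] * S.vy[i] +
                    S.vz[i] * S.vz[i];
        if (v2 > vc2) {
          double sc = std::sqrt(vc2 / v2);
          S.vx[i] *= sc;
          S.vy[i] *= sc;
          S.vz[i] *= sc;
          ++n_vclamp;
        }
      }
    }
    ++steps_done;

    double md2 = 0.0;
    for (int i = 0; i < S.N; ++i) {
      double dx = S.x[i] - px[i], dy = S.y[i] - py[i], dz = S.z[i] - pz[i];
      md2 = std::max(md2, dx * dx + dy * dy + dz * dz);
    }
    if (md2 > max_step_disp * max_step_disp || !std::isfinite(md2)) {
      aborted = true;
      abort_reason = "step displacement exceeded limit; reduce dt or force increments";
      break;
    }
    if (trace_stride > 0 && (step + 1) % trace_stride == 0) {
      double ms = S.edges.empty() ? 0.0 : S.max_spring_stretch();
      tr_step.push_back(step + 1);
      tr_pe.push_back(S.potential_energy());
      tr_ke.push_back(S.kinetic_energy());
      tr_stretch.push_back(ms);
      if (std::isfinite(max_spring_stretch) && ms > max_spring_stretch * S.r0) {
        aborted = true;
        abort_reason = "envelope spring overstretch";
        break;
      }
    }
    if (frame_stride > 0 && (step + 1) % frame_stride == 0) {
      for (int i = 0; i < S.N; ++i) {
        frames.push_back(S.x[i]);
        frames.push_back(S.y[i]);
        frames.push_back(S.z[i]);
      }
      ++n_frames;
    }
    if ((step & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix opos(S.N, 3), ovel(S.N, 3);
  for (int i = 0; i < S.N; ++i) {
    opos(i, 0) = S.x[i];
    opos(i, 1) = S.y[i];
    opos(i, 2) = S.z[i];
    ovel(i, 0) = S.vx[i];
    ovel(i, 1) = S.vy[i];
    ovel(i, 2) = S.vz[i];
  }
  NumericVector fr(frames.begin(), frames.end());
  if (n_frames > 0) fr.attr("dim") = Dimension(3, S.N, n_frames);
  return List::create(
      _["pos"] = opos, _["vel"] = ovel, _["frames"] = fr,
      _["n_frames"] = n_frames, _["steps_done"] = steps_done,
      _["aborted"] = aborted, _["abort_reason"] = abort_reason,
      _["n_capped"] = (double)S.n_capped,
      _["n_vclamp"] = (double)n_vclamp,
      _["trace"] = List::create(_["step"] = tr_step, _["pe"] = tr_pe,
                                _["ke"] = tr_ke,
                                _["max_spring"] = tr_stretch));
}

// brute-force all-pairs within cutoff (test oracle)
// [[Rcpp::export]]
IntegerMatrix cpp_pairs_brute(NumericMatrix pos, double cutoff) {
  int n = pos.nrow();
  std::vector<std::pair<int, int>> out;
  double rc2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1),
             dz = pos(i, 2) - pos(j, 2);
      if (dx * dx + dy * dy + dz * dz < rc2) out.push_back({i, j});
    }
  IntegerMatrix m(out.size(), 2);
  for (size_t k = 0; k < out.size(); ++k) {
    m(k, 0) = out[k].first + 1;
    m(k, 1) = out[k].second + 1;
  }
  return m;
}

// [[Rcpp::export]]
IntegerMatrix cpp_pairs_cell(NumericMatrix pos, double cutoff) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0);
    y[i] = pos(i, 1);
    z[i] = pos(i, 2);
    idx[i] = i;
  }
  std::vector<std::pair<int, int>> out;
  grid_pairs(x, y, z, idx, idx, true, cutoff, out);
  IntegerMatrix m(out.size(), 2);
  for (size_t k = 0; k < out.size(); ++k) {
    int a = out[k].first, b = out[k].second;
    if (a > b) std::swap(a, b);
    m(k, 0) = a + 1;
    m(k, 1) = b + 1;
  }
  return m;
}

// dense self-avoiding random walk inside a sphere of radius r_in,
// step length 1 (= sigma), pairwise clearance min_sep
// [[Rcpp::export]]
NumericMatrix cpp_saw_chain(int n, double r_in, double min_sep, double seed,
                            int max_retry) {
  Xoshiro rng((uint64_t)seed);
  std::vector<double> X, Y, Z;
  X.reserve(n);
  const double ms2 = min_sep * min_sep;
  const double h = std::max(min_sep, 1.0);
  std::unordered_map<long long, std::vector<int>> grid;
  auto key = [&](double px, double py, double pz) {
    int cx = (int)std::floor(px / h), cy = (int)std::floor(py / h),
        cz = (int)std::floor(pz / h);
    return ((long long)cx * 73856093LL) ^ ((long long)cy * 19349663LL) ^
           ((long long)cz * 83492791LL);
  };
  auto clash = [&](double px, double py, double pz, int skip_last) {
    int cx = (int)std::floor(px / h), cy = (int)std::floor(py / h),
        cz = (int)std::floor(pz / h);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          long long k = ((long long)(cx + dx) * 73856093LL) ^
                        ((long long)(cy + dy) * 19349663LL) ^
                        ((long long)(cz + dz) * 83492791LL);
          auto it = grid.find(k);
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j >= (int)X.size() - skip_last) continue;
            double ddx = px - X[j], ddy = py - Y[j], ddz = pz - Z[j];
            if (ddx * ddx + ddy * ddy + ddz * ddz < ms2) return true;
          }
        }
    return false;
  };
  // first monomer: uniform in the allowed ball
  for (int attempt = 0;; ++attempt) {
    double px = (2 * rng.unif() - 1) * r_in, py = (2 * rng.unif() - 1) * r_in,
           pz = (2 * rng.unif() - 1) * r_in;
    if (px * px + py * py + pz * pz <= r_in * r_in) {
      X.push_back(px);
      Y.push_back(py);
      Z.push_back(pz);
      grid[key(px, py, pz)].push_back(0);
      break;
    }
    if (attempt > 1000) stop("could not place first monomer");
  }
  int backtracks = 0;
  while ((int)X.size() < n) {
    int i = X.size();
    bool placed = false;
    for (int t = 0; t < max_retry; ++t) {
      // uniform direction
      double gx = rng.gauss(), gy = rng.gauss(), gz = rng.gauss();
      double nrm = std::sqrt(gx * gx + gy * gy + gz * gz);
      if (nrm < 1e-12) continue;
      double px = X[i - 1] + gx / nrm, py = Y[i - 1] + gy / nrm,
             pz = Z[i - 1] + gz / nrm;
      if (px * px + py * py + pz * pz > r_in * r_in) continue;
      if (clash(px, py, pz, 1)) continue;
      X.push_back(px);
      Y.push_back(py);
      Z.push_back(pz);
      grid[key(px, py, pz)].push_back(i);
      placed = true;
      break;
    }
    if (!placed) {
      ++backtracks;
      if (backtracks > 50 * n)
        stop("self-avoiding walk failed; increase the radius or reduce the chain length");
      // drop a few recent monomers and retry
      int drop = std::min<int>(5, X.size() - 1);
      for (int d = 0; d < drop; ++d) {
        int j = X.size() - 1;
        auto& cell = grid[key(X[j], Y[j], Z[j])];
        for (size_t q = 0; q < cell.size(); ++q)
          if (cell[q] == j) {
            cell.erase(cell.begin() + q);
            break;
          }
        X.pop_back();
        Y.pop_back();
        Z.pop_back();
      }
    }
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = X[i];
    out(i, 1) = Y[i];
    out(i, 2) = Z[i];
  }
  return out;
}
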