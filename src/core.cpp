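// Core simulation engine: Langevin dynamics of point beads (chromatin polymer)
// and rigid seven-sphere dimers (HP1-like proteins).
//
// Conventions:
//  - reduced units: sigma = 1 (polymer bead diameter), k_B T = 1, tau = 1;
//    bead mass = 1, dimer mass = 1 (7 spheres of mass 1/7).
//  - site types: 0 bead, 1 CSD, 2 CD, 3 hinge, 4 NTE.
//  - forces are accumulated over canonically ordered (i asc, j asc) pair lists
//    so that a pair list rebuilt at any time yields bitwise-identical forces:
//    pairs beyond cutoff contribute exactly zero.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <string>
#include <sstream>
#include <iomanip>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG -------

// xoshiro256++ with splitmix64 seeding; Box-Muller normals generated in even
// batches so no generator state is cached between steps.
struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix(uint64_t &x) {
    x += 0x9e3779b97f4a7c15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t sd) {
    uint64_t x = sd;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  // Ziggurat standard-normal sampler (Marsaglia & Tsang layout, 128 layers),
  // with Box-Muller style tail handling; tables built once per process.
  static double zig_w[128], zig_f[128];
  static uint32_t zig_k[128];
  static bool zig_ready;
  static void zig_init() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    zig_k[0] = (uint32_t)((dn / q) * m1); zig_k[1] = 0;
    zig_w[0] = q / m1; zig_w[127] = dn / m1;
    zig_f[0] = 1.0; zig_f[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      zig_k[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      zig_f[i] = std::exp(-0.5 * dn * dn);
      zig_w[i] = dn / m1;
    }
    zig_ready = true;
  }
  double normal() {
    if (!zig_ready) zig_init();
    for (;;) {
      int32_t hz = (int32_t)(uint32_t)(next() >> 32);
      uint32_t iz = (uint32_t)hz & 127u;
      uint32_t ahz = (hz < 0) ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (ahz < zig_k[iz]) return hz * zig_w[iz];
      // slower path
      const double r = 3.442619855899;
      if (iz == 0) { // tail
        double x, y;
        do {
          x = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -(r + x);
      }
      double x = hz * zig_w[iz];
      if (zig_f[iz] + unif() * (zig_f[iz - 1] - zig_f[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
  void normals(double *out, int n) {
    for (int i = 0; i < n; ++i) out[i] = normal();
  }
};

double Xoshiro::zig_w[128];
double Xoshiro::zig_f[128];
uint32_t Xoshiro::zig_k[128];
bool Xoshiro::zig_ready = false;

static std::string state_to_hex(const Xoshiro &r) {
  std::ostringstream os;
  os << std::hex << std::setfill('0');
  for (int i = 0; i < 4; ++i) os << std::setw(16) << r.s[i];
  return os.str();
}
static void hex_to_state(const std::string &h, Xoshiro &r) {
  if (h.size() != 64) stop("invalid RNG state string");
  for (int i = 0; i < 4; ++i) {
    uint64_t v = 0;
    for (int k = 0; k < 16; ++k) {
      char c = h[16 * i + k];
      int d = (c >= '0' && c <= '9') ? c - '0'
            : (c >= 'a' && c <= 'f') ? c - 'a' + 10
            : (c >= 'A' && c <= 'F') ? c - 'A' + 10 : -1;
      if (d < 0) stop("invalid RNG state string");
      v = (v << 4) | (uint64_t)d;
    }
    r.s[i] = v;
  }
}

// --------------------------------------------------------- quaternions ------

struct Quat { double w, x, y, z; };

static inline Quat qnormalize(Quat q) {
  double n = std::sqrt(q.w * q.w + q.x * q.x + q.y * q.y + q.z * q.z);
  return {q.w / n, q.x / n, q.y / n, q.z / n};
}
static inline Quat qmul(const Quat &a, const Quat &b) {
  return {a.w * b.w - a.x * b.x - a.y * b.y - a.z * b.z,
          a.w * b.x + a.x * b.w + a.y * b.z - a.z * b.y,
          a.w * b.y - a.x * b.z + a.y * b.w + a.z * b.x,
          a.w * b.z + a.x * b.y - a.y * b.x + a.z * b.w};
}
// rotation matrix (body -> lab), row major
static inline void qmatrix(const Quat &q, double R[9]) {
  double w = q.w, x = q.x, y = q.y, z = q.z;
  R[0] = 1 - 2 * (y * y + z * z); R[1] = 2 * (x * y - w * z); R[2] = 2 * (x * z + w * y);
  R[3] = 2 * (x * y + w * z);     R[4] = 1 - 2 * (x * x + z * z); R[5] = 2 * (y * z - w * x);
  R[6] = 2 * (x * z - w * y);     R[7] = 2 * (y * z + w * x); R[8] = 1 - 2 * (x * x + y * y);
}
static inline Quat qfrom_rotvec(double rx, double ry, double rz) {
  double th = std::sqrt(rx * rx + ry * ry + rz * rz);
  if (th < 1e-300) return {1.0, 0.0, 0.0, 0.0};
  double h = 0.5 * th, s = std::sin(h) / th;
  return {std::cos(h), rx * s, ry * s, rz * s};
}

// ----------------------------------------------------------- potentials -----

struct PairTerm { double u; double f_over_r; }; // force on i is +f_over_r * (ri - rj)

static inline PairTerm wca_term(double r2, double d, double eps) {
  double dc2 = d * d * 1.2599210498948732; // (2^{1/6} d)^2
  if (r2 >= dc2) return {0.0, 0.0};
  double s2 = d * d / r2, s6 = s2 * s2 * s2;
  double u = 4.0 * eps * (s6 * s6 - s6) + eps;
  double f = 24.0 * eps * (2.0 * s6 * s6 - s6) / r2;
  return {u, f};
}

// Morse-like attraction, truncated and shifted so U(rc) = 0.
static inline PairTerm morse_term(double r, double eps, double a, double r0,
                                  double rc, double shift) {
  if (r >= rc || eps == 0.0) return {0.0, 0.0};
  double e = std::exp(-a * (r - r0));
  double u = eps * ((1.0 - e) * (1.0 - e) - 1.0 - shift);
  double dudr = 2.0 * eps * a * e * (1.0 - e);
  return {u, -dudr / r};
}
static inline double morse_shift(double a, double r0, double rc) {
  double e = std::exp(-a * (rc - r0));
  return (1.0 - e) * (1.0 - e) - 1.0;
}

// ------------------------------------------------------------- system -------

struct Geom {
  int ns;                       // spheres per dimer (7 for the reference)
  std::vector<double> bx, by, bz; // principal-frame, COM-centred coordinates
  std::vector<int> role;        // 1 CSD, 2 CD, 3 hinge, 4 NTE
  double I[3];                  // principal moments of inertia
  double sphere_r;              // sphere radius (0.25 sigma)
};

struct FF {
  int variant;                  // 0 multivalent, 1 limited valence
  double eps_wca;
  double eps_hh, eps_hc;
  double a_hh, r0_hh, rc_hh, shift_hh;
  double a_hc, r0_hc, rc_hc, shift_hc;
  double r_on, r_off;
  double kf, R0;                // FENE
  double kbend;
  int walls;                    // 1 walls, 0 periodic
  double lx;
};

// Tabulated unit-epsilon attraction on an r^2 grid (linear interpolation),
// the production fast path; the exact analytic form is used for single-shot
// force evaluations and oracle comparisons.
struct PairTable {
  int nb = 0;
  double inv_dr2 = 0;
  std::vector<double> u, g; // energy and force/r at unit epsilon
  void build(double a, double r0, double rc, double shift, int n = 4096) {
    nb = n;
    double rc2 = rc * rc;
    inv_dr2 = nb / rc2;
    u.assign(nb + 1, 0.0); g.assign(nb + 1, 0.0);
    for (int i = 0; i < nb; ++i) { // last node stays exactly zero at rc^2
      double r = std::sqrt((i + 0.0) / inv_dr2);
      if (r < 1e-6) r = 1e-6;
      PairTerm t = morse_term(r, 1.0, a, r0, rc, shift);
      u[i] = t.u; g[i] = t.f_over_r;
    }
  }
  inline void eval(double r2, double &uu, double &gg) const {
    double x = r2 * inv_dr2;
    int i = (int)x;
    if (i >= nb) { uu = 0; gg = 0; return; }
    double f = x - i;
    uu = u[i] + (u[i + 1] - u[i]) * f;
    gg = g[i] + (g[i + 1] - g[i]) * f;
  }
};

struct Sim {
  int L, N, M;                  // beads, dimers, total sites
  Geom g;
  FF ff;
  double dt, gamma, kT, skin;
  bool use_tables = false;
  PairTable tab_hh, tab_hc;

  // state
  std::vector<double> px, pv;      // 3L bead positions / velocities
  std::vector<double> dx, dv, dl;  // 3N dimer com pos / vel / angular momentum (lab)
  std::vector<Quat> dq;            // N orientations
  double tnow;

  // derived per-site
  std::vector<double> sx;          // 3M site positions
  std::vector<int> stype, sdimer;  // type, owning dimer (-1 for beads)
  std::vector<double> srad;

  // limited-valence bonds: partner site id per site (-1 free)
  std::vector<int> partner;

  // forces
  std::vector<double> fsite;       // 3M
  double u_wca, u_fene, u_bend, u_hh, u_hc, u_wall;

  // neighbour list
  std::vector<int> nbr_start, nbr;
  std::vector<double> ref_pos;     // site positions at last rebuild
  double rlist2max_disp;           // not used; placeholder

  Xoshiro rng;

  int site_of_bead(int i) const { return i; }
  int site_of_dimer(int d, int k) const { return L + d * g.ns + k; }

  void site_meta() {
    M = L + N * g.ns;
    stype.assign(M, 0); sdimer.assign(M, -1); srad.assign(M, 0.5);
    for (int d = 0; d < N; ++d)
      for (int k = 0; k < g.ns; ++k) {
        int s = site_of_dimer(d, k);
        stype[s] = g.role[k];
        sdimer[s] = d;
        srad[s] = g.sphere_r;
      }
    sx.assign(3 * M, 0.0);
    fsite.assign(3 * M, 0.0);
    if ((int)partner.size() != M) partner.assign(M, -1);
  }

  void update_sites() {
    for (int i = 0; i < L; ++i) {
      sx[3 * i] = px[3 * i]; sx[3 * i + 1] = px[3 * i + 1]; sx[3 * i + 2] = px[3 * i + 2];
    }
    for (int d = 0; d < N; ++d) {
      double R[9]; qmatrix(dq[d], R);
      double cx = dx[3 * d], cy = dx[3 * d + 1], cz = dx[3 * d + 2];
      for (int k = 0; k < g.ns; ++k) {
        int s = site_of_dimer(d, k);
        double bxk = g.bx[k], byk = g.by[k], bzk = g.bz[k];
        sx[3 * s]     = cx + R[0] * bxk + R[1] * byk + R[2] * bzk;
        sx[3 * s + 1] = cy + R[3] * bxk + R[4] * byk + R[5] * bzk;
        sx[3 * s + 2] = cz + R[6] * bxk + R[7] * byk + R[8] * bzk;
      }
    }
  }

  inline void mindelta(double &ddx, double &ddy, double &ddz) const {
    if (!ff.walls) {
      ddx -= ff.lx * std::nearbyint(ddx / ff.lx);
      ddy -= ff.lx * std::nearbyint(ddy / ff.lx);
      ddz -= ff.lx * std::nearbyint(ddz / ff.lx);
    }
  }

  double max_cutoff() const {
    double c = 1.122462048309373; // bead-bead WCA
    c = std::max(c, ff.rc_hc);
    c = std::max(c, ff.rc_hh);
    return c;
  }

  // ---- neighbour list (canonical order) ----
  void build_nbr() {
    double rl = max_cutoff() + skin;
    double rl2 = rl * rl;
    double lx = ff.lx;
    int nc = std::max(1, (int)std::floor(lx / rl));
    bool use_cells = nc >= 3;
    nbr_start.assign(M + 1, 0);
    std::vector<std::vector<int>> tmp(M);
    if (use_cells) {
      double cw = lx / nc;
      std::vector<std::vector<int>> cells(nc * nc * nc);
      auto cidx = [&](double v) {
        int c = (int)std::floor(v / cw);
        if (ff.walls) { if (c < 0) c = 0; if (c >= nc) c = nc - 1; }
        else { c %= nc; if (c < 0) c += nc; }
        return c;
      };
      std::vector<int> ci(M), cj(M), ck(M);
      for (int s = 0; s < M; ++s) {
        ci[s] = cidx(sx[3 * s]); cj[s] = cidx(sx[3 * s + 1]); ck[s] = cidx(sx[3 * s + 2]);
        cells[(ci[s] * nc + cj[s]) * nc + ck[s]].push_back(s);
      }
      for (int s = 0; s < M; ++s) {
        for (int a = -1; a <= 1; ++a)
          for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
              int ia = ci[s] + a, jb = cj[s] + b, kc = ck[s] + c;
              if (ff.walls) {
                if (ia < 0 || ia >= nc || jb < 0 || jb >= nc || kc < 0 || kc >= nc) continue;
              } else {
                ia = (ia % nc + nc) % nc; jb = (jb % nc + nc) % nc; kc = (kc % nc + nc) % nc;
              }
              for (int j : cells[(ia * nc + jb) * nc + kc]) {
                if (j <= s) continue;
                if (sdimer[s] >= 0 && sdimer[s] == sdimer[j]) continue;
                double ddx = sx[3 * s] - sx[3 * j], ddy = sx[3 * s + 1] - sx[3 * j + 1],
                       ddz = sx[3 * s + 2] - sx[3 * j + 2];
                mindelta(ddx, ddy, ddz);
                if (ddx * ddx + ddy * ddy + ddz * ddz < rl2) tmp[s].push_back(j);
              }
            }
        std::sort(tmp[s].begin(), tmp[s].end());
        tmp[s].erase(std::unique(tmp[s].begin(), tmp[s].end()), tmp[s].end());
      }
    } else {
      for (int s = 0; s < M; ++s)
        for (int j = s + 1; j < M; ++j) {
          if (sdimer[s] >= 0 && sdimer[s] == sdimer[j]) continue;
          double ddx = sx[3 * s] - sx[3 * j], ddy = sx[3 * s + 1] - sx[3 * j + 1],
                 ddz = sx[3 * s + 2] - sx[3 * j + 2];
          mindelta(ddx, ddy, ddz);
          if (ddx * ddx + ddy * ddy + ddz * ddz < rl2) tmp[s].push_back(j);
        }
    }
    std::size_t tot = 0;
    for (int s = 0; s < M; ++s) tot += tmp[s].size();
    nbr.resize(tot);
    std::size_t pos = 0;
    for (int s = 0; s < M; ++s) {
      nbr_start[s] = (int)pos;
      for (int j : tmp[s]) nbr[pos++] = j;
    }
    nbr_start[M] = (int)pos;
    ref_pos = sx;
  }

  bool need_rebuild() const {
    if (ref_pos.empty()) return true;
    double lim = 0.25 * skin * skin; // (skin/2)^2
    if (skin <= 0.0) return true;
    for (int s = 0; s < M; ++s) {
      double ddx = sx[3 * s] - ref_pos[3 * s], ddy = sx[3 * s + 1] - ref_pos[3 * s + 1],
             ddz = sx[3 * s + 2] - ref_pos[3 * s + 2];
      if (ddx * ddx + ddy * ddy + ddz * ddz > lim) return true;
    }
    return false;
  }

  // ---- limited-valence bond bookkeeping ----
  void update_bonds() {
    // break bonds that stretched beyond r_off
    double roff2 = ff.r_off * ff.r_off;
    for (int s = 0; s < M; ++s) {
      int p = partner[s];
      if (p < 0 || p < s) continue; // handle each bond once (s < p)
      double ddx = sx[3 * s] - sx[3 * p], ddy = sx[3 * s + 1] - sx[3 * p + 1],
             ddz = sx[3 * s + 2] - sx[3 * p + 2];
      mindelta(ddx, ddy, ddz);
      if (ddx * ddx + ddy * ddy + ddz * ddz > roff2) { partner[s] = -1; partner[p] = -1; }
    }
    // collect free hinge/NTE candidates within r_on from the pair list
    double ron2 = ff.r_on * ff.r_on;
    struct Cand { double d2; int a, b; };
    std::vector<Cand> cand;
    for (int s = 0; s < M; ++s) {
      int ts = stype[s];
      if (ts != 3 && ts != 4) continue;
      if (partner[s] >= 0) continue;
      for (int q = nbr_start[s]; q < nbr_start[s + 1]; ++q) {
        int j = nbr[q];
        int tj = stype[j];
        if (!((ts == 3 && tj == 4) || (ts == 4 && tj == 3))) continue;
        if (partner[j] >= 0) continue;
        double ddx = sx[3 * s] - sx[3 * j], ddy = sx[3 * s + 1] - sx[3 * j + 1],
               ddz = sx[3 * s + 2] - sx[3 * j + 2];
        mindelta(ddx, ddy, ddz);
        double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
        if (d2 <= ron2) cand.push_back({d2, s, j});
      }
    }
    std::sort(cand.begin(), cand.end(), [](const Cand &x, const Cand &y) {
      if (x.d2 != y.d2) return x.d2 < y.d2;
      if (x.a != y.a) return x.a < y.a;
      return x.b < y.b;
    });
    for (const Cand &c : cand) {
      if (partner[c.a] >= 0 || partner[c.b] >= 0) continue;
      partner[c.a] = c.b; partner[c.b] = c.a;
    }
  }

  // ---- forces ----
  void pair_kernel(int s, int j, double eps_hh_t, double eps_hc_t) {
    double ddx = sx[3 * s] - sx[3 * j], ddy = sx[3 * s + 1] - sx[3 * j + 1],
           ddz = sx[3 * s + 2] - sx[3 * j + 2];
    mindelta(ddx, ddy, ddz);
    double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
    int ts = stype[s], tj = stype[j];
    double d = srad[s] + srad[j];
    double u = 0.0, f_over_r = 0.0;
    PairTerm w = wca_term(r2, d, ff.eps_wca);
    u += w.u; f_over_r += w.f_over_r;
    bool hc = (ts == 0 && tj == 2) || (ts == 2 && tj == 0);
    bool hh = (ts == 3 && tj == 4) || (ts == 4 && tj == 3);
    if (hc && r2 < ff.rc_hc * ff.rc_hc) {
      if (use_tables) {
        double uu, gg;
        tab_hc.eval(r2, uu, gg);
        u_hc += eps_hc_t * uu; f_over_r += eps_hc_t * gg;
      } else {
        double r = std::sqrt(r2);
        PairTerm m = morse_term(r, eps_hc_t, ff.a_hc, ff.r0_hc, ff.rc_hc, ff.shift_hc);
        u_hc += m.u; f_over_r += m.f_over_r;
      }
    } else if (hh) {
      bool act = (ff.variant == 0) ? (r2 < ff.rc_hh * ff.rc_hh)
                                   : (partner[s] == j && r2 < ff.rc_hh * ff.rc_hh);
      if (act) {
        if (use_tables) {
          double uu, gg;
          tab_hh.eval(r2, uu, gg);
          u_hh += eps_hh_t * uu; f_over_r += eps_hh_t * gg;
        } else {
          double r = std::sqrt(r2);
          PairTerm m = morse_term(r, eps_hh_t, ff.a_hh, ff.r0_hh, ff.rc_hh, ff.shift_hh);
          u_hh += m.u; f_over_r += m.f_over_r;
        }
      }
    }
    u_wca += u;
    if (f_over_r != 0.0) {
      double fx = f_over_r * ddx, fy = f_over_r * ddy, fz = f_over_r * ddz;
      fsite[3 * s] += fx; fsite[3 * s + 1] += fy; fsite[3 * s + 2] += fz;
      fsite[3 * j] -= fx; fsite[3 * j + 1] -= fy; fsite[3 * j + 2] -= fz;
    }
  }

  void compute_forces(double eps_hh_t, double eps_hc_t) {
    std::fill(fsite.begin(), fsite.end(), 0.0);
    u_wca = u_fene = u_bend = u_hh = u_hc = u_wall = 0.0;

    for (int s = 0; s < M; ++s)
      for (int q = nbr_start[s]; q < nbr_start[s + 1]; ++q)
        pair_kernel(s, nbr[q], eps_hh_t, eps_hc_t);

    // FENE bonds between consecutive beads
    double R02 = ff.R0 * ff.R0;
    for (int i = 0; i + 1 < L; ++i) {
      double ddx = px[3 * i] - px[3 * (i + 1)], ddy = px[3 * i + 1] - px[3 * (i + 1) + 1],
             ddz = px[3 * i + 2] - px[3 * (i + 1) + 2];
      mindelta(ddx, ddy, ddz);
      double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (r2 >= R02)
        stop("bond overstretched: FENE bond %d-%d at r=%.4f >= R0=%.4f (time %.4f); "
             "reduce the timestep", i + 1, i + 2, std::sqrt(r2), ff.R0, tnow);
      double fr = 1.0 - r2 / R02;
      u_fene += -0.5 * ff.kf * R02 * std::log(fr);
      double f_over_r = -ff.kf / fr;
      double fx = f_over_r * ddx, fy = f_over_r * ddy, fz = f_over_r * ddz;
      fsite[3 * i] += fx; fsite[3 * i + 1] += fy; fsite[3 * i + 2] += fz;
      fsite[3 * (i + 1)] -= fx; fsite[3 * (i + 1) + 1] -= fy; fsite[3 * (i + 1) + 2] -= fz;
    }

    // Kratky-Porod bending
    if (ff.kbend > 0.0) {
      for (int i = 1; i + 1 < L; ++i) {
        double b1x = px[3 * i] - px[3 * (i - 1)], b1y = px[3 * i + 1] - px[3 * (i - 1) + 1],
               b1z = px[3 * i + 2] - px[3 * (i - 1) + 2];
        double b2x = px[3 * (i + 1)] - px[3 * i], b2y = px[3 * (i + 1) + 1] - px[3 * i + 1],
               b2z = px[3 * (i + 1) + 2] - px[3 * i + 2];
        mindelta(b1x, b1y, b1z); mindelta(b2x, b2y, b2z);
        double n1 = std::sqrt(b1x * b1x + b1y * b1y + b1z * b1z);
        double n2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
        double ux = b1x / n1, uy = b1y / n1, uz = b1z / n1;
        double vx = b2x / n2, vy = b2y / n2, vz = b2z / n2;
        double c = ux * vx + uy * vy + uz * vz;
        u_bend += ff.kbend * (1.0 - c);
        double k1 = ff.kbend / n1, k2 = ff.kbend / n2;
        double fprevx = -k1 * (vx - c * ux), fprevy = -k1 * (vy - c * uy), fprevz = -k1 * (vz - c * uz);
        double fnextx = k2 * (ux - c * vx), fnexty = k2 * (uy - c * vy), fnextz = k2 * (uz - c * vz);
        fsite[3 * (i - 1)] += fprevx; fsite[3 * (i - 1) + 1] += fprevy; fsite[3 * (i - 1) + 2] += fprevz;
        fsite[3 * (i + 1)] += fnextx; fsite[3 * (i + 1) + 1] += fnexty; fsite[3 * (i + 1) + 2] += fnextz;
        fsite[3 * i] -= fprevx + fnextx; fsite[3 * i + 1] -= fprevy + fnexty; fsite[3 * i + 2] -= fprevz + fnextz;
      }
    }

    // walls: WCA-form repulsion from each face acting on site centres
    if (ff.walls) {
      for (int s = 0; s < M; ++s) {
        double rad = srad[s];
        double cutoff = 1.122462048309373 * rad;
        for (int dim = 0; dim < 3; ++dim) {
          double pos = sx[3 * s + dim];
          // lower face
          if (pos < cutoff) {
            double sdist = std::max(pos, 1e-9);
            PairTerm w = wca_term(sdist * sdist, rad, ff.eps_wca);
            u_wall += w.u;
            fsite[3 * s + dim] += w.f_over_r * sdist;
          }
          // upper face
          double up = ff.lx - pos;
          if (up < cutoff) {
            double sdist = std::max(up, 1e-9);
            PairTerm w = wca_term(sdist * sdist, rad, ff.eps_wca);
            u_wall += w.u;
            fsite[3 * s + dim] -= w.f_over_r * sdist;
          }
        }
      }
    }
  }

  // reduce site forces to bead forces (identity) and dimer force/torque
  void reduce(std::vector<double> &fpol, std::vector<double> &fdim,
              std::vector<double> &tdim) const {
    fpol.assign(3 * L, 0.0); fdim.assign(3 * N, 0.0); tdim.assign(3 * N, 0.0);
    for (int i = 0; i < 3 * L; ++i) fpol[i] = fsite[i];
    for (int d = 0; d < N; ++d) {
      double cx = dx[3 * d], cy = dx[3 * d + 1], cz = dx[3 * d + 2];
      for (int k = 0; k < g.ns; ++k) {
        int s = site_of_dimer(d, k);
        double fx = fsite[3 * s], fy = fsite[3 * s + 1], fz = fsite[3 * s + 2];
        fdim[3 * d] += fx; fdim[3 * d + 1] += fy; fdim[3 * d + 2] += fz;
        double ox = sx[3 * s] - cx, oy = sx[3 * s + 1] - cy, oz = sx[3 * s + 2] - cz;
        tdim[3 * d] += oy * fz - oz * fy;
        tdim[3 * d + 1] += oz * fx - ox * fz;
        tdim[3 * d + 2] += ox * fy - oy * fx;
      }
    }
  }

  double utotal() const { return u_wca + u_fene + u_bend + u_hh + u_hc + u_wall; }
};

// ------------------------------------------------------- list <-> struct ----

static Geom geom_from_list(const List &gl) {
  Geom g;
  NumericMatrix pc = gl["pcoords"];
  IntegerVector role = gl["role_code"];
  NumericVector I = gl["inertia"];
  g.ns = pc.nrow();
  g.bx.resize(g.ns); g.by.resize(g.ns); g.bz.resize(g.ns);
  g.role.resize(g.ns);
  for (int k = 0; k < g.ns; ++k) {
    g.bx[k] = pc(k, 0); g.by[k] = pc(k, 1); g.bz[k] = pc(k, 2);
    g.role[k] = role[k];
  }
  for (int i = 0; i < 3; ++i) g.I[i] = I[i];
  g.sphere_r = as<double>(gl["sphere_diameter"]) / 2.0;
  return g;
}

static FF ff_from_list(const List &fl) {
  FF f;
  std::string v = as<std::string>(fl["variant"]);
  f.variant = (v == "limited_valence") ? 1 : 0;
  f.eps_wca = as<double>(fl["eps_wca"]);
  f.eps_hh = as<double>(fl["eps_hh"]);
  f.eps_hc = as<double>(fl["eps_hc"]);
  f.a_hh = as<double>(fl["a_hh"]); f.r0_hh = as<double>(fl["r0_hh"]); f.rc_hh = as<double>(fl["rc_hh"]);
  f.a_hc = as<double>(fl["a_hc"]); f.r0_hc = as<double>(fl["r0_hc"]); f.rc_hc = as<double>(fl["rc_hc"]);
  f.shift_hh = morse_shift(f.a_hh, f.r0_hh, f.rc_hh);
  f.shift_hc = morse_shift(f.a_hc, f.r0_hc, f.rc_hc);
  f.r_on = as<double>(fl["r_on"]); f.r_off = as<double>(fl["r_off"]);
  f.kf = as<double>(fl["fene_k"]); f.R0 = as<double>(fl["fene_r0"]);
  f.kbend = as<double>(fl["k_bend"]);
  return f;
}

static void state_into_sim(Sim &S, const List &state) {
  NumericMatrix px = state["pol_x"], pv = state["pol_v"];
  S.L = px.nrow();
  S.px.resize(3 * S.L); S.pv.resize(3 * S.L);
  for (int i = 0; i < S.L; ++i)
    for (int c = 0; c < 3; ++c) { S.px[3 * i + c] = px(i, c); S.pv[3 * i + c] = pv(i, c); }
  NumericMatrix dxm = state["dim_x"], dvm = state["dim_v"], dlm = state["dim_l"], dqm = state["dim_q"];
  S.N = dxm.nrow();
  S.dx.resize(3 * S.N); S.dv.resize(3 * S.N); S.dl.resize(3 * S.N); S.dq.resize(S.N);
  for (int d = 0; d < S.N; ++d) {
    for (int c = 0; c < 3; ++c) {
      S.dx[3 * d + c] = dxm(d, c); S.dv[3 * d + c] = dvm(d, c); S.dl[3 * d + c] = dlm(d, c);
    }
    Quat q = {dqm(d, 0), dqm(d, 1), dqm(d, 2), dqm(d, 3)};
    double n2 = q.w * q.w + q.x * q.x + q.y * q.y + q.z * q.z;
    // renormalise only when genuinely off-unit, so that restarting from a
    // checkpoint does not perturb the orientation by a last-bit rescale
    S.dq[d] = (std::fabs(n2 - 1.0) > 1e-12) ? qnormalize(q) : q;
  }
  S.tnow = as<double>(state["time"]);
  S.ff.lx = as<double>(state["lx"]);
  std::string bmode = as<std::string>(state["boundary"]);
  S.ff.walls = (bmode == "walls") ? 1 : 0;
  S.site_meta();
  // bond table: columns site_a, site_b (1-based site ids)
  if (state.containsElementNamed("bonds")) {
    IntegerMatrix bm = state["bonds"];
    std::fill(S.partner.begin(), S.partner.end(), -1);
    for (int b = 0; b < bm.nrow(); ++b) {
      int a = bm(b, 0) - 1, c = bm(b, 1) - 1;
      if (a < 0 || a >= S.M || c < 0 || c >= S.M) stop("bond table refers to unknown site");
      S.partner[a] = c; S.partner[c] = a;
    }
  }
  S.update_sites();
}

static List sim_to_state(const Sim &S) {
  NumericMatrix px(S.L, 3), pv(S.L, 3), dxm(S.N, 3), dvm(S.N, 3), dlm(S.N, 3), dqm(S.N, 4);
  for (int i = 0; i < S.L; ++i)
    for (int c = 0; c < 3; ++c) { px(i, c) = S.px[3 * i + c]; pv(i, c) = S.pv[3 * i + c]; }
  for (int d = 0; d < S.N; ++d) {
    for (int c = 0; c < 3; ++c) {
      dxm(d, c) = S.dx[3 * d + c]; dvm(d, c) = S.dv[3 * d + c]; dlm(d, c) = S.dl[3 * d + c];
    }
    dqm(d, 0) = S.dq[d].w; dqm(d, 1) = S.dq[d].x; dqm(d, 2) = S.dq[d].y; dqm(d, 3) = S.dq[d].z;
  }
  // bond table
  int nb = 0;
  for (int s = 0; s < S.M; ++s) if (S.partner[s] > s) ++nb;
  IntegerMatrix bm(nb, 2);
  int r = 0;
  for (int s = 0; s < S.M; ++s)
    if (S.partner[s] > s) { bm(r, 0) = s + 1; bm(r, 1) = S.partner[s] + 1; ++r; }
  return List::create(
    _["time"] = S.tnow, _["lx"] = S.ff.lx,
    _["boundary"] = S.ff.walls ? "walls" : "periodic",
    _["pol_x"] = px, _["pol_v"] = pv,
    _["dim_x"] = dxm, _["dim_q"] = dqm, _["dim_v"] = dvm, _["dim_l"] = dlm,
    _["bonds"] = bm);
}

// ------------------------------------------------------------ cpp_run -------

// [[Rcpp::export]]
List cpp_run(List state, List geom, List ff, double dt, double gamma_, double kT,
             double skin, int n_steps, int sample_every,
             NumericVector eps_ramp, std::string rng_state, int seed) {
  Sim S;
  S.g = geom_from_list(geom);
  S.ff = ff_from_list(ff);
  state_into_sim(S, state);
  S.dt = dt; S.gamma = gamma_; S.kT = kT; S.skin = skin;
  S.use_tables = true;
  S.tab_hh.build(S.ff.a_hh, S.ff.r0_hh, S.ff.rc_hh, S.ff.shift_hh);
  S.tab_hc.build(S.ff.a_hc, S.ff.r0_hc, S.ff.rc_hc, S.ff.shift_hc);
  if (rng_state.size() == 64) hex_to_state(rng_state, S.rng);
  else S.rng.seed((uint64_t)seed * 0x9e3779b97f4a7c15ULL + 0x2545F4914F6CDD1DULL);

  double eh0 = eps_ramp[0], eh1 = eps_ramp[1], ec0 = eps_ramp[2], ec1 = eps_ramp[3];

  int L = S.L, N = S.N;
  std::vector<double> fpol, fdim, tdim;
  std::vector<double> noise(3 * L + 6 * N + 1);
  double sq_kick_bead = std::sqrt(2.0 * S.gamma * kT / dt);
  // rotational noise: per principal axis, variance 2*(gamma/m)*I_k*kT/dt with m = 1
  double sqI[3];
  for (int c = 0; c < 3; ++c) sqI[c] = std::sqrt(2.0 * S.gamma * S.g.I[c] * kT / dt);

  S.build_nbr();
  if (S.ff.variant == 1) S.update_bonds();

  double frac0 = 0.0;
  auto eps_at = [&](double frac, double &eh, double &ec) {
    eh = eh0 + (eh1 - eh0) * frac; ec = ec0 + (ec1 - ec0) * frac;
  };
  double eh, ec;
  eps_at(frac0, eh, ec);
  S.compute_forces(eh, ec);
  S.reduce(fpol, fdim, tdim);

  // sampled output
  std::vector<List> frames;
  std::vector<double> ser_t, ser_u, ser_uhh, ser_uhc, ser_ke_tr, ser_ke_rot, ser_nbond;

  auto record = [&]() {
    double ke_tr = 0.0, ke_rot = 0.0;
    for (int i = 0; i < 3 * L; ++i) ke_tr += 0.5 * S.pv[i] * S.pv[i];
    for (int d = 0; d < N; ++d) {
      for (int c = 0; c < 3; ++c) ke_tr += 0.5 * S.dv[3 * d + c] * S.dv[3 * d + c];
      double R[9]; qmatrix(S.dq[d], R);
      // L_body = R^T L_lab
      double lb[3];
      for (int c = 0; c < 3; ++c)
        lb[c] = R[c] * S.dl[3 * d] + R[c + 3] * S.dl[3 * d + 1] + R[c + 6] * S.dl[3 * d + 2];
      for (int c = 0; c < 3; ++c) ke_rot += 0.5 * lb[c] * lb[c] / S.g.I[c];
    }
    int nbond = 0;
    for (int s = 0; s < S.M; ++s) if (S.partner[s] > s) ++nbond;
    ser_t.push_back(S.tnow); ser_u.push_back(S.utotal());
    ser_uhh.push_back(S.u_hh); ser_uhc.push_back(S.u_hc);
    ser_ke_tr.push_back(ke_tr); ser_ke_rot.push_back(ke_rot);
    ser_nbond.push_back((double)nbond);
    frames.push_back(sim_to_state(S));
  };

  if (sample_every > 0) record();

  for (int step = 1; step <= n_steps; ++step) {
    double frac = (n_steps > 0) ? ((double)step / n_steps) : 0.0;
    // fresh noise for this step, fixed order: beads, then dimers (trans, rot)
    if (S.gamma > 0.0 && kT > 0.0) S.rng.normals(noise.data(), 3 * L + 6 * N);
    else std::fill(noise.begin(), noise.end(), 0.0);

    double hdt = 0.5 * dt, gdt2 = 0.5 * S.gamma * dt;
    // first half-kick (explicit friction on current velocities)
    for (int i = 0; i < 3 * L; ++i) {
      double f = fpol[i] - S.gamma * S.pv[i] + sq_kick_bead * noise[i];
      S.pv[i] += hdt * f;
    }
    for (int d = 0; d < N; ++d) {
      double R[9]; qmatrix(S.dq[d], R);
      for (int c = 0; c < 3; ++c) {
        int i = 3 * d + c;
        double f = fdim[i] - S.gamma * S.dv[i] + sq_kick_bead * noise[3 * L + 6 * d + c];
        S.dv[i] += hdt * f;
      }
      // rotational: lab-frame noise torque from body-frame components
      double nb[3] = {sqI[0] * noise[3 * L + 6 * d + 3], sqI[1] * noise[3 * L + 6 * d + 4],
                      sqI[2] * noise[3 * L + 6 * d + 5]};
      double nl[3] = {R[0] * nb[0] + R[1] * nb[1] + R[2] * nb[2],
                      R[3] * nb[0] + R[4] * nb[1] + R[5] * nb[2],
                      R[6] * nb[0] + R[7] * nb[1] + R[8] * nb[2]};
      for (int c = 0; c < 3; ++c) {
        int i = 3 * d + c;
        double t = tdim[i] - S.gamma * S.dl[i] + nl[c];
        S.dl[i] += hdt * t;
      }
      // drift: positions and orientation with mid-step velocities
      for (int c = 0; c < 3; ++c) S.dx[3 * d + c] += dt * S.dv[3 * d + c];
      // omega_lab = R I^-1 R^T L_lab
      double lb[3];
      for (int c = 0; c < 3; ++c)
        lb[c] = R[c] * S.dl[3 * d] + R[c + 3] * S.dl[3 * d + 1] + R[c + 6] * S.dl[3 * d + 2];
      double wb[3] = {lb[0] / S.g.I[0], lb[1] / S.g.I[1], lb[2] / S.g.I[2]};
      double wl[3] = {R[0] * wb[0] + R[1] * wb[1] + R[2] * wb[2],
                      R[3] * wb[0] + R[4] * wb[1] + R[5] * wb[2],
                      R[6] * wb[0] + R[7] * wb[1] + R[8] * wb[2]};
      Quat dqr = qfrom_rotvec(wl[0] * dt, wl[1] * dt, wl[2] * dt);
      S.dq[d] = qnormalize(qmul(dqr, S.dq[d]));
    }
    for (int i = 0; i < 3 * L; ++i) S.px[i] += dt * S.pv[i];

    if (!S.ff.walls) {
      // wrap centres back into the primary box
      for (int i = 0; i < 3 * L; ++i) S.px[i] -= S.ff.lx * std::floor(S.px[i] / S.ff.lx);
      for (int i = 0; i < 3 * N; ++i) S.dx[i] -= S.ff.lx * std::floor(S.dx[i] / S.ff.lx);
    }

    S.update_sites();
    S.tnow += dt;

    if (S.need_rebuild()) {
      for (int s = 0; s < S.M; ++s)
        if (!std::isfinite(S.sx[3 * s]) || !std::isfinite(S.sx[3 * s + 1]) ||
            !std::isfinite(S.sx[3 * s + 2]))
          stop("numerical blow-up: non-finite coordinate at site %d (time %.4f)", s + 1, S.tnow);
      S.build_nbr();
    }
    if (S.ff.variant == 1) S.update_bonds();

    eps_at(frac, eh, ec);
    S.compute_forces(eh, ec);
    S.reduce(fpol, fdim, tdim);

    // second half-kick (implicit friction)
    double den = 1.0 + gdt2;
    for (int i = 0; i < 3 * L; ++i)
      S.pv[i] = (S.pv[i] + hdt * (fpol[i] + sq_kick_bead * noise[i])) / den;
    for (int d = 0; d < N; ++d) {
      double R[9]; qmatrix(S.dq[d], R);
      double nb[3] = {sqI[0] * noise[3 * L + 6 * d + 3], sqI[1] * noise[3 * L + 6 * d + 4],
                      sqI[2] * noise[3 * L + 6 * d + 5]};
      double nl[3] = {R[0] * nb[0] + R[1] * nb[1] + R[2] * nb[2],
                      R[3] * nb[0] + R[4] * nb[1] + R[5] * nb[2],
                      R[6] * nb[0] + R[7] * nb[1] + R[8] * nb[2]};
      for (int c = 0; c < 3; ++c) {
        int i = 3 * d + c;
        S.dv[i] = (S.dv[i] + hdt * (fdim[i] + sq_kick_bead * noise[3 * L + 6 * d + c])) / den;
        S.dl[i] = (S.dl[i] + hdt * (tdim[i] + nl[c])) / den;
      }
    }

    if (sample_every > 0 && step % sample_every == 0) record();
  }

  List out_frames(frames.size());
  for (std::size_t i = 0; i < frames.size(); ++i) out_frames[i] = frames[i];
  DataFrame series = DataFrame::create(
    _["time"] = ser_t, _["u_total"] = ser_u, _["u_hh"] = ser_uhh, _["u_hc"] = ser_uhc,
    _["ke_trans"] = ser_ke_tr, _["ke_rot"] = ser_ke_rot, _["n_valence_bonds"] = ser_nbond);
  List fin = sim_to_state(S);
  return List::create(_["state"] = fin, _["frames"] = out_frames, _["series"] = series,
                      _["rng_state"] = state_to_hex(S.rng));
}

// -------------------------------------------------------- single forces -----

// [[Rcpp::export]]
List cpp_forces(List state, List geom, List ff, double skin, bool brute) {
  Sim S;
  S.g = geom_from_list(geom);
  S.ff = ff_from_list(ff);
  state_into_sim(S, state);
  S.skin = skin;
  if (brute) {
    // brute force: neighbour list over everything (huge cutoff not needed --
    // emulate by listing all pairs)
    S.nbr_start.assign(S.M + 1, 0);
    std::vector<int> flat;
    for (int s = 0; s < S.M; ++s) {
      S.nbr_start[s] = (int)flat.size();
      for (int j = s + 1; j < S.M; ++j) {
        if (S.sdimer[s] >= 0 && S.sdimer[s] == S.sdimer[j]) continue;
        flat.push_back(j);
      }
    }
    S.nbr_start[S.M] = (int)flat.size();
    S.nbr = flat;
  } else {
    S.build_nbr();
  }
  if (S.ff.variant == 1) S.update_bonds();
  S.compute_forces(S.ff.eps_hh, S.ff.eps_hc);
  std::vector<double> fpol, fdim, tdim;
  S.reduce(fpol, fdim, tdim);
  NumericMatrix fp(S.L, 3), fd(S.N, 3), td(S.N, 3), fs(S.M, 3);
  for (int i = 0; i < S.L; ++i) for (int c = 0; c < 3; ++c) fp(i, c) = fpol[3 * i + c];
  for (int d = 0; d < S.N; ++d)
    for (int c = 0; c < 3; ++c) { fd(d, c) = fdim[3 * d + c]; td(d, c) = tdim[3 * d + c]; }
  for (int s = 0; s < S.M; ++s) for (int c = 0; c < 3; ++c) fs(s, c) = S.fsite[3 * s + c];
  return List::create(
    _["f_pol"] = fp, _["f_dim"] = fd, _["torque_dim"] = td, _["f_site"] = fs,
    _["u_total"] = S.utotal(),
    _["u_terms"] = NumericVector::create(
      _["steric"] = S.u_wca, _["fene"] = S.u_fene, _["bend"] = S.u_bend,
      _["hh"] = S.u_hh, _["hc"] = S.u_hc, _["wall"] = S.u_wall),
    _["bonds"] = as<List>(sim_to_state(S))["bonds"]);
}

// ---------------------------------------------------------- pair search -----

// Grid-accelerated pair search within a cutoff. If B has zero rows, searches
// A against itself (i < j); otherwise cross pairs A x B. 1-based indices.
// [[Rcpp::export]]
List cpp_pairs_within(NumericMatrix A, NumericMatrix B, double cutoff,
                      double lx, bool periodic) {
  bool self = (B.nrow() == 0);
  int na = A.nrow(), nb = self ? na : B.nrow();
  double c2 = cutoff * cutoff;
  std::vector<int> oi, oj;
  std::vector<double> od;
  auto delta = [&](double v) {
    if (periodic) v -= lx * std::nearbyint(v / lx);
    return v;
  };
  // grid over B
  int nc = std::max(1, (int)std::floor((lx > 0 ? lx : 1.0) / std::max(cutoff, 1e-9)));
  if (lx <= 0 || nc < 3) {
    for (int i = 0; i < na; ++i) {
      int j0 = self ? i + 1 : 0;
      for (int j = j0; j < nb; ++j) {
        double ddx = delta(A(i, 0) - (self ? A(j, 0) : B(j, 0)));
        double ddy = delta(A(i, 1) - (self ? A(j, 1) : B(j, 1)));
        double ddz = delta(A(i, 2) - (self ? A(j, 2) : B(j, 2)));
        double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
        if (d2 <= c2) { oi.push_back(i + 1); oj.push_back(j + 1); od.push_back(std::sqrt(d2)); }
      }
    }
  } else {
    double cw = lx / nc;
    auto cofv = [&](double v) {
      int c = (int)std::floor(v / cw);
      if (periodic) { c %= nc; if (c < 0) c += nc; }
      else { if (c < 0) c = 0; if (c >= nc) c = nc - 1; }
      return c;
    };
    std::vector<std::vector<int>> cells(nc * nc * nc);
    for (int j = 0; j < nb; ++j) {
      double x = self ? A(j, 0) : B(j, 0), y = self ? A(j, 1) : B(j, 1),
             z = self ? A(j, 2) : B(j, 2);
      cells[(cofv(x) * nc + cofv(y)) * nc + cofv(z)].push_back(j);
    }
    for (int i = 0; i < na; ++i) {
      int ci = cofv(A(i, 0)), cj = cofv(A(i, 1)), ck = cofv(A(i, 2));
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          for (int c = -1; c <= 1; ++c) {
            int ia = ci + a, jb = cj + b, kc = ck + c;
            if (periodic) {
              ia = (ia % nc + nc) % nc; jb = (jb % nc + nc) % nc; kc = (kc % nc + nc) % nc;
            } else if (ia < 0 || ia >= nc || jb < 0 || jb >= nc || kc < 0 || kc >= nc) continue;
            for (int j : cells[(ia * nc + jb) * nc + kc]) {
              if (self && j <= i) continue;
              double ddx = delta(A(i, 0) - (self ? A(j, 0) : B(j, 0)));
              double ddy = delta(A(i, 1) - (self ? A(j, 1) : B(j, 1)));
              double ddz = delta(A(i, 2) - (self ? A(j, 2) : B(j, 2)));
              double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if (d2 <= c2) { oi.push_back(i + 1); oj.push_back(j + 1); od.push_back(std::sqrt(d2)); }
            }
          }
    }
  }
  return List::create(_["i"] = wrap(oi), _["j"] = wrap(oj), _["dist"] = wrap(od));
}

// ---------------------------------------------------- initial placement -----

// Self-avoiding random-walk polymer + non-overlapping random dimer placement.
// [[Rcpp::export]]
List cpp_build_initial(int L, int N, double lx, List geom, int seed, double kT,
                       double bond_len, double min_sep_frac, int max_try) {
  Geom g = geom_from_list(geom);
  Xoshiro rng;
  rng.seed((uint64_t)seed * 0x9e3779b97f4a7c15ULL + 0xD1B54A32D192ED03ULL);

  double margin_bead = 0.6, margin_sph = 0.3;
  if (lx <= 2 * margin_bead && L > 0) stop("packing infeasible: box too small for beads");

  // occupancy grid for all placed centres (beads + spheres)
  double cell = 1.0;
  int nc = std::max(1, (int)std::floor(lx / cell));
  double cw = lx / nc;
  std::vector<std::vector<int>> grid(nc * nc * nc);
  std::vector<double> gx, gy, gz, gr; // placed centres and radii
  auto cof = [&](double v) {
    int c = (int)std::floor(v / cw);
    if (c < 0) c = 0; if (c >= nc) c = nc - 1;
    return c;
  };
  auto clear_at = [&](double x, double y, double z, double rad) {
    int ci = cof(x), cj = cof(y), ck = cof(z);
    int reach = (int)std::ceil((rad + 0.5) / cw);
    for (int a = -reach; a <= reach; ++a)
      for (int b = -reach; b <= reach; ++b)
        for (int c = -reach; c <= reach; ++c) {
          int ia = ci + a, jb = cj + b, kc = ck + c;
          if (ia < 0 || ia >= nc || jb < 0 || jb >= nc || kc < 0 || kc >= nc) continue;
          for (int idx : grid[(ia * nc + jb) * nc + kc]) {
            double dx0 = x - gx[idx], dy0 = y - gy[idx], dz0 = z - gz[idx];
            double d2 = dx0 * dx0 + dy0 * dy0 + dz0 * dz0;
            double contact = rad + gr[idx];
            if (d2 < min_sep_frac * min_sep_frac * contact * contact) return false;
          }
        }
    return true;
  };
  auto push_centre = [&](double x, double y, double z, double rad) {
    gx.push_back(x); gy.push_back(y); gz.push_back(z); gr.push_back(rad);
    grid[(cof(x) * nc + cof(y)) * nc + cof(z)].push_back((int)gx.size() - 1);
  };

  // --- polymer: self-avoiding random walk, bond length bond_len ---
  NumericMatrix px(std::max(L, 0), 3);
  long tries = 0;
  {
    std::vector<double> wx(L), wy(L), wz(L);
    int i = 0;
    while (i < L) {
      if (tries++ > (long)max_try * std::max(L, 1))
        stop("packing infeasible: could not grow polymer after bounded retries");
      double x, y, z;
      if (i == 0) {
        x = margin_bead + rng.unif() * (lx - 2 * margin_bead);
        y = margin_bead + rng.unif() * (lx - 2 * margin_bead);
        z = margin_bead + rng.unif() * (lx - 2 * margin_bead);
      } else {
        // random direction on the sphere
        double u = 2.0 * rng.unif() - 1.0, phi = 6.283185307179586 * rng.unif();
        double s = std::sqrt(std::max(0.0, 1.0 - u * u));
        x = wx[i - 1] + bond_len * s * std::cos(phi);
        y = wy[i - 1] + bond_len * s * std::sin(phi);
        z = wz[i - 1] + bond_len * u;
        if (x < margin_bead || x > lx - margin_bead || y < margin_bead ||
            y > lx - margin_bead || z < margin_bead || z > lx - margin_bead)
          continue;
      }
      // self-avoidance against non-adjacent beads already in the walk
      bool ok = true;
      for (int j = 0; j < i - 1 && ok; ++j) {
        double dx0 = x - wx[j], dy0 = y - wy[j], dz0 = z - wz[j];
        if (dx0 * dx0 + dy0 * dy0 + dz0 * dz0 <
            min_sep_frac * min_sep_frac * 1.0) ok = false;
      }
      if (!ok) {
        // occasional backtrack to escape dead ends
        if (tries % 500 == 0 && i > 1) --i;
        continue;
      }
      wx[i] = x; wy[i] = y; wz[i] = z; ++i;
    }
    for (int k = 0; k < L; ++k) {
      px(k, 0) = wx[k]; px(k, 1) = wy[k]; px(k, 2) = wz[k];
      push_centre(wx[k], wy[k], wz[k], 0.5);
    }
  }

  // --- dimers: random position + orientation, rejecting overlaps ---
  NumericMatrix dxm(std::max(N, 0), 3), dqm(std::max(N, 0), 4);
  tries = 0;
  double com_margin = margin_sph + 0.75; // keeps every sphere off the walls
  if (N > 0 && lx <= 2 * com_margin)
    stop("packing infeasible: box too small for dimers");
  for (int d = 0; d < N; ++d) {
    bool placed = false;
    while (!placed) {
      if (tries++ > (long)max_try * std::max(N, 1))
        stop("packing infeasible: could not place dimers after bounded retries");
      double x = com_margin + rng.unif() * (lx - 2 * com_margin);
      double y = com_margin + rng.unif() * (lx - 2 * com_margin);
      double z = com_margin + rng.unif() * (lx - 2 * com_margin);
      double q4[4];
      rng.normals(q4, 4);
      Quat q = qnormalize({q4[0], q4[1], q4[2], q4[3]});
      double R[9]; qmatrix(q, R);
      bool ok = true;
      std::vector<double> sxk(g.ns), syk(g.ns), szk(g.ns);
      for (int k = 0; k < g.ns && ok; ++k) {
        double sxx = x + R[0] * g.bx[k] + R[1] * g.by[k] + R[2] * g.bz[k];
        double syy = y + R[3] * g.bx[k] + R[4] * g.by[k] + R[5] * g.bz[k];
        double szz = z + R[6] * g.bx[k] + R[7] * g.by[k] + R[8] * g.bz[k];
        if (sxx < margin_sph || sxx > lx - margin_sph || syy < margin_sph ||
            syy > lx - margin_sph || szz < margin_sph || szz > lx - margin_sph) { ok = false; break; }
        if (!clear_at(sxx, syy, szz, g.sphere_r)) { ok = false; break; }
        sxk[k] = sxx; syk[k] = syy; szk[k] = szz;
      }
      if (!ok) continue;
      dxm(d, 0) = x; dxm(d, 1) = y; dxm(d, 2) = z;
      dqm(d, 0) = q.w; dqm(d, 1) = q.x; dqm(d, 2) = q.y; dqm(d, 3) = q.z;
      for (int k = 0; k < g.ns; ++k) push_centre(sxk[k], syk[k], szk[k], g.sphere_r);
      placed = true;
    }
  }

  // --- Maxwell-Boltzmann velocities (mass 1 for beads and dimers) ---
  NumericMatrix pv(std::max(L, 0), 3), dvm(std::max(N, 0), 3), dlm(std::max(N, 0), 3);
  std::vector<double> z6(6);
  double sv = std::sqrt(kT);
  for (int i = 0; i < L; ++i) {
    rng.normals(z6.data(), 4); // even batch; 4th value discarded
    for (int c = 0; c < 3; ++c) pv(i, c) = sv * z6[c];
  }
  for (int d = 0; d < N; ++d) {
    rng.normals(z6.data(), 6);
    for (int c = 0; c < 3; ++c) dvm(d, c) = sv * z6[c];
    // body-frame angular momentum L_k ~ N(0, I_k kT), rotated to lab
    Quat q = {dqm(d, 0), dqm(d, 1), dqm(d, 2), dqm(d, 3)};
    double R[9]; qmatrix(q, R);
    double lb[3] = {std::sqrt(g.I[0] * kT) * z6[3], std::sqrt(g.I[1] * kT) * z6[4],
                    std::sqrt(g.I[2] * kT) * z6[5]};
    dlm(d, 0) = R[0] * lb[0] + R[1] * lb[1] + R[2] * lb[2];
    dlm(d, 1) = R[3] * lb[0] + R[4] * lb[1] + R[5] * lb[2];
    dlm(d, 2) = R[6] * lb[0] + R[7] * lb[1] + R[8] * lb[2];
  }

  return List::create(
    _["time"] = 0.0, _["lx"] = lx, _["boundary"] = "walls",
    _["pol_x"] = px, _["pol_v"] = pv,
    _["dim_x"] = dxm, _["dim_q"] = dqm, _["dim_v"] = dvm, _["dim_l"] = dlm,
    _["bonds"] = IntegerMatrix(0, 2));
}

// ------------------------------------------------------ sphere positions ----

// [[Rcpp::export]]
NumericMatrix cpp_sphere_positions(NumericMatrix dxm, NumericMatrix dqm,
                                   NumericMatrix pcoords) {
  int N = dxm.nrow(), ns = pcoords.nrow();
  NumericMatrix out(N * ns, 3);
  for (int d = 0; d < N; ++d) {
    Quat q = qnormalize({dqm(d, 0), dqm(d, 1), dqm(d, 2), dqm(d, 3)});
    double R[9]; qmatrix(q, R);
    for (int k = 0; k < ns; ++k) {
      double bx = pcoords(k, 0), by = pcoords(k, 1), bz = pcoords(k, 2);
      out(d * ns + k, 0) = dxm(d, 0) + R[0] * bx + R[1] * by + R[2] * bz;
      out(d * ns + k, 1) = dxm(d, 1) + R[3] * bx + R[4] * by + R[5] * bz;
      out(d * ns + k, 2) = dxm(d, 2) + R[6] * bx + R[7] * by + R[8] * bz;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rng_normals(int n, int seed) {
  Xoshiro r;
  r.seed((uint64_t)seed * 0x9e3779b97f4a7c15ULL + 0x2545F4914F6CDD1DULL);
  NumericVector out(n);
  r.normals(REAL(out), n);
  return out;
}
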