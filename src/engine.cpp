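// Bead-spring force field and Langevin integrator (reduced units,
// epsilon = sigma = m = 1). Non-bonded pairs interact through a WCA core
// shifted by -phi plus a cosine attractive tail up to r = 1.5; bonded
// pairs additionally feel a FENE spring (and are NOT excluded from the
// non-bonded sum, Kremer-Grest convention). Open boundaries.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double RCUT = 1.5;
static const double RCUT2 = RCUT * RCUT;
static const double RMIN2 = std::pow(2.0, 1.0 / 3.0); // (2^{1/6})^2
static const double SKIN = 0.4;
static const double RLIST = RCUT + SKIN;

// xoshiro256++ with ziggurat normals: the thermostat draws 3N Gaussians
// per step, far too many for R's generic RNG. Seeded from R's RNG
// stream so set.seed() still controls every trajectory.
struct FastRng {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t& z) {
    z += 0x9e3779b97f4a7c15ULL;
    uint64_t x = z;
    x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
    x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
    return x ^ (x >> 31);
  }
  explicit FastRng(uint64_t seed0) {
    uint64_t z = seed0;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(z);
    setup_ziggurat();
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  // Marsaglia-Tsang ziggurat: the thermostat consumes 3N normals per
  // step, so the sampler must be a few ns per draw
  uint32_t kn[128];
  double wn[128], fn[128];
  void setup_ziggurat() {
    double dn = 3.442619855899, tl = dn;
    const double m1 = 2147483648.0, vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tl) * m1);
      tl = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  double normal() {
    for (;;) {
      int32_t hz = (int32_t)(uint32_t)next();
      uint32_t iz = hz & 127;
      if ((uint32_t)std::abs(hz) < kn[iz]) return hz * wn[iz];
      // slow path: tail or wedge
      const double r = 3.442619855899;
      if (iz == 0) {
        double xx, yy;
        do {
          xx = -std::log(unif()) / r;
          yy = -std::log(unif());
        } while (yy + yy < xx * xx);
        return hz > 0 ? r + xx : -(r + xx);
      }
      double x = hz * wn[iz];
      if (fn[iz] + unif() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x)) {
        return x;
      }
    }
  }
};

struct Params {
  double phi, alpha, beta, kf, r0, ks;
  bool wall;
  double wallR, wcx, wcy, wcz;
  // attractive tail V and force/r tabulated on an r^2 grid: the trig
  // calls would otherwise dominate the pair loop (interp error ~1e-8)
  std::vector<double> tabV, tabF;
  double tab_inv_dr;
  void build_tail_table() {
    const int ntab = 4096;
    tabV.resize(ntab + 2); tabF.resize(ntab + 2);
    double dr = (RCUT2 - RMIN2) / ntab;
    tab_inv_dr = 1.0 / dr;
    for (int k = 0; k <= ntab + 1; ++k) {
      double r2 = RMIN2 + k * dr;
      double arg = alpha * r2 + beta;
      tabV[k] = 0.5 * phi * (std::cos(arg) - 1.0);
      tabF[k] = phi * alpha * std::sin(arg);
    }
  }
};

struct NeighborList {
  std::vector<int> pi, pj;      // candidate pairs within RLIST
  std::vector<double> ref;      // positions at build time
  // persistent binning buffers: zeroing a large grid at every rebuild
  // would dominate the cost for swollen (dilute) systems
  std::vector<int> head, nxt, cellof;
  std::vector<long> used;
};

static void build_neighbor_list(const std::vector<double>& x, int n,
                                NeighborList& nl) {
  nl.pi.clear(); nl.pj.clear();
  nl.ref = x;
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      double v = x[3 * i + d];
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  // cell edge >= RLIST so +/-1 cells cover the list cutoff; the per-axis
  // cell count is capped so dilute expanding systems don't inflate the grid
  int nc[3];
  double edge[3];
  for (int d = 0; d < 3; ++d) {
    nc[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / RLIST));
    nc[d] = std::min(nc[d], 64);
    edge[d] = std::max(RLIST, (hi[d] - lo[d]) / nc[d]);
  }
  long ncell = (long)nc[0] * nc[1] * nc[2];
  if ((long)nl.head.size() < ncell) nl.head.assign(ncell, -1);
  nl.nxt.assign(n, -1);
  nl.cellof.resize(n);
  nl.used.clear();
  std::vector<int>& head = nl.head;
  std::vector<int>& nxt = nl.nxt;
  std::vector<int>& cellof = nl.cellof;
  for (int i = 0; i < n; ++i) {
    int c[3];
    for (int d = 0; d < 3; ++d) {
      c[d] = (int)((x[3 * i + d] - lo[d]) / edge[d]);
      if (c[d] >= nc[d]) c[d] = nc[d] - 1;
      if (c[d] < 0) c[d] = 0;
    }
    long cc = (long)c[0] + nc[0] * ((long)c[1] + (long)nc[1] * c[2]);
    cellof[i] = cc;
    if (head[cc] == -1) nl.used.push_back(cc);
    nxt[i] = head[cc];
    head[cc] = i;
  }
  const double rl2 = RLIST * RLIST;
  for (int i = 0; i < n; ++i) {
    long c = cellof[i];
    int cx = c % nc[0], cy = (c / nc[0]) % nc[1], cz = c / ((long)nc[0] * nc[1]);
    for (int dz = -1; dz <= 1; ++dz) {
      int z = cz + dz; if (z < 0 || z >= nc[2]) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int y = cy + dy; if (y < 0 || y >= nc[1]) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int xx = cx + dx; if (xx < 0 || xx >= nc[0]) continue;
          long cc = (long)xx + nc[0] * ((long)y + (long)nc[1] * z);
          for (int j = head[cc]; j != -1; j = nxt[j]) {
            if (j <= i) continue;
            double ddx = x[3 * i] - x[3 * j];
            double ddy = x[3 * i + 1] - x[3 * j + 1];
            double ddz = x[3 * i + 2] - x[3 * j + 2];
            double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (r2 < rl2) { nl.pi.push_back(i); nl.pj.push_back(j); }
          }
        }
      }
    }
  }
  for (long cc : nl.used) head[cc] = -1;   // leave the grid clean
}

static bool list_stale(const std::vector<double>& x, int n,
                       const NeighborList& nl) {
  if ((int)nl.ref.size() != 3 * n) return true;
  const double lim2 = (SKIN / 2) * (SKIN / 2);
  for (int i = 0; i < 3 * n; i += 3) {
    double dx = x[i] - nl.ref[i];
    double dy = x[i + 1] - nl.ref[i + 1];
    double dz = x[i + 2] - nl.ref[i + 2];
    if (dx * dx + dy * dy + dz * dz > lim2) return true;
  }
  return false;
}

// forces into f (overwritten); returns potential energy; throws on broken
// bond (step is only used for the diagnostic message)
static double compute_forces(const std::vector<double>& x, int n,
                             const IntegerMatrix& bonds,
                             const IntegerMatrix& angles,
                             const NumericMatrix& restraints,
                             const Params& p, NeighborList& nl,
                             std::vector<double>& f, long step) {
  std::fill(f.begin(), f.end(), 0.0);
  double pe = 0.0;
  if (list_stale(x, n, nl)) build_neighbor_list(x, n, nl);

  // non-bonded: all candidate pairs. The list is grouped by i, so the
  // i-side force accumulates in registers and is written once per group.
  size_t npair = nl.pi.size();
  {
    int cur = -1;
    double fix = 0, fiy = 0, fiz = 0, xi = 0, yi = 0, zi = 0;
    for (size_t k = 0; k < npair; ++k) {
      int i = nl.pi[k], j = nl.pj[k];
      if (i != cur) {
        if (cur >= 0) {
          f[3 * cur] += fix; f[3 * cur + 1] += fiy; f[3 * cur + 2] += fiz;
        }
        cur = i; fix = fiy = fiz = 0;
        xi = x[3 * i]; yi = x[3 * i + 1]; zi = x[3 * i + 2];
      }
      double dx = xi - x[3 * j];
      double dy = yi - x[3 * j + 1];
      double dz = zi - x[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= RCUT2) continue;
      double fr; // force / r along (ri - rj)
      if (r2 <= RMIN2) {
        double ir2 = 1.0 / r2;
        double ir6 = ir2 * ir2 * ir2;
        pe += 4.0 * (ir6 * ir6 - ir6 + 0.25) - p.phi;
        fr = 24.0 * (2.0 * ir6 * ir6 - ir6) * ir2;
      } else {
        // dV/dr = -phi*alpha*r*sin(arg); f = -dV/dr / r (tabulated)
        double t = (r2 - RMIN2) * p.tab_inv_dr;
        int kt = (int)t;
        double w = t - kt;
        pe += p.tabV[kt] + w * (p.tabV[kt + 1] - p.tabV[kt]);
        fr = p.tabF[kt] + w * (p.tabF[kt + 1] - p.tabF[kt]);
      }
      fix += fr * dx;     f[3 * j] -= fr * dx;
      fiy += fr * dy;     f[3 * j + 1] -= fr * dy;
      fiz += fr * dz;     f[3 * j + 2] -= fr * dz;
    }
    if (cur >= 0) {
      f[3 * cur] += fix; f[3 * cur + 1] += fiy; f[3 * cur + 2] += fiz;
    }
  }

  // FENE bonds
  const double r02 = p.r0 * p.r0;
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= r02) {
      stop("broken bond %d-%d (r = %.3f >= R0 = %.2f) at step %ld",
           i + 1, j + 1, std::sqrt(r2), p.r0, step);
    }
    double den = 1.0 - r2 / r02;
    pe += -0.5 * p.kf * r02 * std::log(den);
    double fr = -p.kf / den; // f/r along (ri - rj): attractive
    f[3 * i] += fr * dx;     f[3 * j] -= fr * dx;
    f[3 * i + 1] += fr * dy; f[3 * j + 1] -= fr * dy;
    f[3 * i + 2] += fr * dz; f[3 * j + 2] -= fr * dz;
  }

  // bending: V = Ks (1 - cos theta) over consecutive-bond triples
  if (p.ks > 0.0) {
    for (int a = 0; a < angles.nrow(); ++a) {
      int i = angles(a, 0) - 1, j = angles(a, 1) - 1, k = angles(a, 2) - 1;
      double b1x = x[3 * j] - x[3 * i], b1y = x[3 * j + 1] - x[3 * i + 1],
             b1z = x[3 * j + 2] - x[3 * i + 2];
      double b2x = x[3 * k] - x[3 * j], b2y = x[3 * k + 1] - x[3 * j + 1],
             b2z = x[3 * k + 2] - x[3 * j + 2];
      double n1 = std::sqrt(b1x * b1x + b1y * b1y + b1z * b1z);
      double n2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
      double e1x = b1x / n1, e1y = b1y / n1, e1z = b1z / n1;
      double e2x = b2x / n2, e2y = b2y / n2, e2z = b2z / n2;
      double c = e1x * e2x + e1y * e2y + e1z * e2z;
      if (c > 1.0) c = 1.0; else if (c < -1.0) c = -1.0;
      pe += p.ks * (1.0 - c);
      // dc/db1 = (e2 - c e1)/n1 ; dc/db2 = (e1 - c e2)/n2
      double g1x = (e2x - c * e1x) / n1, g1y = (e2y - c * e1y) / n1,
             g1z = (e2z - c * e1z) / n1;
      double g2x = (e1x - c * e2x) / n2, g2y = (e1y - c * e2y) / n2,
             g2z = (e1z - c * e2z) / n2;
      // F = Ks * dc/dr
      f[3 * i] -= p.ks * g1x; f[3 * i + 1] -= p.ks * g1y; f[3 * i + 2] -= p.ks * g1z;
      f[3 * k] += p.ks * g2x; f[3 * k + 1] += p.ks * g2y; f[3 * k + 2] += p.ks * g2z;
      f[3 * j] += p.ks * (g1x - g2x);
      f[3 * j + 1] += p.ks * (g1y - g2y);
      f[3 * j + 2] += p.ks * (g1z - g2z);
    }
  }

  // confining spherical wall (synthesis cavity)
  if (p.wall) {
    for (int i = 0; i < n; ++i) {
      double dx = x[3 * i] - p.wcx, dy = x[3 * i + 1] - p.wcy,
             dz = x[3 * i + 2] - p.wcz;
      double rr = std::sqrt(dx * dx + dy * dy + dz * dz);
      double rw = p.wallR - rr;
      if (rw <= 0)
        stop("bead %d outside cavity (|r-c| = %.3f >= Rcav = %.2f) at step %ld",
             i + 1, rr, p.wallR, step);
      if (rw * rw <= RMIN2) {
        double irw = 1.0 / rw;
        double irw6 = std::pow(irw, 6);
        pe += 4.0 * (irw6 * irw6 - irw6 + 0.25);
        double dvdrw = -24.0 * (2.0 * irw6 * irw6 - irw6) * irw;
        // drw/dr_i = -(r-c)/|r-c|  =>  F_i = dV/drw * u  (pushes inward)
        double s = (rr > 0) ? dvdrw / rr : 0.0;
        f[3 * i] += s * dx; f[3 * i + 1] += s * dy; f[3 * i + 2] += s * dz;
      }
    }
  }

  // temporary harmonic restraints (pair, k, rest length)
  for (int rIdx = 0; rIdx < restraints.nrow(); ++rIdx) {
    int i = (int)restraints(rIdx, 0) - 1, j = (int)restraints(rIdx, 1) - 1;
    double kk = restraints(rIdx, 2), rr0 = restraints(rIdx, 3);
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) continue;
    pe += 0.5 * kk * (r - rr0) * (r - rr0);
    double fr = -kk * (r - rr0) / r;
    f[3 * i] += fr * dx;     f[3 * j] -= fr * dx;
    f[3 * i + 1] += fr * dy; f[3 * j + 1] -= fr * dy;
    f[3 * i + 2] += fr * dz; f[3 * j + 2] -= fr * dz;
  }
  return pe;
}

static Params make_params(double phi, double kf, double r0, double ks,
                          bool wall, NumericVector wall_center,
                          double wall_radius) {
  Params p;
  p.phi = phi;
  p.alpha = M_PI / (2.25 - std::pow(2.0, 1.0 / 3.0));
  p.beta = 2.0 * M_PI - 2.25 * p.alpha;
  p.kf = kf; p.r0 = r0; p.ks = ks;
  p.wall = wall;
  if (wall) { p.wcx = wall_center[0]; p.wcy = wall_center[1]; p.wcz = wall_center[2]; }
  p.wallR = wall_radius;
  p.build_tail_table();
  return p;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, IntegerMatrix bonds, IntegerMatrix angles,
                NumericMatrix restraints, double phi, double kf, double r0,
                double ks, bool wall, NumericVector wall_center,
                double wall_radius) {
  int n = pos.nrow();
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);
  Params p = make_params(phi, kf, r0, ks, wall, wall_center, wall_radius);
  NeighborList nl;
  double pe = compute_forces(x, n, bonds, angles, restraints, p, nl, f, 0);
  NumericMatrix fout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) fout(i, d) = f[3 * i + d];
  return List::create(_["forces"] = fout, _["potential"] = pe);
}

// Gronbech-Jensen / Farago discretization of the Langevin equation;
// reduces to symplectic velocity Verlet for gamma = 0. Uses R's RNG.
// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix pos, NumericMatrix vel,
                      IntegerMatrix bonds, IntegerMatrix angles,
                      NumericMatrix restraints,
                      double phi, double kf, double r0, double ks,
                      bool wall, NumericVector wall_center, double wall_radius,
                      double kT, double gamma, double dt,
                      IntegerVector snap_steps, double t_offset) {
  int n = pos.nrow();
  std::vector<double> x(3 * n), v(3 * n), f(3 * n), noise(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) { x[3 * i + d] = pos(i, d); v[3 * i + d] = vel(i, d); }
  Params p = make_params(phi, kf, r0, ks, wall, wall_center, wall_radius);
  NeighborList nl;

  long n_steps = snap_steps.size() ? snap_steps[snap_steps.size() - 1] : 0;
  int nsnap = snap_steps.size();
  List snap_pos(nsnap), snap_vel(nsnap);
  NumericVector snap_t(nsnap), snap_pe(nsnap), snap_ke(nsnap);

  const double b = 1.0 / (1.0 + gamma * dt / 2.0);
  const double a = (1.0 - gamma * dt / 2.0) / (1.0 + gamma * dt / 2.0);
  const double sig = std::sqrt(2.0 * gamma * kT * dt);
  // seed the bulk-noise generator from R's RNG stream (reproducible)
  uint64_t seed0 = ((uint64_t)(unif_rand() * 4294967296.0) << 32) ^
                   (uint64_t)(unif_rand() * 4294967296.0);
  FastRng rng(seed0 ? seed0 : 0x8badf00dULL);

  double pe = compute_forces(x, n, bonds, angles, restraints, p, nl, f, 0);
  int isnap = 0;
  auto record = [&](long step) {
    NumericMatrix sp(n, 3), sv(n, 3);
    double ke = 0;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        sp(i, d) = x[3 * i + d];
        sv(i, d) = v[3 * i + d];
        ke += 0.5 * v[3 * i + d] * v[3 * i + d];
      }
    snap_pos[isnap] = sp; snap_vel[isnap] = sv;
    snap_t[isnap] = t_offset + step * dt;
    snap_pe[isnap] = pe; snap_ke[isnap] = ke;
    ++isnap;
  };
  while (isnap < nsnap && snap_steps[isnap] == 0) record(0);

  std::vector<double> fold(3 * n);
  for (long step = 1; step <= n_steps; ++step) {
    if (gamma > 0) {
      for (int i = 0; i < 3 * n; ++i) noise[i] = sig * rng.normal();
    } else {
      std::fill(noise.begin(), noise.end(), 0.0);
    }
    for (int i = 0; i < 3 * n; ++i) {
      x[i] += b * dt * v[i] + 0.5 * b * dt * dt * f[i] + 0.5 * b * dt * noise[i];
    }
    fold.swap(f);
    pe = compute_forces(x, n, bonds, angles, restraints, p, nl, f, step);
    for (int i = 0; i < 3 * n; ++i) {
      v[i] = a * v[i] + 0.5 * dt * (a * fold[i] + f[i]) + b * noise[i];
      if (!std::isfinite(x[i]))
        stop("non-finite coordinate at step %ld", step);
    }
    while (isnap < nsnap && snap_steps[isnap] == step) record(step);
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["positions"] = snap_pos, _["velocities"] = snap_vel,
                      _["times"] = snap_t, _["pe"] = snap_pe,
                      _["ke"] = snap_ke);
}
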