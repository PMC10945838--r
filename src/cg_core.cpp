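// Coarse-grained bead-rod engine: cut-and-shifted LJ + screened-electrostatic
// (Debye-Hueckel) nonbonded terms, harmonic bonds and angles, BAOAB Langevin
// integration, cell/Verlet neighbor lists, union-find cluster detection.
// All quantities in reduced units (sigma, tau0, kT, m = 1).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <random>
#include <functional>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// xoshiro256++ PRNG with splitmix64 seeding; Box-Muller normal pairs
struct FastRng {
  uint64_t s[4];
  double cache = 0.0;
  bool has = false;
  explicit FastRng(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 1.0) * 0x1.0p-53;
  }
  inline double normal() {
    if (has) { has = false; return cache; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    cache = r * std::sin(a);
    has = true;
    return r * std::cos(a);
  }
};

struct Params {
  double box = 0.0;
  int n_mol = 0, n_beads = 0;
  std::vector<int> q;        // per-bead charge signs (template, length n_beads)
  double epsH = 0.0, epsE = 0.0;
  double kappa = 1.0;        // inverse screening length, 1/sigma
  double rcut = 2.0, rcut2 = 4.0;
  int excl = 4;              // max |bead index difference| excluded intra-molecule
  double lj_shift = 0.0;     // E_shift^LJ
  double dlvo_shift = 0.0;   // E_shift^DLVO per unit qi*qj
  double r0 = 0.255, kbond = 500.0, theta0 = M_PI, kangle = 50.0;
  std::vector<int> qv;       // per-bead charge for every bead in the system
  std::vector<int> molid;    // molecule index per bead
  std::vector<int> beadid;   // intra-molecule bead index per bead
};

inline double min_image(double dx, double box) {
  return dx - box * std::round(dx / box);
}

// Pair energy and force/r for one nonbonded pair at squared distance r2.
// Returns energy; fOverR receives |F|/r with positive = repulsive.
inline double pair_ef(double r2, int qq, const Params& P, double& fOverR) {
  fOverR = 0.0;
  if (r2 >= P.rcut2) return 0.0;
  double e = 0.0;
  const double inv2 = 1.0 / r2;
  const double inv6 = inv2 * inv2 * inv2;
  if (P.epsH != 0.0) {
    e += 4.0 * P.epsH * (inv6 * inv6 - inv6) + P.lj_shift;
    fOverR += 24.0 * P.epsH * inv2 * inv6 * (2.0 * inv6 - 1.0);
  }
  if (qq != 0 && P.epsE != 0.0) {
    const double r = std::sqrt(r2);
    const double ex = std::exp(-P.kappa * r);
    e += P.epsE * qq * ex / r + qq * P.dlvo_shift;
    fOverR += P.epsE * qq * ex * (P.kappa + 1.0 / r) / r2;
  }
  return e;
}

Params make_params(double box, int n_mol, int n_beads, const IntegerVector& q,
                   double epsH, double epsE, double screening_length,
                   double rcut, int excl_depth,
                   double r0, double kbond, double theta0, double kangle) {
  Params P;
  P.box = box; P.n_mol = n_mol; P.n_beads = n_beads;
  P.q.assign(q.begin(), q.end());
  P.epsH = epsH; P.epsE = epsE;
  P.kappa = 1.0 / screening_length;
  P.rcut = rcut; P.rcut2 = rcut * rcut;
  P.excl = excl_depth - 1;  // depth 5 => exclude |i-j| <= 4 (1-2 ... 1-5)
  // shift constants derived from rcut at startup so E(rcut) = 0 exactly
  double ir6 = 1.0 / std::pow(rcut, 6);
  P.lj_shift = -4.0 * epsH * (ir6 * ir6 - ir6);
  P.dlvo_shift = -epsE * std::exp(-P.kappa * rcut) / rcut;
  P.r0 = r0; P.kbond = kbond; P.theta0 = theta0; P.kangle = kangle;
  const int nb = n_mol * n_beads;
  P.qv.resize(nb); P.molid.resize(nb); P.beadid.resize(nb);
  for (int i = 0; i < nb; ++i) {
    P.molid[i] = i / n_beads;
    P.beadid[i] = i % n_beads;
    P.qv[i] = P.q[P.beadid[i]];
  }
  return P;
}

// ---- neighbor list ---------------------------------------------------------

struct NeighborList {
  std::vector<int> head;          // CSR offsets, length nb+1
  std::vector<int> nbr;           // neighbor bead indices (j > i only)
  std::vector<double> ref;        // positions at last build (nb*3)
  double skin = 0.45;
  double rlist2 = 0.0;

  void build(const std::vector<double>& x, const Params& P) {
    const int nb = P.n_mol * P.n_beads;
    const double rl = P.rcut + skin;
    rlist2 = rl * rl;
    head.assign(nb + 1, 0);
    std::vector<std::vector<int>> tmp(nb);
    for (auto& t : tmp) t.reserve(24);
    int ncell = (int)std::floor(P.box / rl);
    if (ncell >= 3) {
      // cell list
      const double cw = P.box / ncell;
      const int ncell3 = ncell * ncell * ncell;
      std::vector<int> chead(ncell3, -1), cnext(nb, -1);
      std::vector<int> cx(nb), cy(nb), cz(nb);
      for (int i = 0; i < nb; ++i) {
        double px = x[3 * i], py = x[3 * i + 1], pz = x[3 * i + 2];
        int ix = (int)std::floor(px / cw); ix = ((ix % ncell) + ncell) % ncell;
        int iy = (int)std::floor(py / cw); iy = ((iy % ncell) + ncell) % ncell;
        int iz = (int)std::floor(pz / cw); iz = ((iz % ncell) + ncell) % ncell;
        cx[i] = ix; cy[i] = iy; cz[i] = iz;
        int c = (ix * ncell + iy) * ncell + iz;
        cnext[i] = chead[c]; chead[c] = i;
      }
      for (int i = 0; i < nb; ++i) {
        const int mi = P.molid[i], bi = P.beadid[i];
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              int jx = (cx[i] + dx + ncell) % ncell;
              int jy = (cy[i] + dy + ncell) % ncell;
              int jz = (cz[i] + dz + ncell) % ncell;
              int c = (jx * ncell + jy) * ncell + jz;
              for (int j = chead[c]; j >= 0; j = cnext[j]) {
                if (j <= i) continue;
                if (mi == P.molid[j] && std::abs(bi - P.beadid[j]) <= P.excl) continue;
                double ddx = min_image(x[3 * i] - x[3 * j], P.box);
                double ddy = min_image(x[3 * i + 1] - x[3 * j + 1], P.box);
                double ddz = min_image(x[3 * i + 2] - x[3 * j + 2], P.box);
                if (ddx * ddx + ddy * ddy + ddz * ddz < rlist2) tmp[i].push_back(j);
              }
            }
      }
    } else {
      // small box: all-pairs candidates
      for (int i = 0; i < nb; ++i) {
        const int mi = P.molid[i], bi = P.beadid[i];
        for (int j = i + 1; j < nb; ++j) {
          if (mi == P.molid[j] && std::abs(bi - P.beadid[j]) <= P.excl) continue;
          double ddx = min_image(x[3 * i] - x[3 * j], P.box);
          double ddy = min_image(x[3 * i + 1] - x[3 * j + 1], P.box);
          double ddz = min_image(x[3 * i + 2] - x[3 * j + 2], P.box);
          if (ddx * ddx + ddy * ddy + ddz * ddz < rlist2) tmp[i].push_back(j);
        }
      }
    }
    int tot = 0;
    for (int i = 0; i < nb; ++i) { head[i] = tot; tot += (int)tmp[i].size(); }
    head[nb] = tot;
    nbr.resize(tot);
    for (int i = 0, k = 0; i < nb; ++i)
      for (int j : tmp[i]) nbr[k++] = j;
    ref = x;
  }

  bool stale(const std::vector<double>& x) const {
    const double lim2 = 0.25 * skin * skin;
    for (size_t i = 0; i < x.size(); i += 3) {
      double dx = x[i] - ref[i], dy = x[i + 1] - ref[i + 1], dz = x[i + 2] - ref[i + 2];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }
};

// ---- energies and forces ---------------------------------------------------

double nonbonded_ef(const std::vector<double>& x, const Params& P,
                    const NeighborList& nl, std::vector<double>& f) {
  const int nb = P.n_mol * P.n_beads;
  double e = 0.0;
  for (int i = 0; i < nb; ++i) {
    const int qi = P.qv[i];
    for (int k = nl.head[i]; k < nl.head[i + 1]; ++k) {
      const int j = nl.nbr[k];
      double dx = min_image(x[3 * i] - x[3 * j], P.box);
      double dy = min_image(x[3 * i + 1] - x[3 * j + 1], P.box);
      double dz = min_image(x[3 * i + 2] - x[3 * j + 2], P.box);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= P.rcut2) continue;
      double fr;
      e += pair_ef(r2, qi * P.qv[j], P, fr);
      f[3 * i] += fr * dx;       f[3 * j] -= fr * dx;
      f[3 * i + 1] += fr * dy;   f[3 * j + 1] -= fr * dy;
      f[3 * i + 2] += fr * dz;   f[3 * j + 2] -= fr * dz;
    }
  }
  return e;
}

// harmonic bonds E = kbond (r - r0)^2 and angles E = kangle (theta - theta0)^2
// bond vectors and lengths are computed once per molecule and shared
double bonded_ef(const std::vector<double>& x, const Params& P,
                 std::vector<double>& f, std::vector<double>* per_mol = nullptr) {
  double e = 0.0;
  const int nbm = P.n_beads - 1;   // bonds per molecule
  std::vector<double> bx(nbm), by(nbm), bz(nbm), bl(nbm), binv(nbm);
  for (int m = 0; m < P.n_mol; ++m) {
    double em = 0.0;
    const int o = m * P.n_beads;
    for (int b = 0; b < nbm; ++b) {
      const int i = o + b, j = i + 1;
      double dx = x[3 * j] - x[3 * i];
      double dy = x[3 * j + 1] - x[3 * i + 1];
      double dz = x[3 * j + 2] - x[3 * i + 2];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double rinv = 1.0 / r;
      bx[b] = dx; by[b] = dy; bz[b] = dz; bl[b] = r; binv[b] = rinv;
      double dr = r - P.r0;
      em += P.kbond * dr * dr;
      double fr = -2.0 * P.kbond * dr * rinv;  // force on j along (rj - ri)
      f[3 * j] += fr * dx;     f[3 * i] -= fr * dx;
      f[3 * j + 1] += fr * dy; f[3 * i + 1] -= fr * dy;
      f[3 * j + 2] += fr * dz; f[3 * i + 2] -= fr * dz;
    }
    for (int b = 1; b < nbm; ++b) {
      // angle at bead o+b between bonds b-1 (into it) and b (out of it):
      // r21 = -bond[b-1], r23 = bond[b]
      const int i1 = o + b - 1, i2 = o + b, i3 = o + b + 1;
      const double ax = -bx[b - 1], ay = -by[b - 1], az = -bz[b - 1];
      const double cx2 = bx[b], cy2 = by[b], cz2 = bz[b];
      const double inv_ab = binv[b - 1] * binv[b];
      double c = (ax * cx2 + ay * cy2 + az * cz2) * inv_ab;
      c = std::max(-1.0, std::min(1.0, c));
      double th = std::acos(c);
      double dth = th - P.theta0;
      em += P.kangle * dth * dth;
      double s2 = 1.0 - c * c;
      double s = (s2 > 0.0) ? std::sqrt(s2) : 0.0;
      // F_i = (2 k dth / s) * grad_i c; as s -> 0 with theta0 = pi,
      // dth/s -> -1 so the prefactor tends to -2k (finite).
      double fac = (s > 1e-8) ? 2.0 * P.kangle * dth / s : -2.0 * P.kangle;
      const double inv_a2 = binv[b - 1] * binv[b - 1];
      const double inv_b2 = binv[b] * binv[b];
      double g1x = cx2 * inv_ab - c * ax * inv_a2;
      double g1y = cy2 * inv_ab - c * ay * inv_a2;
      double g1z = cz2 * inv_ab - c * az * inv_a2;
      double g3x = ax * inv_ab - c * cx2 * inv_b2;
      double g3y = ay * inv_ab - c * cy2 * inv_b2;
      double g3z = az * inv_ab - c * cz2 * inv_b2;
      f[3 * i1] += fac * g1x;     f[3 * i1 + 1] += fac * g1y;     f[3 * i1 + 2] += fac * g1z;
      f[3 * i3] += fac * g3x;     f[3 * i3 + 1] += fac * g3y;     f[3 * i3 + 2] += fac * g3z;
      f[3 * i2] -= fac * (g1x + g3x);
      f[3 * i2 + 1] -= fac * (g1y + g3y);
      f[3 * i2 + 2] -= fac * (g1z + g3z);
    }
    if (per_mol) (*per_mol)[m] = em;
    e += em;
  }
  return e;
}

// keep each molecule whole; wrap its centroid into [0, box)
void wrap_molecules(std::vector<double>& x, const Params& P) {
  for (int m = 0; m < P.n_mol; ++m) {
    const int o = m * P.n_beads;
    double cx = 0, cy = 0, cz = 0;
    for (int b = 0; b < P.n_beads; ++b) {
      cx += x[3 * (o + b)]; cy += x[3 * (o + b) + 1]; cz += x[3 * (o + b) + 2];
    }
    cx /= P.n_beads; cy /= P.n_beads; cz /= P.n_beads;
    double sx = -P.box * std::floor(cx / P.box);
    double sy = -P.box * std::floor(cy / P.box);
    double sz = -P.box * std::floor(cz / P.box);
    if (sx != 0 || sy != 0 || sz != 0)
      for (int b = 0; b < P.n_beads; ++b) {
        x[3 * (o + b)] += sx; x[3 * (o + b) + 1] += sy; x[3 * (o + b) + 2] += sz;
      }
  }
}

std::vector<double> as_vec(const NumericMatrix& m) {
  std::vector<double> v(m.nrow() * 3);
  for (int i = 0; i < m.nrow(); ++i)
    for (int k = 0; k < 3; ++k) v[3 * i + k] = m(i, k);
  return v;
}

NumericMatrix as_mat(const std::vector<double>& v) {
  int n = (int)v.size() / 3;
  NumericMatrix m(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) m(i, k) = v[3 * i + k];
  return m;
}

} // namespace

// [[Rcpp::export(name = ".cf_energy_forces")]]
List cf_energy_forces(NumericMatrix pos, double box, int n_beads, IntegerVector charges,
                      double epsH, double epsE, double screening_length, double rcut,
                      int excl_depth, double r0, double kbond, double theta0, double kangle) {
  const int nb = pos.nrow();
  if (nb % n_beads != 0) stop("position count is not a multiple of n_beads");
  Params P = make_params(box, nb / n_beads, n_beads, charges, epsH, epsE,
                         screening_length, rcut, excl_depth, r0, kbond, theta0, kangle);
  std::vector<double> x = as_vec(pos);
  for (double v : x) if (!std::isfinite(v)) stop("non-finite coordinate");
  NeighborList nl; nl.build(x, P);
  std::vector<double> f(x.size(), 0.0);
  std::vector<double> per_mol(P.n_mol, 0.0);
  double enb = nonbonded_ef(x, P, nl, f);
  double eb = bonded_ef(x, P, f, &per_mol);
  return List::create(_["energy"] = enb + eb, _["nonbonded"] = enb,
                      _["bonded"] = eb, _["bonded_per_molecule"] = wrap(per_mol),
                      _["forces"] = as_mat(f));
}

// [[Rcpp::export(name = ".cf_run")]]
List cf_run(NumericMatrix pos, NumericMatrix vel, double box, int n_beads,
            IntegerVector charges, double epsH, double epsE, double screening_length,
            double rcut, int excl_depth, double r0, double kbond, double theta0,
            double kangle, double dt, double damping, double temperature,
            int n_steps, int snapshot_every, int seed, bool thermostat,
            double limit_disp) {
  const int nb = pos.nrow();
  if (nb % n_beads != 0) stop("position count is not a multiple of n_beads");
  Params P = make_params(box, nb / n_beads, n_beads, charges, epsH, epsE,
                         screening_length, rcut, excl_depth, r0, kbond, theta0, kangle);
  std::vector<double> x = as_vec(pos), v = as_vec(vel);
  FastRng rng((uint64_t)(int64_t)seed);

  const double gamma = thermostat ? 1.0 / damping : 0.0;
  const double c1 = std::exp(-gamma * dt);
  const double c2 = (gamma > 0.0) ? std::sqrt((1.0 - c1 * c1) * temperature) : 0.0;
  const double half = 0.5 * dt;
  const double blow = 0.5 * box;

  NeighborList nl; nl.build(x, P);
  std::vector<double> f(x.size(), 0.0);
  nonbonded_ef(x, P, nl, f);
  bonded_ef(x, P, f);

  std::vector<NumericMatrix> snaps;
  std::vector<double> snap_t, snap_pot, snap_kin;
  auto record = [&](int step) {
    std::vector<double> ftmp(x.size(), 0.0);
    double pe = nonbonded_ef(x, P, nl, ftmp) + bonded_ef(x, P, ftmp);
    double ke = 0.0;
    for (double vv : v) ke += 0.5 * vv * vv;
    snaps.push_back(as_mat(x));
    snap_t.push_back(step * dt);
    snap_pot.push_back(pe);
    snap_kin.push_back(ke);
  };
  record(0);

  const size_t nn = x.size();
  const double max_step = blow;          // one-step displacement sanity bound
  const double stale_lim2 = 0.25 * nl.skin * nl.skin;
  for (int step = 1; step <= n_steps; ++step) {
    // BAOAB: B (half kick) A (half drift) O (friction+noise) A B
    bool bad = false, stale = false;
    for (size_t i = 0; i < nn; ++i) {
      double vv = v[i] + half * f[i];
      double xm = x[i] + half * vv;
      if (thermostat) vv = c1 * vv + c2 * rng.normal();
      double xn = xm + half * vv;
      double dstep = xn - x[i];
      if (limit_disp > 0.0) {
        if (dstep > limit_disp) { xn = x[i] + limit_disp; }
        else if (dstep < -limit_disp) { xn = x[i] - limit_disp; }
        dstep = xn - x[i];
      }
      if (!std::isfinite(xn) || std::fabs(dstep) > max_step) bad = true;
      x[i] = xn;
      v[i] = vv;
    }
    if (bad) stop("integration instability at step %d", step);
    for (size_t i = 0; i < nn; i += 3) {
      double dx = x[i] - nl.ref[i], dy = x[i + 1] - nl.ref[i + 1],
             dz = x[i + 2] - nl.ref[i + 2];
      if (dx * dx + dy * dy + dz * dz > stale_lim2) { stale = true; break; }
    }
    if (stale) { wrap_molecules(x, P); nl.build(x, P); }
    std::fill(f.begin(), f.end(), 0.0);
    nonbonded_ef(x, P, nl, f);
    bonded_ef(x, P, f);
    for (size_t i = 0; i < nn; ++i) v[i] += half * f[i];
    if (snapshot_every > 0 && step % snapshot_every == 0) record(step);
  }
  if (snapshot_every <= 0 || n_steps % std::max(snapshot_every, 1) != 0) record(n_steps);

  List snl(snaps.size());
  for (size_t i = 0; i < snaps.size(); ++i) snl[i] = snaps[i];
  return List::create(_["snapshots"] = snl, _["times"] = wrap(snap_t),
                      _["potential"] = wrap(snap_pot), _["kinetic"] = wrap(snap_kin),
                      _["final_positions"] = as_mat(x), _["final_velocities"] = as_mat(v));
}

// Soft push-off relaxation: purely repulsive (WCA) nonbonded core + bonded
// terms, steepest descent with a per-iteration displacement cap.
// [[Rcpp::export(name = ".cf_relax")]]
NumericMatrix cf_relax(NumericMatrix pos, double box, int n_beads, IntegerVector charges,
                       double rcut_wca, int excl_depth, double r0, double kbond,
                       double theta0, double kangle, int n_iter, double max_disp) {
  const int nb = pos.nrow();
  Params P = make_params(box, nb / n_beads, n_beads, charges, 1.0, 0.0, 1.0,
                         rcut_wca, excl_depth, r0, kbond, theta0, kangle);
  std::vector<double> x = as_vec(pos);
  NeighborList nl; nl.build(x, P);
  std::vector<double> f(x.size());
  const double alpha = 2e-4;
  for (int it = 0; it < n_iter; ++it) {
    std::fill(f.begin(), f.end(), 0.0);
    nonbonded_ef(x, P, nl, f);
    bonded_ef(x, P, f);
    for (size_t i = 0; i < x.size(); ++i) {
      double d = alpha * f[i];
      if (d > max_disp) d = max_disp; else if (d < -max_disp) d = -max_disp;
      x[i] += d;
    }
    if (nl.stale(x)) { wrap_molecules(x, P); nl.build(x, P); }
  }
  wrap_molecules(x, P);
  return as_mat(x);
}

// Union-find cluster detection: molecules are connected iff any inter-molecular
// bead pair is closer than cutoff (minimum image).  Also returns per-molecule
// integer image shifts that make each cluster spatially whole.
// [[Rcpp::export(name = ".cf_clusters")]]
List cf_clusters(NumericMatrix pos, double box, int n_beads, double cutoff) {
  const int nb = pos.nrow();
  const int n_mol = nb / n_beads;
  std::vector<double> x = as_vec(pos);
  const double c2 = cutoff * cutoff;

  std::vector<int> parent(n_mol);
  for (int i = 0; i < n_mol; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  // adjacency with bead-level image shifts for unwrapping
  std::vector<std::vector<std::array<double, 4>>> adj(n_mol);

  auto consider = [&](int i, int j) {
    const int mi = i / n_beads, mj = j / n_beads;
    if (mi == mj) return;
    double rx = x[3 * i] - x[3 * j], ry = x[3 * i + 1] - x[3 * j + 1],
           rz = x[3 * i + 2] - x[3 * j + 2];
    double sx = std::round(rx / box), sy = std::round(ry / box), sz = std::round(rz / box);
    double dx = rx - box * sx, dy = ry - box * sy, dz = rz - box * sz;
    if (dx * dx + dy * dy + dz * dz < c2) {
      int ra = find(mi), rb = find(mj);
      if (ra != rb) parent[ra] = rb;
      // shift to apply to mj so that it sits next to mi: pos_j + s*box ~ pos_i
      adj[mi].push_back({(double)mj, sx, sy, sz});
      adj[mj].push_back({(double)mi, -sx, -sy, -sz});
    }
  };

  int ncell = (int)std::floor(box / cutoff);
  if (ncell >= 3) {
    const double cw = box / ncell;
    const int ncell3 = ncell * ncell * ncell;
    std::vector<int> chead(ncell3, -1), cnext(nb, -1), cx(nb), cy(nb), cz(nb);
    for (int i = 0; i < nb; ++i) {
      int ix = (int)std::floor(x[3 * i] / cw); ix = ((ix % ncell) + ncell) % ncell;
      int iy = (int)std::floor(x[3 * i + 1] / cw); iy = ((iy % ncell) + ncell) % ncell;
      int iz = (int)std::floor(x[3 * i + 2] / cw); iz = ((iz % ncell) + ncell) % ncell;
      cx[i] = ix; cy[i] = iy; cz[i] = iz;
      int c = (ix * ncell + iy) * ncell + iz;
      cnext[i] = chead[c]; chead[c] = i;
    }
    for (int i = 0; i < nb; ++i)
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int jx = (cx[i] + dx + ncell) % ncell, jy = (cy[i] + dy + ncell) % ncell,
                jz = (cz[i] + dz + ncell) % ncell;
            int c = (jx * ncell + jy) * ncell + jz;
            for (int j = chead[c]; j >= 0; j = cnext[j])
              if (j > i) consider(i, j);
          }
  } else {
    for (int i = 0; i < nb; ++i)
      for (int j = i + 1; j < nb; ++j) consider(i, j);
  }

  // relabel clusters 1..k
  std::vector<int> lab(n_mol, 0);
  int k = 0;
  for (int i = 0; i < n_mol; ++i) {
    int r = find(i);
    if (lab[r] == 0) lab[r] = ++k;
  }
  IntegerVector assignment(n_mol);
  for (int i = 0; i < n_mol; ++i) assignment[i] = lab[find(i)];

  // BFS per cluster for unwrapping shifts (units of box length)
  NumericMatrix shifts(n_mol, 3);
  std::vector<char> seen(n_mol, 0);
  std::vector<int> queue;
  for (int s = 0; s < n_mol; ++s) {
    if (seen[s]) continue;
    seen[s] = 1;
    queue.clear(); queue.push_back(s);
    for (size_t qh = 0; qh < queue.size(); ++qh) {
      int i = queue[qh];
      for (auto& e : adj[i]) {
        int j = (int)e[0];
        if (seen[j]) continue;
        seen[j] = 1;
        // pos_i - pos_j - s*box was the direct vector => unwrapped_j = pos_j + s*box + shift_i*box...
        shifts(j, 0) = shifts(i, 0) + e[1];
        shifts(j, 1) = shifts(i, 1) + e[2];
        shifts(j, 2) = shifts(i, 2) + e[3];
        queue.push_back(j);
      }
    }
  }
  return List::create(_["assignment"] = assignment, _["shifts"] = shifts);
}
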