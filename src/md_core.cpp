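// Core molecular-dynamics engine for the strings-and-binders (SBS) polymer
// model: self-avoiding-walk initial states, random binder injection,
// FENE + WCA + cognate Lennard-Jones energetics, and Langevin dynamics
// integrated with velocity-Verlet under cubic periodic boundaries.
//
// Units: bead/binder diameter sigma = 1, mass m = 1, k_B T = 1 at T = 1.
// Positions are integrated unwrapped (for analysis); a wrapped copy is
// maintained for neighbour search and minimum-image arithmetic. Particle
// coordinates, velocities and forces are stored interleaved (x,y,z per
// particle) for cache locality in the pair loops.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG -----
// xoshiro256++ seeded through splitmix64; independent of R's RNG so that
// long runs are cheap and reproducible from a single integer seed.
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }      // [0,1)
  inline double unif_pos() {                                        // (0,1]
    return ((next() >> 11) + 1) * 0x1.0p-53;
  }
};

// Marsaglia-Tsang ziggurat for standard normals (128 layers); tables are
// built once at construction from the classic layer constants.
struct ZigNormal {
  uint32_t kn[128];
  double wn[128], fn[128];
  ZigNormal() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
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
  inline double draw(Xoshiro &rng) {
    for (;;) {
      const int32_t hz = (int32_t)(uint32_t)rng.next();
      const uint32_t iz = (uint32_t)hz & 127u;
      const uint32_t ahz = (hz < 0) ? (uint32_t)(-(int64_t)hz)
                                    : (uint32_t)hz;
      if (ahz < kn[iz]) return hz * wn[iz];
      if (iz == 0) {            // tail beyond r
        const double r = 3.442619855899;
        double x, y;
        do {
          x = -std::log(rng.unif_pos()) / r;
          y = -std::log(rng.unif_pos());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -(r + x);
      }
      const double x = hz * wn[iz];
      if (fn[iz] + rng.unif() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

// ---------------------------------------------------------- potentials ----
struct PairParams {
  double r0;        // FENE maximum extension
  double kfene;     // FENE spring constant
  double rc_wca;    // 2^(1/6) sigma
  double rc_att;    // attractive cut-off (1.5 sigma)
  double r02, rc_wca2, rc_att2;
  double att_shift_unit;  // 4[(1/rc)^12 - (1/rc)^6], per unit epsilon
  void finish() {
    r02 = r0 * r0;
    rc_wca2 = rc_wca * rc_wca;
    rc_att2 = rc_att * rc_att;
    const double s6 = std::pow(rc_att, -6.0);
    att_shift_unit = 4.0 * (s6 * s6 - s6);
  }
};

// general minimum image (any separation magnitude)
static inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// minimum image for wrapped-coordinate differences, |d| < L guaranteed
static inline double min_image_w(double d, double L, double halfL) {
  if (d > halfL) return d - L;
  if (d < -halfL) return d + L;
  return d;
}

// WCA energy and force/r at squared separation r2 (r2 < rc_wca2 assumed)
static inline void wca_pair(double r2, double &u, double &fr) {
  const double sr2 = 1.0 / r2;
  const double sr6 = sr2 * sr2 * sr2;
  const double sr12 = sr6 * sr6;
  u = 4.0 * (sr12 - sr6) + 1.0;
  fr = 24.0 * (2.0 * sr12 - sr6) * sr2;
}

// full truncated-shifted LJ with depth parameter eps
static inline void lj_pair(double r2, double eps, double shift_unit,
                           double &u, double &fr) {
  const double sr2 = 1.0 / r2;
  const double sr6 = sr2 * sr2 * sr2;
  const double sr12 = sr6 * sr6;
  u = eps * (4.0 * (sr12 - sr6) - shift_unit);
  fr = eps * 24.0 * (2.0 * sr12 - sr6) * sr2;
}

// ------------------------------------------------------------ system ------
// Particle i is a polymer bead when i < n_beads (chain bonds i,i+1) and a
// binder otherwise. `mask` carries binding-site labels as bits: for a bead,
// the set of site types it exposes; for a binder, the single bit of its
// type. A pair is cognate (attractive) iff exactly one of the two is a
// binder and the masks intersect; epsilon is the binder type's affinity.
struct System {
  int n, n_beads;
  double L, halfL;
  std::vector<double> u;          // unwrapped, interleaved x,y,z
  std::vector<double> w;          // wrapped to [0, L), interleaved
  std::vector<uint32_t> mask;
  std::vector<double> eps;        // per-particle affinity (binders), 0 beads
  PairParams pp;

  inline bool is_binder(int i) const { return i >= n_beads; }
  void rewrap() {
    for (int k = 0; k < 3 * n; ++k)
      w[k] = u[k] - L * std::floor(u[k] / L);
  }
};

// ----------------------------------------------------- neighbour lists ----
// Verlet half pair lists built from a counting-sort cell decomposition of
// the wrapped box, split by interaction class (WCA vs cognate LJ).
struct NeighborList {
  double skin, rlist_att2, rlist_wca2, rmax;
  int ncell, ncell3;
  double cell_sz;
  std::vector<int> cell_start, cell_count, order, ci, fillpos, occupied;
  std::vector<double> sp;          // sorted coordinates, interleaved
  std::vector<uint32_t> smask;
  std::vector<uint8_t> sbind;
  std::vector<double> seps;
  std::vector<int> stencil;        // 13 forward cells per cell
  std::vector<int> wi, wj;         // WCA pairs
  std::vector<int> ai, aj;         // cognate pairs
  std::vector<double> ae;          // cognate epsilon
  std::vector<double> u0;          // unwrapped positions at last build

  void setup(const System &S, double skin_) {
    skin = skin_;
    const double ra = S.pp.rc_att + skin, rw = S.pp.rc_wca + skin;
    rlist_att2 = ra * ra;
    rlist_wca2 = rw * rw;
    rmax = ra;
    ncell = (int)std::floor(S.L / rmax);
    if (ncell < 3)
      stop("box too small for neighbour search: need L >= 3*(cutoff+skin)");
    ncell3 = ncell * ncell * ncell;
    cell_sz = S.L / ncell;
    cell_start.resize(ncell3 + 1);
    cell_count.resize(ncell3);
    fillpos.resize(ncell3 + 1);
    order.resize(S.n);
    ci.resize(S.n);
    sp.resize(3 * S.n);
    smask.resize(S.n);
    sbind.resize(S.n);
    seps.resize(S.n);
    stencil.assign((size_t)ncell3 * 13, 0);
    int offs[13][3];
    int off = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          if (dz > 0 || (dz == 0 && dy > 0) ||
              (dz == 0 && dy == 0 && dx > 0)) {
            offs[off][0] = dx; offs[off][1] = dy; offs[off][2] = dz;
            ++off;
          }
    for (int cz = 0; cz < ncell; ++cz)
      for (int cy = 0; cy < ncell; ++cy)
        for (int cx = 0; cx < ncell; ++cx) {
          const int c = (cz * ncell + cy) * ncell + cx;
          for (int k = 0; k < 13; ++k) {
            const int ex = (cx + offs[k][0] + ncell) % ncell;
            const int ey = (cy + offs[k][1] + ncell) % ncell;
            const int ez = (cz + offs[k][2] + ncell) % ncell;
            stencil[(size_t)c * 13 + k] = (ez * ncell + ey) * ncell + ex;
          }
        }
    wi.reserve((size_t)S.n * 6);
    wj.reserve((size_t)S.n * 6);
    ai.reserve((size_t)S.n * 2);
    aj.reserve((size_t)S.n * 2);
    ae.reserve((size_t)S.n * 2);
  }

  inline int cell_of(const System &S, int i) const {
    int cx = (int)(S.w[3 * i] / cell_sz),
        cy = (int)(S.w[3 * i + 1] / cell_sz),
        cz = (int)(S.w[3 * i + 2] / cell_sz);
    if (cx >= ncell) cx = ncell - 1;
    if (cy >= ncell) cy = ncell - 1;
    if (cz >= ncell) cz = ncell - 1;
    if (cx < 0) cx = 0;
    if (cy < 0) cy = 0;
    if (cz < 0) cz = 0;
    return (cz * ncell + cy) * ncell + cx;
  }

  inline void classify_push(int a, int b) {
    if ((sbind[a] != sbind[b]) && (smask[a] & smask[b])) {
      ai.push_back(order[a]);
      aj.push_back(order[b]);
      ae.push_back(sbind[a] ? seps[a] : seps[b]);
    } else {
      wi.push_back(order[a]);
      wj.push_back(order[b]);
    }
  }

  void build(const System &S) {
    const int n = S.n;
    const double L = S.L, halfL = S.halfL;
    std::fill(cell_count.begin(), cell_count.end(), 0);
    occupied.clear();
    for (int i = 0; i < n; ++i) {
      ci[i] = cell_of(S, i);
      if (cell_count[ci[i]]++ == 0) occupied.push_back(ci[i]);
    }
    cell_start[0] = 0;
    for (int c = 0; c < ncell3; ++c)
      cell_start[c + 1] = cell_start[c] + cell_count[c];
    std::copy(cell_start.begin(), cell_start.end(), fillpos.begin());
    for (int i = 0; i < n; ++i) {
      const int pos = fillpos[ci[i]]++;
      order[pos] = i;
      sp[3 * pos] = S.w[3 * i];
      sp[3 * pos + 1] = S.w[3 * i + 1];
      sp[3 * pos + 2] = S.w[3 * i + 2];
      smask[pos] = S.mask[i];
      sbind[pos] = S.is_binder(i) ? 1 : 0;
      seps[pos] = S.eps[i];
    }
    wi.clear(); wj.clear();
    ai.clear(); aj.clear(); ae.clear();
    std::sort(occupied.begin(), occupied.end());
    for (const int c : occupied) {
      const int a0 = cell_start[c], a1 = cell_start[c + 1];
      for (int a = a0; a < a1; ++a) {
        const double xa = sp[3 * a], ya = sp[3 * a + 1],
                     za = sp[3 * a + 2];
        // same cell, second half (no wrap possible within one cell)
        for (int b = a + 1; b < a1; ++b) {
          const double dx = xa - sp[3 * b], dy = ya - sp[3 * b + 1],
                       dz = za - sp[3 * b + 2];
          const double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 < rlist_att2 &&
              (r2 < rlist_wca2 ||
               ((sbind[a] != sbind[b]) && (smask[a] & smask[b]))))
            classify_push(a, b);
        }
        for (int k = 0; k < 13; ++k) {
          const int cc = stencil[(size_t)c * 13 + k];
          const int b1 = cell_start[cc + 1];
          for (int b = cell_start[cc]; b < b1; ++b) {
            const double dx = min_image_w(xa - sp[3 * b], L, halfL);
            const double dy = min_image_w(ya - sp[3 * b + 1], L, halfL);
            const double dz = min_image_w(za - sp[3 * b + 2], L, halfL);
            const double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 < rlist_att2 &&
                (r2 < rlist_wca2 ||
                 ((sbind[a] != sbind[b]) && (smask[a] & smask[b]))))
              classify_push(a, b);
          }
        }
      }
    }
    u0 = S.u;
  }

  // true when some particle moved more than skin/2 since last build
  bool stale(const System &S) const {
    const double lim = 0.25 * skin * skin;
    const double *a = S.u.data(), *b = u0.data();
    for (int i = 0; i < S.n; ++i) {
      const double dx = a[3 * i] - b[3 * i];
      const double dy = a[3 * i + 1] - b[3 * i + 1];
      const double dz = a[3 * i + 2] - b[3 * i + 2];
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  }
};

// ------------------------------------------------------------- forces -----
struct EnergyAcc {
  double fene = 0.0, rep = 0.0, att = 0.0;
  bool fene_diverged = false;
  int bad_bond = -1;
};

// FENE contribution over chain bonds; returns false on r >= R0
static bool add_fene(const System &S, double *f, EnergyAcc &E) {
  const double L = S.L;
  const double *u = S.u.data();
  for (int i = 0; i + 1 < S.n_beads; ++i) {
    const double dx = min_image(u[3 * i] - u[3 * i + 3], L);
    const double dy = min_image(u[3 * i + 1] - u[3 * i + 4], L);
    const double dz = min_image(u[3 * i + 2] - u[3 * i + 5], L);
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= S.pp.r02) {
      E.fene_diverged = true;
      E.bad_bond = i;
      return false;
    }
    const double wfac = 1.0 - r2 / S.pp.r02;
    E.fene += -0.5 * S.pp.kfene * S.pp.r02 * std::log(wfac);
    const double fr = -S.pp.kfene / wfac;  // attractive toward r = 0
    f[3 * i] += fr * dx;     f[3 * i + 1] += fr * dy;
    f[3 * i + 2] += fr * dz;
    f[3 * i + 3] -= fr * dx; f[3 * i + 4] -= fr * dy;
    f[3 * i + 5] -= fr * dz;
  }
  return true;
}

static bool forces_cell(const System &S, const NeighborList &NL,
                        std::vector<double> &fv, EnergyAcc &E) {
  std::fill(fv.begin(), fv.end(), 0.0);
  double *f = fv.data();
  const double L = S.L, halfL = S.halfL;
  const double rc_wca2 = S.pp.rc_wca2, rc_att2 = S.pp.rc_att2;
  const double shift_unit = S.pp.att_shift_unit;
  const double *w = S.w.data();
  {
    const size_t np = NL.wi.size();
    const int *pa = NL.wi.data(), *pb = NL.wj.data();
    for (size_t k = 0; k < np; ++k) {
      const int i3 = 3 * pa[k], j3 = 3 * pb[k];
      const double dx = min_image_w(w[i3] - w[j3], L, halfL);
      const double dy = min_image_w(w[i3 + 1] - w[j3 + 1], L, halfL);
      const double dz = min_image_w(w[i3 + 2] - w[j3 + 2], L, halfL);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc_wca2) continue;
      double uu, fr;
      wca_pair(r2, uu, fr);
      E.rep += uu;
      f[i3] += fr * dx; f[i3 + 1] += fr * dy; f[i3 + 2] += fr * dz;
      f[j3] -= fr * dx; f[j3 + 1] -= fr * dy; f[j3 + 2] -= fr * dz;
    }
  }
  {
    const size_t np = NL.ai.size();
    const int *pa = NL.ai.data(), *pb = NL.aj.data();
    const double *pe = NL.ae.data();
    for (size_t k = 0; k < np; ++k) {
      const int i3 = 3 * pa[k], j3 = 3 * pb[k];
      const double dx = min_image_w(w[i3] - w[j3], L, halfL);
      const double dy = min_image_w(w[i3 + 1] - w[j3 + 1], L, halfL);
      const double dz = min_image_w(w[i3 + 2] - w[j3 + 2], L, halfL);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc_att2) continue;
      double uu, fr;
      lj_pair(r2, pe[k], shift_unit, uu, fr);
      E.att += uu;
      f[i3] += fr * dx; f[i3 + 1] += fr * dy; f[i3 + 2] += fr * dz;
      f[j3] -= fr * dx; f[j3 + 1] -= fr * dy; f[j3 + 2] -= fr * dz;
    }
  }
  return add_fene(S, f, E);
}

static bool forces_all(const System &S, std::vector<double> &fv,
                       EnergyAcc &E) {
  std::fill(fv.begin(), fv.end(), 0.0);
  double *f = fv.data();
  const double L = S.L;
  const double *u = S.u.data();
  for (int i = 0; i < S.n; ++i)
    for (int j = i + 1; j < S.n; ++j) {
      const double dx = min_image(u[3 * i] - u[3 * j], L);
      const double dy = min_image(u[3 * i + 1] - u[3 * j + 1], L);
      const double dz = min_image(u[3 * i + 2] - u[3 * j + 2], L);
      const double r2 = dx * dx + dy * dy + dz * dz;
      double uu, fr;
      const bool cog = (S.is_binder(i) != S.is_binder(j)) &&
                       (S.mask[i] & S.mask[j]);
      if (cog) {
        if (r2 >= S.pp.rc_att2) continue;
        const double e = S.is_binder(i) ? S.eps[i] : S.eps[j];
        lj_pair(r2, e, S.pp.att_shift_unit, uu, fr);
        E.att += uu;
      } else {
        if (r2 >= S.pp.rc_wca2) continue;
        wca_pair(r2, uu, fr);
        E.rep += uu;
      }
      f[3 * i] += fr * dx;
      f[3 * i + 1] += fr * dy;
      f[3 * i + 2] += fr * dz;
      f[3 * j] -= fr * dx;
      f[3 * j + 1] -= fr * dy;
      f[3 * j + 2] -= fr * dz;
    }
  return add_fene(S, f, E);
}

// ------------------------------------------------------- construction -----
static System make_system(const NumericMatrix &coords, int n_beads,
                          const IntegerVector &mask,
                          const NumericVector &eps, double L, double r0,
                          double kfene, double rc_wca, double rc_att) {
  System S;
  S.n = coords.nrow();
  S.n_beads = n_beads;
  S.L = L;
  S.halfL = 0.5 * L;
  S.u.resize(3 * S.n);
  S.w.resize(3 * S.n);
  for (int i = 0; i < S.n; ++i) {
    S.u[3 * i] = coords(i, 0);
    S.u[3 * i + 1] = coords(i, 1);
    S.u[3 * i + 2] = coords(i, 2);
  }
  S.rewrap();
  S.mask.resize(S.n);
  S.eps.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    S.mask[i] = (uint32_t)mask[i];
    S.eps[i] = eps[i];
  }
  S.pp.r0 = r0; S.pp.kfene = kfene; S.pp.rc_wca = rc_wca;
  S.pp.rc_att = rc_att; S.pp.finish();
  return S;
}

// ------------------------------------------------------------ exports -----

// Energy breakdown and forces; method "all" is the brute-force reference,
// "cell" exercises the production neighbour-list path.
// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix coords, int n_beads,
                       IntegerVector mask, NumericVector eps, double L,
                       double r0, double kfene, double rc_wca,
                       double rc_att, std::string method = "all",
                       double skin = 0.5) {
  System S = make_system(coords, n_beads, mask, eps, L, r0, kfene, rc_wca,
                         rc_att);
  std::vector<double> fv(3 * S.n);
  EnergyAcc E;
  if (method == "cell") {
    NeighborList NL;
    NL.setup(S, skin);
    NL.build(S);
    forces_cell(S, NL, fv, E);
  } else {
    forces_all(S, fv, E);
  }
  NumericMatrix F(S.n, 3);
  for (int i = 0; i < S.n; ++i) {
    F(i, 0) = fv[3 * i]; F(i, 1) = fv[3 * i + 1]; F(i, 2) = fv[3 * i + 2];
  }
  return List::create(_["fene"] = E.fene, _["repulsive"] = E.rep,
                      _["attractive"] = E.att,
                      _["total"] = E.fene + E.rep + E.att,
                      _["forces"] = F, _["diverged"] = E.fene_diverged,
                      _["bad_bond"] = E.bad_bond + 1);
}

// Self-avoiding-walk chain growth: unit-ish bonds, all non-bonded pairs
// kept >= min_sep apart (minimum image), grown with backtracking.
// [[Rcpp::export]]
NumericMatrix cpp_init_saw(int n, double L, int seed, double min_sep = 0.9,
                           double bond_lo = 0.95, double bond_hi = 1.05,
                           int max_restarts = 200) {
  Xoshiro rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 1234567ULL);
  const double ms2 = min_sep * min_sep;
  std::vector<double> x(n), y(n), z(n);

  const int g = std::max(3, (int)std::floor(L / 1.0));
  const double gs = L / g;
  auto wrap = [&](double v) { return v - L * std::floor(v / L); };
  auto cell_idx = [&](double px, double py, double pz) {
    int cx = (int)(wrap(px) / gs) % g, cy = (int)(wrap(py) / gs) % g,
        cz = (int)(wrap(pz) / gs) % g;
    return (cz * g + cy) * g + cx;
  };

  for (int restart = 0; restart < max_restarts; ++restart) {
    std::vector<std::vector<int>> grid(g * g * g);
    auto ok_at = [&](double px, double py, double pz, int upto, int skip) {
      const int cx = (int)(wrap(px) / gs) % g, cy = (int)(wrap(py) / gs) % g,
                cz = (int)(wrap(pz) / gs) % g;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            const int c = (((cz + dz + g) % g) * g + ((cy + dy + g) % g)) * g +
                          ((cx + dx + g) % g);
            for (int j : grid[c]) {
              if (j >= upto || j == skip) continue;
              const double ddx = min_image(px - x[j], L);
              const double ddy = min_image(py - y[j], L);
              const double ddz = min_image(pz - z[j], L);
              if (ddx * ddx + ddy * ddy + ddz * ddz < ms2) return false;
            }
          }
      return true;
    };

    x[0] = rng.unif() * L; y[0] = rng.unif() * L; z[0] = rng.unif() * L;
    grid[cell_idx(x[0], y[0], z[0])].push_back(0);
    int i = 1;
    bool failed = false;
    while (i < n) {
      bool placed = false;
      for (int attempt = 0; attempt < 60; ++attempt) {
        double ux, uy, uz, s2;
        do {
          ux = 2.0 * rng.unif() - 1.0;
          uy = 2.0 * rng.unif() - 1.0;
          uz = 2.0 * rng.unif() - 1.0;
          s2 = ux * ux + uy * uy + uz * uz;
        } while (s2 > 1.0 || s2 < 1e-12);
        const double inv = 1.0 / std::sqrt(s2);
        const double b = bond_lo + (bond_hi - bond_lo) * rng.unif();
        const double px = x[i - 1] + b * ux * inv;
        const double py = y[i - 1] + b * uy * inv;
        const double pz = z[i - 1] + b * uz * inv;
        if (ok_at(px, py, pz, i, i - 1)) {
          x[i] = px; y[i] = py; z[i] = pz;
          grid[cell_idx(px, py, pz)].push_back(i);
          placed = true;
          break;
        }
      }
      if (placed) {
        ++i;
      } else {
        const int back = std::min(i - 1, 8);
        for (int k = 0; k < back; ++k) {
          --i;
          grid[cell_idx(x[i], y[i], z[i])].pop_back();
        }
        if (i <= 1) { failed = true; break; }
      }
    }
    if (!failed && i == n) {
      // Pivot refinement: growth alone samples a kinetically biased
      // ensemble; Metropolis pivot moves (rigid rotation of one tail,
      // accepted when excluded volume holds) converge to the uniform
      // self-avoiding ensemble with the correct swelling exponent.
      const int n_pivots = 12 * n;
      for (int it = 0; it < n_pivots; ++it) {
        const int p = 1 + (int)(rng.unif() * (n - 2));
        const bool tail_right = (n - 1 - p) <= p;
        const int m0 = tail_right ? p + 1 : 0;
        const int m1 = tail_right ? n : p;      // [m0, m1) moves
        // uniform random rotation from a normalized quaternion
        double q0, q1, q2, q3, qs;
        do {
          q0 = 2 * rng.unif() - 1; q1 = 2 * rng.unif() - 1;
          q2 = 2 * rng.unif() - 1; q3 = 2 * rng.unif() - 1;
          qs = q0 * q0 + q1 * q1 + q2 * q2 + q3 * q3;
        } while (qs > 1.0 || qs < 1e-8);
        const double s = 1.0 / qs;
        const double R[3][3] = {
          {1 - 2 * s * (q2 * q2 + q3 * q3),
           2 * s * (q1 * q2 - q0 * q3), 2 * s * (q1 * q3 + q0 * q2)},
          {2 * s * (q1 * q2 + q0 * q3),
           1 - 2 * s * (q1 * q1 + q3 * q3),
           2 * s * (q2 * q3 - q0 * q1)},
          {2 * s * (q1 * q3 - q0 * q2), 2 * s * (q2 * q3 + q0 * q1),
           1 - 2 * s * (q1 * q1 + q2 * q2)}};
        const double px = x[p], py = y[p], pz = z[p];
        std::vector<double> nx(m1 - m0), ny(m1 - m0), nz(m1 - m0);
        bool ok = true;
        for (int k = m0; k < m1 && ok; ++k) {
          const double dx = x[k] - px, dy = y[k] - py, dz = z[k] - pz;
          const double rx = R[0][0] * dx + R[0][1] * dy + R[0][2] * dz;
          const double ry = R[1][0] * dx + R[1][1] * dy + R[1][2] * dz;
          const double rz = R[2][0] * dx + R[2][1] * dy + R[2][2] * dz;
          const double cx = px + rx, cy = py + ry, cz = pz + rz;
          nx[k - m0] = cx; ny[k - m0] = cy; nz[k - m0] = cz;
          // moved beads keep their internal distances (rigid rotation);
          // check only against the unmoved part, skipping the pivot
          // bead's bonded neighbour inside the moved set
          const int lo = tail_right ? 0 : p;
          const int hi = tail_right ? p + 1 : n;
          for (int j = lo; j < hi; ++j) {
            if (tail_right && j == p && k == p + 1) continue;
            if (!tail_right && j == p && k == p - 1) continue;
            const double ddx = min_image(cx - x[j], L);
            const double ddy = min_image(cy - y[j], L);
            const double ddz = min_image(cz - z[j], L);
            if (ddx * ddx + ddy * ddy + ddz * ddz < ms2) {
              ok = false;
              break;
            }
          }
        }
        // a rigid rotation preserves true intra-tail distances but not
        // minimum-image ones: when the chain extent exceeds the box,
        // rotated beads can collide through the periodic boundary
        if (ok) {
          const int nm = m1 - m0;
          for (int a = 0; a < nm && ok; ++a)
            for (int b = a + 2; b < nm; ++b) {
              const double ddx = min_image(nx[a] - nx[b], L);
              const double ddy = min_image(ny[a] - ny[b], L);
              const double ddz = min_image(nz[a] - nz[b], L);
              if (ddx * ddx + ddy * ddy + ddz * ddz < ms2) {
                ok = false;
                break;
              }
            }
        }
        if (ok) {
          for (int k = m0; k < m1; ++k) {
            x[k] = nx[k - m0]; y[k] = ny[k - m0]; z[k] = nz[k - m0];
          }
        }
      }
      NumericMatrix out(n, 3);
      for (int k = 0; k < n; ++k) {
        out(k, 0) = x[k]; out(k, 1) = y[k]; out(k, 2) = z[k];
      }
      return out;
    }
  }
  stop("SAW placement failed after %d restarts; try a larger box",
       max_restarts);
  return NumericMatrix(0, 3);  // not reached
}

// Random sequential insertion of binders, keeping >= min_sep from all
// previously placed particles (beads included), minimum image.
// [[Rcpp::export]]
NumericMatrix cpp_place_binders(NumericMatrix bead_coords, int m, double L,
                                int seed, double min_sep = 0.9,
                                int max_tries = 200) {
  Xoshiro rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 777ULL);
  const int nb = bead_coords.nrow();
  const double ms2 = min_sep * min_sep;
  const int g = std::max(3, (int)std::floor(L / 1.0));
  const double gs = L / g;
  std::vector<std::vector<int>> grid(g * g * g);
  std::vector<double> x(nb + m), y(nb + m), z(nb + m);
  auto wrap = [&](double v) { return v - L * std::floor(v / L); };
  auto cell_idx = [&](double px, double py, double pz) {
    int cx = (int)(wrap(px) / gs) % g, cy = (int)(wrap(py) / gs) % g,
        cz = (int)(wrap(pz) / gs) % g;
    return (cz * g + cy) * g + cx;
  };
  for (int i = 0; i < nb; ++i) {
    x[i] = bead_coords(i, 0); y[i] = bead_coords(i, 1);
    z[i] = bead_coords(i, 2);
    grid[cell_idx(x[i], y[i], z[i])].push_back(i);
  }
  auto ok_at = [&](double px, double py, double pz, int upto) {
    const int cx = (int)(wrap(px) / gs) % g, cy = (int)(wrap(py) / gs) % g,
              cz = (int)(wrap(pz) / gs) % g;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          const int c = (((cz + dz + g) % g) * g + ((cy + dy + g) % g)) * g +
                        ((cx + dx + g) % g);
          for (int j : grid[c]) {
            if (j >= upto) continue;
            const double ddx = min_image(px - x[j], L);
            const double ddy = min_image(py - y[j], L);
            const double ddz = min_image(pz - z[j], L);
            if (ddx * ddx + ddy * ddy + ddz * ddz < ms2) return false;
          }
        }
    return true;
  };
  for (int k = 0; k < m; ++k) {
    const int i = nb + k;
    bool placed = false;
    for (int t = 0; t < max_tries; ++t) {
      const double px = rng.unif() * L, py = rng.unif() * L,
                   pz = rng.unif() * L;
      if (ok_at(px, py, pz, i)) {
        x[i] = px; y[i] = py; z[i] = pz;
        grid[cell_idx(px, py, pz)].push_back(i);
        placed = true;
        break;
      }
    }
    if (!placed)
      stop("binder packing too dense: failed to place binder %d of %d",
           k + 1, m);
  }
  NumericMatrix out(m, 3);
  for (int k = 0; k < m; ++k) {
    out(k, 0) = x[nb + k]; out(k, 1) = y[nb + k]; out(k, 2) = z[nb + k];
  }
  return out;
}

static double rg_beads(const System &S) {
  double c[3] = {0, 0, 0};
  for (int i = 0; i < S.n_beads; ++i)
    for (int d = 0; d < 3; ++d) c[d] += S.u[3 * i + d];
  for (int d = 0; d < 3; ++d) c[d] /= S.n_beads;
  double s = 0;
  for (int i = 0; i < S.n_beads; ++i)
    for (int d = 0; d < 3; ++d) {
      const double dd = S.u[3 * i + d] - c[d];
      s += dd * dd;
    }
  return std::sqrt(s / S.n_beads);
}

// Langevin dynamics via velocity-Verlet. Friction -zeta*m*v plus Gaussian
// kicks of per-component variance 2*zeta*m*kT/dt enter the force once per
// step; zeta = 0 gives plain NVE (used by energy-conservation checks).
// store_frames: 0 = Rg/KE series only, 1 = bead frames, 2 = full frames.
// [[Rcpp::export]]
List cpp_run_md(NumericMatrix coords, int n_beads, IntegerVector mask,
                NumericVector eps, double L, double r0, double kfene,
                double rc_wca, double rc_att, double dt, double zeta,
                double temperature, int n_steps, int sample_every,
                int seed, int store_frames = 0, double skin = 0.5,
                bool draw_velocities = true) {
  System S = make_system(coords, n_beads, mask, eps, L, r0, kfene, rc_wca,
                         rc_att);
  Xoshiro rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 99991ULL);
  ZigNormal zig;
  const int n = S.n, n3 = 3 * n;
  std::vector<double> v(n3, 0.0), fv(n3, 0.0);
  if (draw_velocities && temperature > 0) {
    const double sv = std::sqrt(temperature);
    for (int k = 0; k < n3; ++k) v[k] = sv * zig.draw(rng);
  }
  NeighborList NL;
  NL.setup(S, skin);
  NL.build(S);

  const double noise_sd =
      (zeta > 0) ? std::sqrt(2.0 * zeta * temperature / dt) : 0.0;
  auto thermo_kick = [&](void) {
    if (zeta <= 0) return;
    double *f = fv.data();
    const double *vv = v.data();
    for (int k = 0; k < n3; ++k)
      f[k] += -zeta * vv[k] + noise_sd * zig.draw(rng);
  };

  EnergyAcc E0;
  if (!forces_cell(S, NL, fv, E0))
    stop("FENE bond %d at or beyond maximum extension in initial state",
         E0.bad_bond + 1);
  thermo_kick();

  const int n_samples = n_steps / sample_every;
  NumericVector rg(n_samples), ke(n_samples), pe(n_samples);
  IntegerVector steps(n_samples);
  List frames(store_frames > 0 ? n_samples : 0);
  int isamp = 0;
  bool aborted = false;
  int abort_step = -1;

  const double hdt = 0.5 * dt;
  for (int step = 1; step <= n_steps; ++step) {
    {
      double *vv = v.data(), *uu = S.u.data(), *ww = S.w.data();
      const double *f = fv.data();
      bool blown = false;
      for (int k = 0; k < n3; ++k) {
        vv[k] += hdt * f[k];
        const double mv = dt * vv[k];
        if (!(std::fabs(mv) < 0.5 * L)) blown = true;  // catches NaN too
        uu[k] += mv;
        double a = ww[k] + mv;
        if (a >= L) a -= L; else if (a < 0) a += L;
        ww[k] = a;
      }
      if (blown) {  // runaway forces: stop with the last stable samples
        aborted = true;
        abort_step = step;
        break;
      }
    }
    if (NL.stale(S)) NL.build(S);
    EnergyAcc E;
    if (!forces_cell(S, NL, fv, E)) {
      aborted = true;
      abort_step = step;
      break;
    }
    thermo_kick();
    {
      double *vv = v.data();
      const double *f = fv.data();
      for (int k = 0; k < n3; ++k) vv[k] += hdt * f[k];
    }
    if (step % sample_every == 0 && isamp < n_samples) {
      double kin = 0;
      for (int k = 0; k < n3; ++k) kin += v[k] * v[k];
      const double rgv = rg_beads(S);
      if (!std::isfinite(rgv) || !std::isfinite(kin)) {
        aborted = true;
        abort_step = step;
        break;
      }
      rg[isamp] = rgv;
      ke[isamp] = 0.5 * kin;
      pe[isamp] = E.fene + E.rep + E.att;
      steps[isamp] = step;
      if (store_frames > 0) {
        const int nn = (store_frames == 2) ? n : n_beads;
        NumericMatrix fr(nn, 3);
        for (int i = 0; i < nn; ++i) {
          fr(i, 0) = S.u[3 * i];
          fr(i, 1) = S.u[3 * i + 1];
          fr(i, 2) = S.u[3 * i + 2];
        }
        frames[isamp] = fr;
      }
      ++isamp;
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix final_pos(n, 3);
  for (int i = 0; i < n; ++i) {
    final_pos(i, 0) = S.u[3 * i];
    final_pos(i, 1) = S.u[3 * i + 1];
    final_pos(i, 2) = S.u[3 * i + 2];
  }
  if (isamp < n_samples) {
    rg = head(rg, isamp);
    ke = head(ke, isamp);
    pe = head(pe, isamp);
    steps = head(steps, isamp);
    if (store_frames > 0) frames = head(frames, isamp);
  }
  return List::create(
      _["rg"] = rg, _["kinetic"] = ke, _["potential"] = pe,
      _["steps"] = steps, _["frames"] = frames, _["final"] = final_pos,
      _["n_dof"] = 3 * n, _["aborted"] = aborted,
      _["abort_step"] = abort_step);
}

// Standard-normal draws from the engine's generator (distributional QA).
// [[Rcpp::export]]
NumericVector cpp_normal_draws(int n, int seed) {
  Xoshiro rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 5551ULL);
  ZigNormal zig;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = zig.draw(rng);
  return out;
}
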