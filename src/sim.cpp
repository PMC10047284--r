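// Langevin (overdamped) bead-spring engine for confined chromatin polymers
// with type-dependent truncated LJ attraction and dynamic harmonic bonds
// between H3K27me3 beads and a fixed spherical lamina shell.
//
// Units: lengths in sigma (bead diameter), energies in kBT, time in tau.
// Bead types: 0 = EU, 1 = PCH, 2 = H3K27me3.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>
#include <functional>
using namespace Rcpp;

namespace {

// xoshiro256++ seeded via splitmix64; own stream so a long run does not pay
// R's RNG call overhead per coordinate (~1e9 draws per production run).
struct FastRNG {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;
  explicit FastRNG(uint64_t seed) {
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
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // Marsaglia polar method
  inline double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    double m = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = v * m; have_spare = true;
    return u * m;
  }
};

// Uniform grid over the cube [-ext, ext]^3 for short-range neighbor search.
struct CellGrid {
  double ext, cs;
  int nc;            // cells per axis
  std::vector<int> head, nxt;
  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, double extent, double cell_size) {
    ext = extent; cs = cell_size;
    nc = std::max(1, (int)std::floor(2.0 * ext / cs));
    head.assign((size_t)nc * nc * nc, -1);
    nxt.assign(x.size(), -1);
    for (int i = 0; i < (int)x.size(); ++i) {
      int c = cell_of(x[i], y[i], z[i]);
      nxt[i] = head[c];
      head[c] = i;
    }
  }
  inline int clampc(int a) const { return a < 0 ? 0 : (a >= nc ? nc - 1 : a); }
  inline int cell_of(double x, double y, double z) const {
    int cx = clampc((int)std::floor((x + ext) / (2.0 * ext) * nc));
    int cy = clampc((int)std::floor((y + ext) / (2.0 * ext) * nc));
    int cz = clampc((int)std::floor((z + ext) / (2.0 * ext) * nc));
    return (cx * nc + cy) * nc + cz;
  }
};

struct Params {
  double eps_EE, eps_HH, eps_cross, cutoff;
  double k_backbone, r0_backbone;
  double K_lamina, bond_form, bond_break, bond_rest;
  double R, dt, gamma, kT, eps_wall, fmax;
  int registry_stride;
};

inline int cell_coord(double v, double ext, int nc) {
  int c = (int)std::floor((v + ext) / (2.0 * ext) * nc);
  return c < 0 ? 0 : (c >= nc ? nc - 1 : c);
}

inline double eps_pair(const Params& p, int ti, int tj) {
  if (ti == 0 && tj == 0) return p.eps_EE;
  if (ti != 0 && tj != 0) return p.eps_HH;   // PCH and H3K27me3 share eps_HH
  return p.eps_cross;
}

// truncated + energy-shifted LJ force magnitude / r (i.e., dU/dr * (-1/r))
inline double lj_force_over_r(double r2, double eps, double cutoff2) {
  if (r2 >= cutoff2 || eps <= 0.0) return 0.0;
  double inv2 = 1.0 / r2;
  double inv6 = inv2 * inv2 * inv2;
  // F/r = 24*eps*(2*inv12 - inv6)/r^2
  return 24.0 * eps * (2.0 * inv6 * inv6 - inv6) * inv2;
}

const double WCA_CUT2 = std::pow(2.0, 1.0 / 3.0); // (2^(1/6))^2

inline double wca_force_over_r(double r2, double eps) {
  if (r2 >= WCA_CUT2 || eps <= 0.0) return 0.0;
  return lj_force_over_r(r2, eps, WCA_CUT2 + 1e-12);
}

} // namespace

// [[Rcpp::export]]
double cpp_pair_energy(double r, double eps, double cutoff) {
  if (r > cutoff) return 0.0;
  double inv6 = std::pow(1.0 / r, 6.0);
  double u = 4.0 * eps * (inv6 * inv6 - inv6);
  double ic6 = std::pow(1.0 / cutoff, 6.0);
  double shift = 4.0 * eps * (ic6 * ic6 - ic6);
  return u - shift;
}

// Break bonds stretched beyond `brk`; bond every unbonded H3K27me3 bead to
// its nearest lamina bead within `form`. Brute force; used standalone and
// as the reference path. bond entries: 0 = none, else 1-based lamina index.
// [[Rcpp::export]]
IntegerVector cpp_update_bonds(NumericMatrix pos, LogicalVector is_h3k,
                               NumericMatrix lam, IntegerVector bond,
                               double form, double brk) {
  int n = pos.nrow(), m = lam.nrow();
  IntegerVector out = clone(bond);
  double form2 = form * form, brk2 = brk * brk;
  for (int i = 0; i < n; ++i) {
    if (!is_h3k[i]) { out[i] = 0; continue; }
    if (out[i] > 0) {
      int j = out[i] - 1;
      double dx = pos(i,0)-lam(j,0), dy = pos(i,1)-lam(j,1), dz = pos(i,2)-lam(j,2);
      if (dx*dx + dy*dy + dz*dz > brk2) out[i] = 0;
    }
    if (out[i] == 0) {
      double best = form2; int bj = -1;
      for (int j = 0; j < m; ++j) {
        double dx = pos(i,0)-lam(j,0), dy = pos(i,1)-lam(j,1), dz = pos(i,2)-lam(j,2);
        double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 <= best) { best = d2; bj = j; }
      }
      if (bj >= 0) out[i] = bj + 1;
    }
  }
  return out;
}

// Connected components of the contact graph (edge iff distance <= cutoff)
// via union-find over a cell grid.
// [[Rcpp::export]]
IntegerVector cpp_cluster_labels(NumericMatrix pos, double cutoff) {
  int n = pos.nrow();
  IntegerVector lab(n);
  if (n == 0) return lab;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  std::vector<double> x(n), y(n), z(n);
  double ext = 1.0;
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i,0); y[i] = pos(i,1); z[i] = pos(i,2);
    ext = std::max(ext, std::max(std::abs(x[i]), std::max(std::abs(y[i]), std::abs(z[i]))));
  }
  ext += 1e-6;
  CellGrid g;
  g.build(x, y, z, ext, std::max(cutoff, 2.0 * ext / 64.0));
  double c2 = cutoff * cutoff;
  int reach = (int)std::ceil(g.cs > 0 ? cutoff / g.cs : 1.0);
  for (int i = 0; i < n; ++i) {
    int cx = g.clampc((int)std::floor((x[i] + g.ext) / (2.0 * g.ext) * g.nc));
    int cy = g.clampc((int)std::floor((y[i] + g.ext) / (2.0 * g.ext) * g.nc));
    int cz = g.clampc((int)std::floor((z[i] + g.ext) / (2.0 * g.ext) * g.nc));
    for (int ax = std::max(0, cx - reach); ax <= std::min(g.nc - 1, cx + reach); ++ax)
      for (int ay = std::max(0, cy - reach); ay <= std::min(g.nc - 1, cy + reach); ++ay)
        for (int az = std::max(0, cz - reach); az <= std::min(g.nc - 1, cz + reach); ++az) {
          for (int j = g.head[((size_t)ax * g.nc + ay) * g.nc + az]; j >= 0; j = g.nxt[j]) {
            if (j <= i) continue;
            double dx = x[i]-x[j], dy = y[i]-y[j], dz = z[i]-z[j];
            if (dx*dx + dy*dy + dz*dz <= c2) {
              int ra = find(i), rb = find(j);
              if (ra != rb) parent[ra] = rb;
            }
          }
        }
  }
  // relabel components 1..k in order of first appearance
  std::vector<int> remap(n, 0);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    if (remap[r] == 0) remap[r] = ++k;
    lab[i] = remap[r];
  }
  return lab;
}

// Core integrator. Runs `steps` overdamped Langevin steps and samples every
// `stride` steps (the initial state is frame 0). Returns sampled positions,
// per-frame bond registries and the final state.
// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix pos0, IntegerVector type,
                      IntegerVector chain_id, NumericMatrix lam,
                      IntegerVector bond0, List par,
                      int steps, int stride, double seed,
                      bool sample_frames) {
  int n = pos0.nrow();
  int m = lam.nrow();
  Params p;
  p.eps_EE = as<double>(par["eps_EE"]);
  p.eps_HH = as<double>(par["eps_HH"]);
  p.eps_cross = as<double>(par["eps_cross"]);
  p.cutoff = as<double>(par["lj_cutoff"]);
  p.k_backbone = as<double>(par["backbone_k"]);
  p.r0_backbone = as<double>(par["backbone_rest"]);
  p.K_lamina = as<double>(par["lamina_bond_K"]);
  p.bond_form = as<double>(par["bond_form_dist"]);
  p.bond_break = as<double>(par["bond_break_dist"]);
  p.bond_rest = as<double>(par["bond_rest"]);
  p.R = as<double>(par["radius"]);
  p.dt = as<double>(par["timestep"]);
  p.gamma = as<double>(par["damping"]);
  p.kT = as<double>(par["temperature"]);
  p.eps_wall = as<double>(par["eps_wall"]);
  p.fmax = as<double>(par["force_cap"]);
  p.registry_stride = as<int>(par["registry_stride"]);

  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) { x[i] = pos0(i,0); y[i] = pos0(i,1); z[i] = pos0(i,2); }
  std::vector<double> lx(m), ly(m), lz(m);
  for (int j = 0; j < m; ++j) { lx[j] = lam(j,0); ly[j] = lam(j,1); lz[j] = lam(j,2); }
  std::vector<int> bond(n);
  for (int i = 0; i < n; ++i) bond[i] = bond0[i];

  FastRNG rng((uint64_t)seed);
  double cutoff2 = p.cutoff * p.cutoff;
  double noise_amp = std::sqrt(2.0 * p.kT * p.dt / p.gamma);
  double mob = p.dt / p.gamma;
  double ext = p.R + 1.0;

  // lamina grid is static; reach for bond formation / steric wall beads
  double lam_reach = std::max(p.bond_form, std::pow(2.0, 1.0/6.0));
  CellGrid lgrid;
  bool have_lam = m > 0;
  if (have_lam) lgrid.build(lx, ly, lz, ext, std::max(lam_reach, 0.5));
  int lreach_cells = have_lam ? (int)std::ceil(lam_reach / lgrid.cs) : 0;

  bool any_lj = p.eps_EE > 0.0 || p.eps_HH > 0.0 || p.eps_cross > 0.0;

  // sorted cell list machinery for the LJ pass
  double cell_size = std::max(p.cutoff / 2.0, 0.6);
  int ncell = std::max(1, std::min(256, (int)std::floor(2.0 * ext / cell_size)));
  size_t ncells_tot = (size_t)ncell * ncell * ncell;
  std::vector<int> cstart, ccursor, cellof, order, ts;
  std::vector<double> xs, ys, zs, gx, gy, gz;
  if (any_lj && n > 1) {
    cstart.assign(ncells_tot + 1, 0); ccursor.assign(ncells_tot, 0);
    cellof.resize(n); order.resize(n); ts.resize(n);
    xs.resize(n); ys.resize(n); zs.resize(n);
    gx.resize(n); gy.resize(n); gz.resize(n);
  }
  int reach = std::max(1, (int)std::ceil(p.cutoff * ncell / (2.0 * ext)));
  std::vector<int> sx, sy, sz;
  for (int a = -reach; a <= reach; ++a)
    for (int b = -reach; b <= reach; ++b)
      for (int c = -reach; c <= reach; ++c) {
        bool half = a > 0 || (a == 0 && b > 0) || (a == 0 && b == 0 && c >= 0);
        if (!half) continue;
        // prune stencil cells that can never be within the cutoff
        double md = 0.0, cs_ = 2.0 * ext / ncell;
        for (int d : {a, b, c})
          md += std::pow(cs_ * std::max(0, std::abs(d) - 1), 2);
        if (md > p.cutoff * p.cutoff) continue;
        sx.push_back(a); sy.push_back(b); sz.push_back(c);
      }
  int n_stencil = (int)sx.size();

  auto update_registry = [&]() {
    double form2 = p.bond_form * p.bond_form, brk2 = p.bond_break * p.bond_break;
    for (int i = 0; i < n; ++i) {
      if (type[i] != 2) continue;
      if (bond[i] > 0) {
        int j = bond[i] - 1;
        double dx = x[i]-lx[j], dy = y[i]-ly[j], dz = z[i]-lz[j];
        if (dx*dx + dy*dy + dz*dz > brk2) bond[i] = 0;
      }
      if (bond[i] == 0 && have_lam) {
        double ri = std::sqrt(x[i]*x[i] + y[i]*y[i] + z[i]*z[i]);
        if (p.R - ri > p.bond_form + 0.5) continue; // far from the shell
        double best = form2; int bj = -1;
        int cx = lgrid.clampc((int)std::floor((x[i]+lgrid.ext)/(2.0*lgrid.ext)*lgrid.nc));
        int cy = lgrid.clampc((int)std::floor((y[i]+lgrid.ext)/(2.0*lgrid.ext)*lgrid.nc));
        int cz = lgrid.clampc((int)std::floor((z[i]+lgrid.ext)/(2.0*lgrid.ext)*lgrid.nc));
        int rc = lreach_cells;
        for (int ax = std::max(0,cx-rc); ax <= std::min(lgrid.nc-1,cx+rc); ++ax)
          for (int ay = std::max(0,cy-rc); ay <= std::min(lgrid.nc-1,cy+rc); ++ay)
            for (int az = std::max(0,cz-rc); az <= std::min(lgrid.nc-1,cz+rc); ++az)
              for (int j = lgrid.head[((size_t)ax*lgrid.nc+ay)*lgrid.nc+az]; j >= 0; j = lgrid.nxt[j]) {
                double dx = x[i]-lx[j], dy = y[i]-ly[j], dz = z[i]-lz[j];
                double d2 = dx*dx + dy*dy + dz*dz;
                if (d2 <= best) { best = d2; bj = j; }
              }
        if (bj >= 0) bond[i] = bj + 1;
      }
    }
  };

  int n_frames = sample_frames ? steps / stride + 1 : 1;
  List frames(n_frames), bonds_out(n_frames);
  int frame_i = 0;
  auto record = [&]() {
    NumericMatrix fp(n, 3);
    IntegerVector fb(n);
    for (int i = 0; i < n; ++i) {
      fp(i,0) = x[i]; fp(i,1) = y[i]; fp(i,2) = z[i];
      fb[i] = bond[i];
    }
    frames[frame_i] = fp;
    bonds_out[frame_i] = fb;
    ++frame_i;
  };
  update_registry();
  if (sample_frames) record();

  for (int s = 1; s <= steps; ++s) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);

    // backbone springs (skip chromosome boundaries)
    if (p.k_backbone > 0.0) {
      for (int i = 0; i + 1 < n; ++i) {
        if (chain_id[i] != chain_id[i + 1]) continue;
        double dx = x[i+1]-x[i], dy = y[i+1]-y[i], dz = z[i+1]-z[i];
        double r = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (r < 1e-12) continue;
        double f = p.k_backbone * (r - p.r0_backbone) / r;
        fx[i] += f*dx; fy[i] += f*dy; fz[i] += f*dz;
        fx[i+1] -= f*dx; fy[i+1] -= f*dy; fz[i+1] -= f*dz;
      }
    }

    // pairwise LJ via a spatially sorted cell list (half stencil)
    if (any_lj && n > 1) {
      int nc = ncell;
      size_t ncells = (size_t)nc * nc * nc;
      // bin
      std::fill(cstart.begin(), cstart.end(), 0);
      for (int i = 0; i < n; ++i) {
        int cx = cell_coord(x[i], ext, nc);
        int cy = cell_coord(y[i], ext, nc);
        int cz = cell_coord(z[i], ext, nc);
        cellof[i] = (cx * nc + cy) * nc + cz;
        ++cstart[cellof[i] + 1];
      }
      for (size_t c = 0; c < ncells; ++c) cstart[c + 1] += cstart[c];
      {
        std::vector<int>& fill = ccursor;
        std::copy(cstart.begin(), cstart.end() - 1, fill.begin());
        for (int i = 0; i < n; ++i) {
          int slot = fill[cellof[i]]++;
          order[slot] = i;
          xs[slot] = x[i]; ys[slot] = y[i]; zs[slot] = z[i];
          ts[slot] = type[i];
          gx[slot] = 0.0; gy[slot] = 0.0; gz[slot] = 0.0;
        }
      }
      for (int cx = 0; cx < nc; ++cx)
        for (int cy = 0; cy < nc; ++cy)
          for (int cz = 0; cz < nc; ++cz) {
            int c = (cx * nc + cy) * nc + cz;
            int a0 = cstart[c], a1 = cstart[c + 1];
            if (a0 == a1) continue;
            for (int s = 0; s < n_stencil; ++s) {
              int dx_ = sx[s], dy_ = sy[s], dz_ = sz[s];
              int ex_ = cx + dx_, ey_ = cy + dy_, ez_ = cz + dz_;
              if (ex_ < 0 || ex_ >= nc || ey_ < 0 || ey_ >= nc ||
                  ez_ < 0 || ez_ >= nc) continue;
              int d = (ex_ * nc + ey_) * nc + ez_;
              int b0 = cstart[d], b1 = cstart[d + 1];
              if (b0 == b1) continue;
              bool same = d == c;
              for (int a = a0; a < a1; ++a) {
                double xa = xs[a], ya = ys[a], za = zs[a];
                int ta = ts[a];
                double ax_ = 0.0, ay_ = 0.0, az_ = 0.0;
                int bstart = same ? a + 1 : b0;
                for (int b = bstart; b < b1; ++b) {
                  double ddx = xa - xs[b], ddy = ya - ys[b], ddz = za - zs[b];
                  double r2 = ddx*ddx + ddy*ddy + ddz*ddz;
                  if (r2 >= cutoff2) continue;
                  double e = eps_pair(p, ta, ts[b]);
                  double fr = lj_force_over_r(r2, e, cutoff2);
                  if (fr != 0.0) {
                    ax_ += fr*ddx; ay_ += fr*ddy; az_ += fr*ddz;
                    gx[b] -= fr*ddx; gy[b] -= fr*ddy; gz[b] -= fr*ddz;
                  }
                }
                gx[a] += ax_; gy[a] += ay_; gz[a] += az_;
              }
            }
          }
      for (int s = 0; s < n; ++s) {
        int i = order[s];
        fx[i] += gx[s]; fy[i] += gy[s]; fz[i] += gz[s];
      }
    }

    // lamina sterics (repulsive WCA from every lamina bead) + wall + bonds
    for (int i = 0; i < n; ++i) {
      double ri = std::sqrt(x[i]*x[i] + y[i]*y[i] + z[i]*z[i]);
      if (have_lam && p.eps_wall > 0.0 && p.R - ri < lam_reach + 0.5) {
        int cx = lgrid.clampc((int)std::floor((x[i]+lgrid.ext)/(2.0*lgrid.ext)*lgrid.nc));
        int cy = lgrid.clampc((int)std::floor((y[i]+lgrid.ext)/(2.0*lgrid.ext)*lgrid.nc));
        int cz = lgrid.clampc((int)std::floor((z[i]+lgrid.ext)/(2.0*lgrid.ext)*lgrid.nc));
        for (int ax = std::max(0,cx-lreach_cells); ax <= std::min(lgrid.nc-1,cx+lreach_cells); ++ax)
          for (int ay = std::max(0,cy-lreach_cells); ay <= std::min(lgrid.nc-1,cy+lreach_cells); ++ay)
            for (int az = std::max(0,cz-lreach_cells); az <= std::min(lgrid.nc-1,cz+lreach_cells); ++az)
              for (int j = lgrid.head[((size_t)ax*lgrid.nc+ay)*lgrid.nc+az]; j >= 0; j = lgrid.nxt[j]) {
                if (bond[i] == j + 1) continue; // bonded pair handled below
                double dx = x[i]-lx[j], dy = y[i]-ly[j], dz = z[i]-lz[j];
                double r2 = dx*dx + dy*dy + dz*dz;
                double fr = wca_force_over_r(r2, p.eps_wall);
                if (fr != 0.0) { fx[i] += fr*dx; fy[i] += fr*dy; fz[i] += fr*dz; }
              }
      }
      // smooth repulsive wall just inside the confining sphere
      if (p.eps_wall > 0.0) {
        double d = p.R - ri;
        if (d < std::pow(2.0, 1.0/6.0) && ri > 1e-9) {
          double dd = std::max(d, 0.05);
          double fr = wca_force_over_r(dd * dd, p.eps_wall); // (dU/dd)/d
          double f = fr * dd;                                 // magnitude, inward
          fx[i] -= f * x[i]/ri; fy[i] -= f * y[i]/ri; fz[i] -= f * z[i]/ri;
        }
      }
      // active lamina bond
      if (bond[i] > 0 && p.K_lamina > 0.0) {
        int j = bond[i] - 1;
        double dx = lx[j]-x[i], dy = ly[j]-y[i], dz = lz[j]-z[i];
        double r = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (r > 1e-12) {
          double f = p.K_lamina * (r - p.bond_rest) / r;
          fx[i] += f*dx; fy[i] += f*dy; fz[i] += f*dz;
        }
      }
    }

    // cap net force, integrate, reflect
    for (int i = 0; i < n; ++i) {
      double f2 = fx[i]*fx[i] + fy[i]*fy[i] + fz[i]*fz[i];
      if (p.fmax > 0.0 && f2 > p.fmax * p.fmax) {
        double sc = p.fmax / std::sqrt(f2);
        fx[i] *= sc; fy[i] *= sc; fz[i] *= sc;
      }
      x[i] += mob * fx[i];
      y[i] += mob * fy[i];
      z[i] += mob * fz[i];
      if (p.kT > 0.0) {
        x[i] += noise_amp * rng.norm();
        y[i] += noise_amp * rng.norm();
        z[i] += noise_amp * rng.norm();
      }
      double r = std::sqrt(x[i]*x[i] + y[i]*y[i] + z[i]*z[i]);
      if (r > p.R) {
        double rn = 2.0 * p.R - r;       // radial reflection
        if (rn < 0.0) rn = 0.5 * p.R;    // pathological kick: recenter
        double sc = rn / r;
        x[i] *= sc; y[i] *= sc; z[i] *= sc;
      }
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]) || !std::isfinite(z[i]))
        stop("simulation diverged: non-finite coordinate for bead %d at step %d", i + 1, s);
    }

    if (p.registry_stride > 0 && s % p.registry_stride == 0) update_registry();
    if (sample_frames && s % stride == 0) record();
  }

  if (!sample_frames) record();
  NumericMatrix final_pos(n, 3);
  IntegerVector final_bond(n);
  for (int i = 0; i < n; ++i) {
    final_pos(i,0) = x[i]; final_pos(i,1) = y[i]; final_pos(i,2) = z[i];
    final_bond[i] = bond[i];
  }
  return List::create(_["frames"] = frames, _["bonds"] = bonds_out,
                      _["final_positions"] = final_pos,
                      _["final_bonds"] = final_bond);
}
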