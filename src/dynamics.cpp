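// Charged-particle dynamics surrogate for the Coulomb explosion.
//
// Forces: pairwise Coulomb between charged atoms (k q_i q_j / r^2, with the
// separation clamped below r_soft), harmonic bond restraints that sever
// permanently once stretched past break_factor * r0, and a short-range r^-12
// repulsion (cell list, bonded pairs excluded).  Velocity-Verlet integration
// from rest; charges are piecewise constant between 0.5 fs frames.
// Units: nm, fs, eV; masses in eV fs^2 nm^-2.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_set>
#include <cstdint>

using namespace Rcpp;

struct Params {
  double k_coulomb;   // eV nm
  double r_soft;      // nm, Coulomb clamp radius
  double k_bond;      // eV nm^-2
  double break_factor;
  double rep_A;       // eV nm^12
  double rep_cutoff;  // nm
};

struct Energy { double coulomb = 0, bond = 0, rep = 0; };

static inline std::int64_t pair_key(int i, int j, int m) {
  if (i > j) std::swap(i, j);
  return static_cast<std::int64_t>(i) * m + j;
}

// simple uniform cell list over the current bounding box; grid dimensions
// are capped so an exploded (tens of nm) cloud cannot blow up the cell count
// — cells only ever grow past the cutoff, which keeps the search correct
class CellList {
public:
  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, double cell) {
    n_ = static_cast<int>(x.size());
    x0_ = y0_ = z0_ = 1e30;
    for (int i = 0; i < n_; ++i) {
      x0_ = std::min(x0_, x[i]); y0_ = std::min(y0_, y[i]);
      z0_ = std::min(z0_, z[i]);
    }
    double x1 = -1e30, y1 = -1e30, z1 = -1e30;
    for (int i = 0; i < n_; ++i) {
      x1 = std::max(x1, x[i]); y1 = std::max(y1, y[i]); z1 = std::max(z1, z[i]);
    }
    const int max_dim = 48;
    double ext = std::max({x1 - x0_, y1 - y0_, z1 - z0_, cell});
    cell_ = std::max(cell, ext / max_dim);
    nx_ = std::min(max_dim, std::max(1, static_cast<int>((x1 - x0_) / cell_) + 1));
    ny_ = std::min(max_dim, std::max(1, static_cast<int>((y1 - y0_) / cell_) + 1));
    nz_ = std::min(max_dim, std::max(1, static_cast<int>((z1 - z0_) / cell_) + 1));
    head_.assign(static_cast<size_t>(nx_) * ny_ * nz_, -1);
    next_.assign(n_, -1);
    for (int i = 0; i < n_; ++i) {
      int c = idx(x[i], y[i], z[i]);
      next_[i] = head_[c];
      head_[c] = i;
    }
  }
  int idx(double x, double y, double z) const {
    int ix = std::min(nx_ - 1, std::max(0, static_cast<int>((x - x0_) / cell_)));
    int iy = std::min(ny_ - 1, std::max(0, static_cast<int>((y - y0_) / cell_)));
    int iz = std::min(nz_ - 1, std::max(0, static_cast<int>((z - z0_) / cell_)));
    return (iz * ny_ + iy) * nx_ + ix;
  }
  template <class F>
  void for_neighbours(const std::vector<double>& x, const std::vector<double>& y,
                      const std::vector<double>& z, F f) const {
    for (int i = 0; i < n_; ++i) {
      int ix = std::min(nx_ - 1, std::max(0, static_cast<int>((x[i] - x0_) / cell_)));
      int iy = std::min(ny_ - 1, std::max(0, static_cast<int>((y[i] - y0_) / cell_)));
      int iz = std::min(nz_ - 1, std::max(0, static_cast<int>((z[i] - z0_) / cell_)));
      for (int dz = -1; dz <= 1; ++dz) {
        int jz = iz + dz; if (jz < 0 || jz >= nz_) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int jy = iy + dy; if (jy < 0 || jy >= ny_) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int jx = ix + dx; if (jx < 0 || jx >= nx_) continue;
            for (int j = head_[(static_cast<size_t>(jz) * ny_ + jy) * nx_ + jx];
                 j >= 0; j = next_[j]) {
              if (j > i) f(i, j);
            }
          }
        }
      }
    }
  }
private:
  int n_ = 0, nx_ = 1, ny_ = 1, nz_ = 1;
  double cell_ = 1, x0_ = 0, y0_ = 0, z0_ = 0;
  std::vector<int> head_, next_;
};

// accumulate all forces; returns potential energy terms
static Energy forces(const std::vector<double>& x, const std::vector<double>& y,
                     const std::vector<double>& z,
                     const std::vector<double>& q,
                     const std::vector<int>& charged,
                     const std::vector<int>& bond_i,
                     const std::vector<int>& bond_j,
                     const std::vector<double>& bond_r0,
                     std::vector<char>& bond_alive,
                     const std::unordered_set<std::int64_t>& bonded,
                     const Params& par,
                     std::vector<double>& fx, std::vector<double>& fy,
                     std::vector<double>& fz, bool want_energy) {
  const int m = static_cast<int>(x.size());
  Energy en;
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);

  // Coulomb between charged atoms, clamped below r_soft; charged atoms are
  // packed into contiguous scratch arrays so the pair loop streams linearly
  const double rs2 = par.r_soft * par.r_soft;
  const int nc = static_cast<int>(charged.size());
  static thread_local std::vector<double> cx, cy, cz, cq, cfx, cfy, cfz;
  cx.resize(nc); cy.resize(nc); cz.resize(nc); cq.resize(nc);
  cfx.assign(nc, 0.0); cfy.assign(nc, 0.0); cfz.assign(nc, 0.0);
  for (int a = 0; a < nc; ++a) {
    const int i = charged[a];
    cx[a] = x[i]; cy[a] = y[i]; cz[a] = z[i]; cq[a] = q[i];
  }
  for (int a = 0; a < nc; ++a) {
    const double xi = cx[a], yi = cy[a], zi = cz[a];
    const double qi = par.k_coulomb * cq[a];
    double fxi = 0, fyi = 0, fzi = 0;
    for (int b = a + 1; b < nc; ++b) {
      double dx = xi - cx[b], dy = yi - cy[b], dz = zi - cz[b];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < rs2) r2 = rs2;
      const double inv_r = 1.0 / std::sqrt(r2);
      const double c = qi * cq[b] * inv_r * inv_r * inv_r;
      fxi += c * dx; fyi += c * dy; fzi += c * dz;
      cfx[b] -= c * dx; cfy[b] -= c * dy; cfz[b] -= c * dz;
      if (want_energy) en.coulomb += qi * cq[b] * inv_r;
    }
    cfx[a] += fxi; cfy[a] += fyi; cfz[a] += fzi;
  }
  for (int a = 0; a < nc; ++a) {
    const int i = charged[a];
    fx[i] += cfx[a]; fy[i] += cfy[a]; fz[i] += cfz[a];
  }

  // bonds (harmonic, breakable)
  for (size_t b = 0; b < bond_i.size(); ++b) {
    if (!bond_alive[b]) continue;
    const int i = bond_i[b], j = bond_j[b];
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r > par.break_factor * bond_r0[b]) { bond_alive[b] = 0; continue; }
    double c = -par.k_bond * (r - bond_r0[b]) / std::max(r, 1e-12);
    fx[i] += c * dx; fy[i] += c * dy; fz[i] += c * dz;
    fx[j] -= c * dx; fy[j] -= c * dy; fz[j] -= c * dz;
    if (want_energy) en.bond += 0.5 * par.k_bond *
      (r - bond_r0[b]) * (r - bond_r0[b]);
  }

  // r^-12 repulsion via cell list, bonded pairs excluded
  if (par.rep_A > 0 && m > 1) {
    CellList cl;
    cl.build(x, y, z, par.rep_cutoff);
    const double rc2 = par.rep_cutoff * par.rep_cutoff;
    cl.for_neighbours(x, y, z, [&](int i, int j) {
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2 || r2 < 1e-12) return;
      if (!bonded.empty() &&
          bonded.count(pair_key(i, j, m))) return;
      double inv_r2 = 1.0 / r2;
      double inv_r12 = inv_r2 * inv_r2 * inv_r2;
      inv_r12 *= inv_r12;
      double c = 12.0 * par.rep_A * inv_r12 * inv_r2;
      fx[i] += c * dx; fy[i] += c * dy; fz[i] += c * dz;
      fx[j] -= c * dx; fy[j] -= c * dy; fz[j] -= c * dz;
      if (want_energy) en.rep += par.rep_A * inv_r12;
    });
  }
  return en;
}

static Params params_from_list(List p) {
  Params par;
  par.k_coulomb = as<double>(p["k_coulomb"]);
  par.r_soft = as<double>(p["r_soft"]);
  par.k_bond = as<double>(p["k_bond"]);
  par.break_factor = as<double>(p["break_factor"]);
  par.rep_A = as<double>(p["rep_A"]);
  par.rep_cutoff = as<double>(p["rep_cutoff"]);
  return par;
}

// [[Rcpp::export(name = ".compute_forces_cpp")]]
List compute_forces_cpp(NumericMatrix pos, NumericVector charges,
                        IntegerMatrix bonds, NumericVector bond_r0,
                        List par_list) {
  const int m = pos.nrow();
  if (pos.ncol() != 3) stop("positions must be M x 3");
  for (int i = 0; i < m; ++i)
    for (int c = 0; c < 3; ++c)
      if (!std::isfinite(pos(i, c))) stop("non-finite position at atom %d", i + 1);
  Params par = params_from_list(par_list);
  std::vector<double> x(m), y(m), z(m), q(m);
  for (int i = 0; i < m; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); q[i] = charges[i];
  }
  std::vector<int> charged;
  for (int i = 0; i < m; ++i) if (q[i] != 0) charged.push_back(i);
  std::vector<int> bi, bj;
  std::vector<double> br0;
  std::unordered_set<std::int64_t> bonded;
  for (int b = 0; b < bonds.nrow(); ++b) {
    bi.push_back(bonds(b, 0) - 1);
    bj.push_back(bonds(b, 1) - 1);
    br0.push_back(bond_r0[b]);
    bonded.insert(pair_key(bi.back(), bj.back(), m));
  }
  std::vector<char> alive(bi.size(), 1);
  std::vector<double> fx(m), fy(m), fz(m);
  Energy en = forces(x, y, z, q, charged, bi, bj, br0, alive, bonded, par,
                     fx, fy, fz, true);
  NumericMatrix f(m, 3);
  for (int i = 0; i < m; ++i) { f(i, 0) = fx[i]; f(i, 1) = fy[i]; f(i, 2) = fz[i]; }
  return List::create(_["forces"] = f,
                      _["energy"] = NumericVector::create(
                        _["coulomb"] = en.coulomb, _["bond"] = en.bond,
                        _["repulsion"] = en.rep));
}

// [[Rcpp::export(name = ".explode_cpp")]]
List explode_cpp(NumericMatrix pos0, NumericVector mass_ev,
                 IntegerMatrix charge_frames, NumericVector frame_times,
                 double dt, IntegerMatrix bonds, NumericVector bond_r0,
                 List par_list) {
  const int m = pos0.nrow();
  const int nf = frame_times.size();
  if (charge_frames.nrow() != m || charge_frames.ncol() != nf)
    stop("charge matrix must be M x n_frames");
  Params par = params_from_list(par_list);

  std::vector<double> x(m), y(m), z(m), vx(m, 0), vy(m, 0), vz(m, 0), q(m, 0);
  for (int i = 0; i < m; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
    if (!std::isfinite(x[i] + y[i] + z[i])) stop("non-finite initial position");
  }
  std::vector<int> bi, bj;
  std::vector<double> br0;
  std::unordered_set<std::int64_t> bonded;
  for (int b = 0; b < bonds.nrow(); ++b) {
    bi.push_back(bonds(b, 0) - 1);
    bj.push_back(bonds(b, 1) - 1);
    br0.push_back(bond_r0[b]);
    bonded.insert(pair_key(bi.back(), bj.back(), m));
  }
  std::vector<char> alive(bi.size(), 1);
  std::vector<double> fx(m, 0), fy(m, 0), fz(m, 0);

  NumericVector traj(static_cast<R_xlen_t>(m) * 3 * nf);
  NumericMatrix energy(nf, 4);  // kinetic, coulomb, bond, repulsion
  colnames(energy) = CharacterVector::create("kinetic", "coulomb", "bond",
                                             "repulsion");

  std::vector<int> charged;
  auto set_charges = [&](int f) {
    charged.clear();
    for (int i = 0; i < m; ++i) {
      q[i] = charge_frames(i, f);
      if (q[i] != 0) charged.push_back(i);
    }
  };
  auto record = [&](int f, const Energy& en) {
    double ke = 0;
    for (int i = 0; i < m; ++i)
      ke += 0.5 * mass_ev[i] * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    energy(f, 0) = ke; energy(f, 1) = en.coulomb;
    energy(f, 2) = en.bond; energy(f, 3) = en.rep;
    R_xlen_t off = static_cast<R_xlen_t>(f) * m * 3;
    for (int i = 0; i < m; ++i) {
      traj[off + i] = x[i];
      traj[off + m + i] = y[i];
      traj[off + 2 * m + i] = z[i];
    }
  };

  set_charges(0);
  Energy en = forces(x, y, z, q, charged, bi, bj, br0, alive, bonded, par,
                     fx, fy, fz, true);
  record(0, en);

  const double max_step = 1.0;  // nm; larger single-step moves abort
  for (int f = 0; f + 1 < nf; ++f) {
    set_charges(f);  // charges constant over [t_f, t_{f+1})
    if (f > 0)       // refresh forces for the new charge state
      forces(x, y, z, q, charged, bi, bj, br0, alive, bonded, par,
             fx, fy, fz, false);
    double span = frame_times[f + 1] - frame_times[f];
    int nsub = std::max(1, static_cast<int>(std::lround(span / dt)));
    double h = span / nsub;
    for (int s = 0; s < nsub; ++s) {
      bool last = (s == nsub - 1);
      for (int i = 0; i < m; ++i) {
        const double im = h / mass_ev[i];
        vx[i] += 0.5 * im * fx[i];
        vy[i] += 0.5 * im * fy[i];
        vz[i] += 0.5 * im * fz[i];
        const double ddx = h * vx[i], ddy = h * vy[i], ddz = h * vz[i];
        if (ddx * ddx + ddy * ddy + ddz * ddz > max_step * max_step)
          stop("integrator step moved an atom more than 1 nm; "
               "use a smaller integration step");
        x[i] += ddx; y[i] += ddy; z[i] += ddz;
      }
      en = forces(x, y, z, q, charged, bi, bj, br0, alive, bonded, par,
                  fx, fy, fz, last);
      for (int i = 0; i < m; ++i) {
        const double im = h / mass_ev[i];
        vx[i] += 0.5 * im * fx[i];
        vy[i] += 0.5 * im * fy[i];
        vz[i] += 0.5 * im * fz[i];
      }
    }
    record(f + 1, en);
  }

  traj.attr("dim") = IntegerVector::create(m, 3, nf);
  NumericMatrix vel(m, 3);
  for (int i = 0; i < m; ++i) { vel(i, 0) = vx[i]; vel(i, 1) = vy[i]; vel(i, 2) = vz[i]; }
  return List::create(_["positions"] = traj, _["energy"] = energy,
                      _["final_velocities"] = vel,
                      _["bonds_alive"] = LogicalVector(alive.begin(), alive.end()));
}
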