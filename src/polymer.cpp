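#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coarse-grained polymer engine for the 10 nm chromatin fibre.
//
// Units: length nm, energy kBT, bead mass 1; time is in reduced units (the
// model targets conformational equilibrium, not real-time kinetics).
//
// Force field:
//   backbone: U = 1/2 k_bond (r - r0)^2 between chain neighbours,
//             k_bond = kBT / wiggle^2 (wiggle = RMS bond-length fluctuation)
//   stiffness: U = k_ang (1 - cos theta) per internal bead, theta the angle
//             between consecutive bond vectors (0 for a straight fibre)
//   soft-core repulsion: U = E (1 - (r/rc)^2)^2 for r < rc, else 0.
//             Finite barrier E at full overlap permits strand passage
//             (topoisomerase II-like) for chromatin-chromatin pairs; the
//             kinetochore barrier is set high enough to be impassable.
//   LE bonds: harmonic, replayed per block from the 1D bond trace.
//   tethers:  harmonic wells pinning listed beads to reference coordinates.
//
// Integrator: fixed-step BAOAB Langevin; friction = 0 reduces it to velocity
// Verlet (used for energy-conservation checks). All randomness comes from
// R's RNG stream.

struct CellList {
  double rc, x0, y0, z0;
  int nx, ny, nz;
  std::vector<int> head, nxt;
  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, int n, double rc_) {
    rc = rc_;
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0],
           zmin = z[0], zmax = z[0];
    for (int i = 1; i < n; ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
      zmin = std::min(zmin, z[i]); zmax = std::max(zmax, z[i]);
    }
    x0 = xmin; y0 = ymin; z0 = zmin;
    nx = std::max(1, (int)((xmax - xmin) / rc) + 1);
    ny = std::max(1, (int)((ymax - ymin) / rc) + 1);
    nz = std::max(1, (int)((zmax - zmin) / rc) + 1);
    head.assign((size_t)nx * ny * nz, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int c = cell_of(x[i], y[i], z[i]);
      nxt[i] = head[c];
      head[c] = i;
    }
  }
  inline int cell_of(double xi, double yi, double zi) const {
    int cx = std::min(nx - 1, (int)((xi - x0) / rc));
    int cy = std::min(ny - 1, (int)((yi - y0) / rc));
    int cz = std::min(nz - 1, (int)((zi - z0) / rc));
    return (cz * ny + cy) * nx + cx;
  }
};

struct FF {
  int n, n_chrom;
  double k_bond, bond_r0, k_ang;
  double rep_e_cc, rep_e_kin, rep_rc;
  double le_k, le_r0;
  double tether_k;
  std::vector<int> tether_idx;
  std::vector<double> tref_x, tref_y, tref_z;
  std::vector<int> le_a, le_b; // current LE bonds (0-based)
};

// returns potential energy; accumulates forces into fx/fy/fz (zeroed here)
static double compute_forces(const std::vector<double>& x,
                             const std::vector<double>& y,
                             const std::vector<double>& z,
                             std::vector<double>& fx, std::vector<double>& fy,
                             std::vector<double>& fz, const FF& ff,
                             CellList& cl) {
  const int n = ff.n, nc = ff.n_chrom;
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  double U = 0.0;

  // backbone bonds along the chromatin chain
  for (int i = 0; i + 1 < nc; ++i) {
    double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i], dz = z[i + 1] - z[i];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) continue;
    double dr = r - ff.bond_r0;
    U += 0.5 * ff.k_bond * dr * dr;
    double fmag = -ff.k_bond * dr / r;
    fx[i] -= fmag * dx; fy[i] -= fmag * dy; fz[i] -= fmag * dz;
    fx[i + 1] += fmag * dx; fy[i + 1] += fmag * dy; fz[i + 1] += fmag * dz;
  }

  // angular stiffness on internal chromatin beads
  if (ff.k_ang > 0) {
    for (int i = 1; i + 1 < nc; ++i) {
      double ax = x[i] - x[i - 1], ay = y[i] - y[i - 1], az = z[i] - z[i - 1];
      double bx = x[i + 1] - x[i], by = y[i + 1] - y[i], bz = z[i + 1] - z[i];
      double la = std::sqrt(ax * ax + ay * ay + az * az);
      double lb = std::sqrt(bx * bx + by * by + bz * bz);
      if (la < 1e-12 || lb < 1e-12) continue;
      double dot = ax * bx + ay * by + az * bz;
      double ct = dot / (la * lb);
      U += ff.k_ang * (1.0 - ct);
      // grad of cos(theta): d/da = (b/|b| - ct a/|a|)/|a|, d/db analogous
      double gax = (bx / lb - ct * ax / la) / la;
      double gay = (by / lb - ct * ay / la) / la;
      double gaz = (bz / lb - ct * az / la) / la;
      double gbx = (ax / la - ct * bx / lb) / lb;
      double gby = (ay / la - ct * by / lb) / lb;
      double gbz = (az / la - ct * bz / lb) / lb;
      // F = +k_ang * grad(cos theta) at each bead
      fx[i - 1] -= ff.k_ang * gax; fy[i - 1] -= ff.k_ang * gay; fz[i - 1] -= ff.k_ang * gaz;
      fx[i] += ff.k_ang * (gax - gbx); fy[i] += ff.k_ang * (gay - gby); fz[i] += ff.k_ang * (gaz - gbz);
      fx[i + 1] += ff.k_ang * gbx; fy[i + 1] += ff.k_ang * gby; fz[i + 1] += ff.k_ang * gbz;
    }
  }

  // soft-core repulsion via cell list, half-neighbourhood iteration: each
  // unordered cell pair is visited once (kinetochore-kinetochore skipped)
  const double rc = ff.rep_rc, rc2 = rc * rc;
  cl.build(x, y, z, n, rc);
  static const int OFF[14][3] = {
    {0, 0, 0},  {1, 0, 0},  {-1, 1, 0}, {0, 1, 0},  {1, 1, 0},
    {-1, -1, 1}, {0, -1, 1}, {1, -1, 1}, {-1, 0, 1}, {0, 0, 1},
    {1, 0, 1},  {-1, 1, 1}, {0, 1, 1},  {1, 1, 1}};
  auto pair_force = [&](int i, int j) {
    if (i >= ff.n_chrom && j >= ff.n_chrom) return;
    // chain neighbours interact through the bond term only
    if ((j == i + 1 || i == j + 1) && i < ff.n_chrom && j < ff.n_chrom)
      return;
    double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2) return;
    double E = (i >= ff.n_chrom || j >= ff.n_chrom) ? ff.rep_e_kin
                                                    : ff.rep_e_cc;
    double s = r2 / rc2;
    double om = 1.0 - s;
    U += E * om * om;
    double fmag = 4.0 * E * om / rc2; // * r, along -r_ij for i
    fx[i] -= fmag * dx; fy[i] -= fmag * dy; fz[i] -= fmag * dz;
    fx[j] += fmag * dx; fy[j] += fmag * dy; fz[j] += fmag * dz;
  };
  for (int cz0 = 0; cz0 < cl.nz; ++cz0) {
    for (int cy0 = 0; cy0 < cl.ny; ++cy0) {
      for (int cx0 = 0; cx0 < cl.nx; ++cx0) {
        int c0 = (cz0 * cl.ny + cy0) * cl.nx + cx0;
        if (cl.head[c0] < 0) continue;
        for (int k = 0; k < 14; ++k) {
          int xc = cx0 + OFF[k][0], yc = cy0 + OFF[k][1],
              zc = cz0 + OFF[k][2];
          if (xc < 0 || xc >= cl.nx || yc < 0 || yc >= cl.ny || zc < 0 ||
              zc >= cl.nz)
            continue;
          int c1 = (zc * cl.ny + yc) * cl.nx + xc;
          if (k == 0) { // within-cell pairs
            for (int i = cl.head[c0]; i >= 0; i = cl.nxt[i])
              for (int j = cl.nxt[i]; j >= 0; j = cl.nxt[j])
                pair_force(i, j);
          } else {
            for (int i = cl.head[c0]; i >= 0; i = cl.nxt[i])
              for (int j = cl.head[c1]; j >= 0; j = cl.nxt[j])
                pair_force(i, j);
          }
        }
      }
    }
  }

  // LE bonds
  for (size_t b = 0; b < ff.le_a.size(); ++b) {
    int i = ff.le_a[b], j = ff.le_b[b];
    double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) continue;
    double dr = r - ff.le_r0;
    U += 0.5 * ff.le_k * dr * dr;
    double fmag = -ff.le_k * dr / r;
    fx[i] -= fmag * dx; fy[i] -= fmag * dy; fz[i] -= fmag * dz;
    fx[j] += fmag * dx; fy[j] += fmag * dy; fz[j] += fmag * dz;
  }

  // tethers
  for (size_t t = 0; t < ff.tether_idx.size(); ++t) {
    int i = ff.tether_idx[t];
    double dx = x[i] - ff.tref_x[t], dy = y[i] - ff.tref_y[t],
           dz = z[i] - ff.tref_z[t];
    U += 0.5 * ff.tether_k * (dx * dx + dy * dy + dz * dz);
    fx[i] -= ff.tether_k * dx;
    fy[i] -= ff.tether_k * dy;
    fz[i] -= ff.tether_k * dz;
  }

  return U;
}

// [[Rcpp::export]]
List cpp_chromatin_forces(NumericMatrix coords, int n_chrom, double k_bond,
                          double bond_r0, double k_ang, double rep_e_cc,
                          double rep_e_kin, double rep_rc,
                          IntegerVector le_a, IntegerVector le_b, double le_k,
                          double le_r0, IntegerVector tether_idx,
                          NumericMatrix tether_ref, double tether_k) {
  int n = coords.nrow();
  FF ff;
  ff.n = n; ff.n_chrom = n_chrom;
  ff.k_bond = k_bond; ff.bond_r0 = bond_r0; ff.k_ang = k_ang;
  ff.rep_e_cc = rep_e_cc; ff.rep_e_kin = rep_e_kin; ff.rep_rc = rep_rc;
  ff.le_k = le_k; ff.le_r0 = le_r0; ff.tether_k = tether_k;
  ff.le_a.assign(le_a.begin(), le_a.end());
  ff.le_b.assign(le_b.begin(), le_b.end());
  ff.tether_idx.assign(tether_idx.begin(), tether_idx.end());
  for (int t = 0; t < tether_idx.size(); ++t) {
    ff.tref_x.push_back(tether_ref(t, 0));
    ff.tref_y.push_back(tether_ref(t, 1));
    ff.tref_z.push_back(tether_ref(t, 2));
  }
  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
    if (!std::isfinite(x[i]) || !std::isfinite(y[i]) || !std::isfinite(z[i]))
      stop("non-finite coordinate at bead %d", i + 1);
  }
  CellList cl;
  double U = compute_forces(x, y, z, fx, fy, fz, ff, cl);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) {
    F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i];
  }
  return List::create(_["forces"] = F, _["energy"] = U);
}

// [[Rcpp::export]]
List cpp_run_dynamics(NumericMatrix coords, int n_chrom, double k_bond,
                      double bond_r0, double k_ang, double rep_e_cc,
                      double rep_e_kin, double rep_rc,
                      IntegerMatrix trace_left, IntegerMatrix trace_right,
                      IntegerVector block_state, // per block: row of trace (0-based) or -1
                      double le_k, double le_r0, IntegerVector tether_idx,
                      NumericMatrix tether_ref, double tether_k, double kBT,
                      double gamma, double dt, int steps_per_block,
                      int snapshot_every, NumericVector plane,
                      bool zero_velocities, IntegerVector freeze_idx) {
  // plane: length 0 (disabled) or c(y0, xmin, xmax, zmin, zmax) — the
  // kinetochore plate footprint used by the through-plane crossing counter.
  int n = coords.nrow();
  int n_blocks = block_state.size();
  FF ff;
  ff.n = n; ff.n_chrom = n_chrom;
  ff.k_bond = k_bond; ff.bond_r0 = bond_r0; ff.k_ang = k_ang;
  ff.rep_e_cc = rep_e_cc; ff.rep_e_kin = rep_e_kin; ff.rep_rc = rep_rc;
  ff.le_k = le_k; ff.le_r0 = le_r0; ff.tether_k = tether_k;
  ff.tether_idx.assign(tether_idx.begin(), tether_idx.end());
  for (int t = 0; t < tether_idx.size(); ++t) {
    ff.tref_x.push_back(tether_ref(t, 0));
    ff.tref_y.push_back(tether_ref(t, 1));
    ff.tref_z.push_back(tether_ref(t, 2));
  }

  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n), fx(n), fy(n),
      fz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
    if (!std::isfinite(x[i]) || !std::isfinite(y[i]) || !std::isfinite(z[i]))
      stop("non-finite coordinate at bead %d", i + 1);
  }
  std::vector<bool> frozen(n, false);
  for (int i = 0; i < freeze_idx.size(); ++i) frozen[freeze_idx[i]] = true;
  double sd_v = std::sqrt(kBT);
  for (int i = 0; i < n; ++i) {
    if (zero_velocities || frozen[i]) {
      vx[i] = vy[i] = vz[i] = 0.0;
    } else {
      vx[i] = sd_v * norm_rand();
      vy[i] = sd_v * norm_rand();
      vz[i] = sd_v * norm_rand();
    }
  }

  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(std::max(0.0, (1.0 - c1 * c1))) * std::sqrt(kBT);
  const bool thermostat = (gamma > 0.0);

  const bool count_cross = plane.size() == 5;
  double pl_y = 0, pl_xmin = 0, pl_xmax = 0, pl_zmin = 0, pl_zmax = 0;
  if (count_cross) {
    pl_y = plane[0]; pl_xmin = plane[1]; pl_xmax = plane[2];
    pl_zmin = plane[3]; pl_zmax = plane[4];
  }
  long crossings = 0;
  std::vector<int> cross_bead, cross_block;
  std::vector<double> prev_y;
  if (count_cross) prev_y.assign(y.begin(), y.end());

  CellList cl;
  double U = compute_forces(x, y, z, fx, fy, fz, ff, cl);

  std::vector<NumericMatrix> frames;
  std::vector<int> frame_block;
  std::vector<double> pot_e, kin_e;
  auto snapshot = [&](int block) {
    NumericMatrix fr(n, 3);
    for (int i = 0; i < n; ++i) {
      fr(i, 0) = x[i]; fr(i, 1) = y[i]; fr(i, 2) = z[i];
    }
    frames.push_back(fr);
    frame_block.push_back(block);
    double ke = 0;
    for (int i = 0; i < n; ++i)
      ke += 0.5 * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    pot_e.push_back(U);
    kin_e.push_back(ke);
  };

  for (int b = 0; b < n_blocks; ++b) {
    // update LE bond set from the trace
    int st = block_state[b];
    if (st < 0) {
      ff.le_a.clear(); ff.le_b.clear();
    } else {
      int n_les = trace_left.ncol();
      ff.le_a.resize(n_les); ff.le_b.resize(n_les);
      for (int k = 0; k < n_les; ++k) {
        ff.le_a[k] = trace_left(st, k);
        ff.le_b[k] = trace_right(st, k);
      }
    }
    for (int s = 0; s < steps_per_block; ++s) {
      // BAOAB (frozen beads are immobile grid points)
      for (int i = 0; i < n; ++i) {
        if (frozen[i]) continue;
        vx[i] += 0.5 * dt * fx[i];
        vy[i] += 0.5 * dt * fy[i];
        vz[i] += 0.5 * dt * fz[i];
        x[i] += 0.5 * dt * vx[i];
        y[i] += 0.5 * dt * vy[i];
        z[i] += 0.5 * dt * vz[i];
      }
      if (thermostat) {
        for (int i = 0; i < n; ++i) {
          if (frozen[i]) continue;
          vx[i] = c1 * vx[i] + c2 * norm_rand();
          vy[i] = c1 * vy[i] + c2 * norm_rand();
          vz[i] = c1 * vz[i] + c2 * norm_rand();
        }
      }
      for (int i = 0; i < n; ++i) {
        if (frozen[i]) continue;
        x[i] += 0.5 * dt * vx[i];
        y[i] += 0.5 * dt * vy[i];
        z[i] += 0.5 * dt * vz[i];
        if (!std::isfinite(x[i]))
          stop("integration blew up at block %d", b + 1);
      }
      U = compute_forces(x, y, z, fx, fy, fz, ff, cl);
      for (int i = 0; i < n; ++i) {
        if (frozen[i]) continue;
        vx[i] += 0.5 * dt * fx[i];
        vy[i] += 0.5 * dt * fy[i];
        vz[i] += 0.5 * dt * fz[i];
      }
      if (count_cross) {
        for (int i = 0; i < n_chrom; ++i) {
          if ((prev_y[i] - pl_y) * (y[i] - pl_y) < 0) {
            if (x[i] >= pl_xmin && x[i] <= pl_xmax && z[i] >= pl_zmin &&
                z[i] <= pl_zmax) {
              ++crossings;
              cross_bead.push_back(i + 1);
              cross_block.push_back(b + 1);
            }
          }
          prev_y[i] = y[i];
        }
      }
    }
    if ((b + 1) % snapshot_every == 0 || b == n_blocks - 1) snapshot(b + 1);
    if ((b & 63) == 0) Rcpp::checkUserInterrupt();
  }

  List fr(frames.size());
  for (size_t i = 0; i < frames.size(); ++i) fr[i] = frames[i];
  return List::create(
    _["frames"] = fr,
    _["frame_block"] = IntegerVector(frame_block.begin(), frame_block.end()),
    _["potential_energy"] = NumericVector(pot_e.begin(), pot_e.end()),
    _["kinetic_energy"] = NumericVector(kin_e.begin(), kin_e.end()),
    _["plane_crossings"] = (double)crossings,
    _["crossing_beads"] = IntegerVector(cross_bead.begin(), cross_bead.end()),
    _["crossing_blocks"] = IntegerVector(cross_block.begin(),
                                         cross_block.end()));
}

// Contact analytics (O(N^2) pair scans with early cutoff) -------------------

// [[Rcpp::export]]
NumericMatrix cpp_contact_map(List frames, int from, int to, int bin_sites,
                              double radius) {
  // from/to: 0-based inclusive site range; bins are half-open windows of
  // bin_sites sites starting at `from`.
  int n_bins = (to - from + 1 + bin_sites - 1) / bin_sites;
  NumericMatrix M(n_bins, n_bins);
  double r2 = radius * radius;
  for (int f = 0; f < frames.size(); ++f) {
    NumericMatrix C = frames[f];
    for (int i = from; i <= to; ++i) {
      int bi = (i - from) / bin_sites;
      double xi = C(i, 0), yi = C(i, 1), zi = C(i, 2);
      for (int j = i; j <= to; ++j) {
        double dx = C(j, 0) - xi;
        double dy = C(j, 1) - yi;
        double dz = C(j, 2) - zi;
        if (dx * dx + dy * dy + dz * dz <= r2) {
          int bj = (j - from) / bin_sites;
          M(bi, bj) += 1;
          if (bi != bj) M(bj, bi) += 1;
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
List cpp_contact_probability(NumericMatrix coords, double radius,
                             NumericVector breaks_sites) {
  // breaks_sites: ascending genomic-separation bin edges in sites; bin b is
  // [breaks[b], breaks[b+1]).
  int n = coords.nrow();
  int n_bins = breaks_sites.size() - 1;
  NumericVector contacts(n_bins), possible(n_bins);
  double r2 = radius * radius;
  double smin = breaks_sites[0], smax = breaks_sites[n_bins];
  for (int i = 0; i < n; ++i) {
    double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    for (int j = i + 1; j < n; ++j) {
      double s = j - i;
      if (s < smin || s >= smax) continue;
      // binary search for the bin
      int lo = 0, hi = n_bins;
      while (hi - lo > 1) {
        int mid = (lo + hi) / 2;
        if (s >= breaks_sites[mid]) lo = mid; else hi = mid;
      }
      possible[lo] += 1;
      double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi,
             dz = coords(j, 2) - zi;
      if (dx * dx + dy * dy + dz * dz <= r2) contacts[lo] += 1;
    }
  }
  return List::create(_["contacts"] = contacts, _["possible"] = possible);
}
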