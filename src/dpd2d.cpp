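// Explicit DPD solvent in a small 2D box (units: rc = 1, m = 1, k_B = 1).
// Standard conservative/dissipative/random force triplet with the
// fluctuation-dissipation relation sigma^2 = 2 gamma kBT, modified
// velocity-Verlet integration (velocity prediction lambda = 0.5), periodic
// in x, and either fully periodic in z or frozen-particle walls with
// bounce-back (bottom at rest, top moving at U for Couette flow).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "sim_rng.h"

using namespace Rcpp;

namespace {
inline double pimg(double d, double L) { return d - L * std::floor(d / L + 0.5); }
}

// [[Rcpp::export]]
List run_dpd_box(double Lx, double Lz, double rho, double a_cons,
                 double gamma_, double kBT, double dt, int n_steps,
                 int warmup, double U_top, int walls, int nzbins, int seed) {
  const double sigma = std::sqrt(2.0 * gamma_ * kBT);
  const uint64_t useed = (uint64_t)seed;

  // fluid particles on a jittered lattice
  int nfx = (int)std::round(std::sqrt(rho * Lx * Lx * Lz / Lz / Lx) * 1);
  nfx = std::max(1, (int)std::round(Lx * std::sqrt(rho)));
  int nfz = std::max(1, (int)std::round(Lz * std::sqrt(rho)));
  int nfluid = nfx * nfz;
  std::vector<double> px, pz, vx, vz;
  px.reserve(nfluid);
  for (int i = 0; i < nfx; ++i) {
    for (int j = 0; j < nfz; ++j) {
      double jx = 0.3 * (simrng::unif(useed, simrng::STREAM_INIT, 0,
                                      2 * (i * nfz + j)) - 0.5);
      double jz = 0.3 * (simrng::unif(useed, simrng::STREAM_INIT, 0,
                                      2 * (i * nfz + j) + 1) - 0.5);
      px.push_back((i + 0.5) * Lx / nfx + jx);
      pz.push_back((j + 0.5) * Lz / nfz + jz);
    }
  }
  vx.assign(nfluid, 0.0);
  vz.assign(nfluid, 0.0);

  // wall particles (frozen): one rc-thick layer outside each wall
  int nwall = 0;
  std::vector<double> wvx;  // wall particle x-velocity (0 bottom, U top)
  if (walls) {
    int nwx = std::max(1, (int)std::round(Lx * std::sqrt(rho)));
    int nwz = std::max(1, (int)std::round(std::sqrt(rho)));
    for (int layer = 0; layer < 2; ++layer) {
      for (int i = 0; i < nwx; ++i) {
        for (int j = 0; j < nwz; ++j) {
          double zz = (j + 0.5) / nwz;  // in (0,1)
          px.push_back((i + 0.5) * Lx / nwx +
                       0.17 * Lx / nwx * ((layer == 0) ? 1 : -1) * 0.0);
          pz.push_back(layer == 0 ? -zz : Lz + zz);
          vx.push_back(layer == 0 ? 0.0 : U_top);
          vz.push_back(0.0);
          wvx.push_back(layer == 0 ? 0.0 : U_top);
          ++nwall;
        }
      }
    }
  }
  const int n = nfluid + nwall;

  // cell list over [0,Lx) x [zlo, zhi)
  double zlo = walls ? -1.0 : 0.0;
  double zhi = walls ? Lz + 1.0 : Lz;
  int ncx = std::max(3, (int)std::floor(Lx));
  int ncz = std::max(3, (int)std::floor(zhi - zlo));
  double cwx = Lx / ncx, cwz = (zhi - zlo) / ncz;
  std::vector<int> head(ncx * ncz), nxt(n);

  std::vector<double> fx(n), fz(n), fx_old(n, 0.0), fz_old(n, 0.0);
  std::vector<double> vtx(n), vtz(n);  // predicted velocities

  auto build_cells = [&]() {
    std::fill(head.begin(), head.end(), -1);
    for (int i = 0; i < n; ++i) {
      double xw = px[i] - Lx * std::floor(px[i] / Lx);
      int cxi = std::min(ncx - 1, std::max(0, (int)(xw / cwx)));
      double zz = pz[i];
      if (!walls) zz -= Lz * std::floor(zz / Lz);
      int czi = std::min(ncz - 1, std::max(0, (int)((zz - zlo) / cwz)));
      int cc = czi * ncx + cxi;
      nxt[i] = head[cc];
      head[cc] = i;
    }
  };

  uint64_t gstep = 1;
  auto forces = [&](const std::vector<double>& ux,
                    const std::vector<double>& uz) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    build_cells();
    for (int czi = 0; czi < ncz; ++czi) {
      for (int cxi = 0; cxi < ncx; ++cxi) {
        int cc = czi * ncx + cxi;
        // neighbor stencil: self, E, N, NE, NW (half stencil)
        const int sten[5][2] = {{0, 0}, {1, 0}, {0, 1}, {1, 1}, {-1, 1}};
        for (int sdx = 0; sdx < 5; ++sdx) {
          int cx2 = (cxi + sten[sdx][0] + ncx) % ncx;
          int cz2 = czi + sten[sdx][1];
          if (walls) {
            if (cz2 < 0 || cz2 >= ncz) continue;
          } else {
            cz2 = (cz2 + ncz) % ncz;
          }
          int cc2 = cz2 * ncx + cx2;
          for (int i = head[cc]; i != -1; i = nxt[i]) {
            for (int j = (cc2 == cc) ? nxt[i] : head[cc2]; j != -1;
                 j = nxt[j]) {
              if (i >= nfluid && j >= nfluid) continue;  // wall-wall
              double dx = pimg(px[i] - px[j], Lx);
              double dz = pz[i] - pz[j];
              if (!walls) dz = pimg(dz, Lz);
              double r2 = dx * dx + dz * dz;
              if (r2 >= 1.0 || r2 < 1e-16) continue;
              double r = std::sqrt(r2);
              double w = 1.0 - r;
              double ex = dx / r, ez = dz / r;
              double dvx = ux[i] - ux[j], dvz = uz[i] - uz[j];
              double evdot = ex * dvx + ez * dvz;
              uint64_t pid =
                  (uint64_t)std::min(i, j) * (uint64_t)n + std::max(i, j);
              double xi = simrng::gauss(useed, simrng::STREAM_DPD, gstep, pid);
              double fmag = a_cons * w - gamma_ * w * w * evdot +
                            sigma * w * xi / std::sqrt(dt);
              fx[i] += fmag * ex;
              fz[i] += fmag * ez;
              fx[j] -= fmag * ex;
              fz[j] -= fmag * ez;
            }
          }
        }
      }
    }
  };

  int ntb = std::max(1, nzbins);
  std::vector<double> bin_vx(ntb, 0.0);
  std::vector<int> bin_cnt(ntb, 0);
  double tsum = 0.0;
  long tcnt = 0;
  double max_fsum = 0.0;

  forces(vx, vz);
  std::swap(fx, fx_old);
  std::swap(fz, fz_old);

  for (int s = 0; s < n_steps; ++s) {
    // modified velocity Verlet (lambda = 0.5)
    for (int i = 0; i < nfluid; ++i) {
      px[i] += dt * vx[i] + 0.5 * dt * dt * fx_old[i];
      pz[i] += dt * vz[i] + 0.5 * dt * dt * fz_old[i];
      vtx[i] = vx[i] + 0.5 * dt * fx_old[i];
      vtz[i] = vz[i] + 0.5 * dt * fz_old[i];
    }
    for (int i = nfluid; i < n; ++i) {
      vtx[i] = vx[i];
      vtz[i] = vz[i];
    }
    // boundaries
    for (int i = 0; i < nfluid; ++i) {
      px[i] -= Lx * std::floor(px[i] / Lx);
      if (walls) {
        if (pz[i] < 0.0) {
          pz[i] = -pz[i];
          vx[i] = -vx[i];
          vz[i] = -vz[i];
          vtx[i] = -vtx[i];
          vtz[i] = -vtz[i];
        } else if (pz[i] > Lz) {
          pz[i] = 2.0 * Lz - pz[i];
          vx[i] = 2.0 * U_top - vx[i];
          vz[i] = -vz[i];
          vtx[i] = 2.0 * U_top - vtx[i];
          vtz[i] = -vtz[i];
        }
      } else {
        pz[i] -= Lz * std::floor(pz[i] / Lz);
      }
    }
    forces(vtx, vtz);
    double fsx = 0.0, fsz = 0.0;
    for (int i = 0; i < nfluid; ++i) {
      vx[i] += 0.5 * dt * (fx_old[i] + fx[i]);
      vz[i] += 0.5 * dt * (fz_old[i] + fz[i]);
    }
    if (!walls) {
      for (int i = 0; i < n; ++i) {
        fsx += fx[i];
        fsz += fz[i];
      }
      double fs = std::sqrt(fsx * fsx + fsz * fsz);
      if (fs > max_fsum) max_fsum = fs;
    }
    std::swap(fx, fx_old);
    std::swap(fz, fz_old);
    ++gstep;

    if (s >= warmup && (s % 10 == 0)) {
      // temperature from wall-normal velocity (no streaming component)
      for (int i = 0; i < nfluid; ++i) {
        tsum += vz[i] * vz[i];
        ++tcnt;
      }
      for (int i = 0; i < nfluid; ++i) {
        int b = std::min(ntb - 1,
                         std::max(0, (int)(pz[i] / Lz * ntb)));
        bin_vx[b] += vx[i];
        bin_cnt[b] += 1;
      }
    }
  }

  NumericVector prof(ntb), prof_z(ntb);
  for (int b = 0; b < ntb; ++b) {
    prof[b] = bin_cnt[b] > 0 ? bin_vx[b] / bin_cnt[b] : NA_REAL;
    prof_z[b] = (b + 0.5) * Lz / ntb;
  }
  double momx = 0.0, momz = 0.0;
  for (int i = 0; i < nfluid; ++i) {
    momx += vx[i];
    momz += vz[i];
  }
  return List::create(
      _["temperature"] = (tcnt > 0) ? tsum / tcnt : NA_REAL,
      _["profile_u"] = prof, _["profile_z"] = prof_z,
      _["momentum"] = NumericVector::create(momx, momz),
      _["max_pair_force_sum"] = max_fsum, _["n_fluid"] = nfluid,
      _["n_wall"] = nwall);
}

// Single evaluation of DPD pair forces for a given configuration: used to
// test Newton's third law, the cutoff, and zero-separation regularity.
// [[Rcpp::export]]
List dpd_forces_once(NumericMatrix pos, NumericMatrix vel, double a_cons,
                     double gamma_, double sigma, double kBT, double dt,
                     int seed) {
  int n = pos.nrow();
  NumericMatrix F(n, 2);
  const uint64_t useed = (uint64_t)seed;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dz = pos(i, 1) - pos(j, 1);
      double r2 = dx * dx + dz * dz;
      if (r2 >= 1.0) continue;
      double r = std::sqrt(r2);
      double w = 1.0 - r;
      double ex, ez;
      if (r < 1e-12) {
        // overlapping particles: soft potential, finite force along a
        // deterministic fallback direction
        ex = 1.0;
        ez = 0.0;
      } else {
        ex = dx / r;
        ez = dz / r;
      }
      double dvx = vel(i, 0) - vel(j, 0), dvz = vel(i, 1) - vel(j, 1);
      double evdot = ex * dvx + ez * dvz;
      uint64_t pid = (uint64_t)i * (uint64_t)n + (uint64_t)j;
      double xi = simrng::gauss(useed, simrng::STREAM_DPD, 1, pid);
      double fmag = a_cons * w - gamma_ * w * w * evdot +
                    sigma * w * xi / std::sqrt(dt);
      F(i, 0) += fmag * ex;
      F(i, 1) += fmag * ez;
      F(j, 0) -= fmag * ex;
      F(j, 1) -= fmag * ez;
    }
  }
  return List::create(_["forces"] = F);
}
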