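// Desk-scale 2D reduced mode: cells are closed polygons (line-tension
// membrane: springs + bending + global area constraint) advected by an
// analytic Couette background through Langevin drag + FDT noise, with a
// near-surface deformability-lift term, soft steric interactions, the
// stochastic receptor-ligand adhesion model against rigid macrophage caps,
// and optional Morse cell-cell aggregation. Periodicity in x is handled via
// minimum-image in interactions; vertex coordinates are never wrapped, so
// centroid displacements come out unwrapped for free.
//
// Integration is semi-implicit (symplectic) Euler with one force evaluation
// per step, so the full dynamical state lives at step boundaries and a saved
// state restarts bitwise-identically (the RNG is counter-based on the global
// step index).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
#include "sim_rng.h"

using namespace Rcpp;

namespace {

struct Params {
  int nv, ncell, nmac;
  double kedge, kA, m, zeta_v, kBT, dt, mu, UL, aeq;
  double L, h;
  // adhesion
  int adhesion_on;
  double Ks, l0b, don, doff, son, soff, kon0, koff0;
  // aggregation + sterics
  int agg_on;
  double De, beta, r0b, rcut;
  double k_rep, r_rep, k_mac, d_rep, k_wall, d_wall;
  double touch_dist;
};

inline double min_image(double dx, double L) {
  if (L <= 0) return dx;
  dx -= L * std::floor(dx / L + 0.5);
  return dx;
}

inline double sched_value(const NumericVector& st, const NumericVector& sU,
                          double t) {
  int j = 0;
  int n = st.size();
  while (j + 1 < n && st[j + 1] <= t) ++j;
  return sU[j];
}

// Membrane (springs + bending + area) forces; returns total elastic energy.
double membrane_forces(const std::vector<double>& px,
                       const std::vector<double>& pz,
                       const Params& P,
                       const std::vector<double>& l0,
                       const std::vector<double>& th0c,
                       const std::vector<double>& th0s,
                       const std::vector<double>& A0,
                       const std::vector<double>& kbend,
                       std::vector<double>& fx, std::vector<double>& fz,
                       std::vector<double>* area_out) {
  double E = 0.0;
  const int nv = P.nv;
  for (int c = 0; c < P.ncell; ++c) {
    const int o = c * nv;
    // springs
    for (int i = 0; i < nv; ++i) {
      int jn = (i + 1) % nv;
      double dx = px[o + jn] - px[o + i];
      double dz = pz[o + jn] - pz[o + i];
      double L2 = dx * dx + dz * dz;
      double Ln = std::sqrt(L2);
      double stretch = Ln - l0[o + i];
      E += 0.5 * P.kedge * stretch * stretch;
      double fmag = P.kedge * stretch / Ln;
      fx[o + i] += fmag * dx;
      fz[o + i] += fmag * dz;
      fx[o + jn] -= fmag * dx;
      fz[o + jn] -= fmag * dz;
    }
    // bending: E_i = kb (1 - cos(phi_i - phi0_i))
    double kb = kbend[c];
    for (int i = 0; i < nv; ++i) {
      int im = (i + nv - 1) % nv;
      int ip = (i + 1) % nv;
      double ax = px[o + i] - px[o + im], az = pz[o + i] - pz[o + im];
      double bx = px[o + ip] - px[o + i], bz = pz[o + ip] - pz[o + i];
      double na = std::sqrt(ax * ax + az * az);
      double nb = std::sqrt(bx * bx + bz * bz);
      double inv = 1.0 / (na * nb);
      double u = ax * bx + az * bz;
      double w = ax * bz - az * bx;
      double cphi = u * inv, sphi = w * inv;
      double c0 = th0c[o + i], s0 = th0s[o + i];
      E += kb * (1.0 - cphi * c0 - sphi * s0);
      // gradients of cos(phi) and sin(phi) wrt edge vectors a and b
      double ia2 = 1.0 / (na * na), ib2 = 1.0 / (nb * nb);
      double dca_x = bx * inv - u * inv * ia2 * ax;
      double dca_z = bz * inv - u * inv * ia2 * az;
      double dcb_x = ax * inv - u * inv * ib2 * bx;
      double dcb_z = az * inv - u * inv * ib2 * bz;
      double dsa_x = bz * inv - w * inv * ia2 * ax;
      double dsa_z = -bx * inv - w * inv * ia2 * az;
      double dsb_x = -az * inv - w * inv * ib2 * bx;
      double dsb_z = ax * inv - w * inv * ib2 * bz;
      double ga_x = -kb * (c0 * dca_x + s0 * dsa_x);
      double ga_z = -kb * (c0 * dca_z + s0 * dsa_z);
      double gb_x = -kb * (c0 * dcb_x + s0 * dsb_x);
      double gb_z = -kb * (c0 * dcb_z + s0 * dsb_z);
      // F_k = -dE/dx_k; dE/dx_{i-1} = -ga, dE/dx_i = ga - gb, dE/dx_{i+1} = gb
      fx[o + im] += ga_x;
      fz[o + im] += ga_z;
      fx[o + i] -= (ga_x - gb_x);
      fz[o + i] -= (ga_z - gb_z);
      fx[o + ip] -= gb_x;
      fz[o + ip] -= gb_z;
    }
    // global area constraint (signed, CCW positive)
    double A = 0.0;
    for (int i = 0; i < nv; ++i) {
      int ip = (i + 1) % nv;
      A += px[o + i] * pz[o + ip] - px[o + ip] * pz[o + i];
    }
    A *= 0.5;
    if (area_out) (*area_out)[c] = A;
    double dA = A - A0[c];
    E += 0.5 * P.kA * dA * dA / A0[c];
    double coef = -P.kA * dA / A0[c];
    for (int i = 0; i < nv; ++i) {
      int im = (i + nv - 1) % nv;
      int ip = (i + 1) % nv;
      fx[o + i] += coef * 0.5 * (pz[o + ip] - pz[o + im]);
      fz[o + i] += coef * 0.5 * (px[o + im] - px[o + ip]);
    }
  }
  return E;
}

}  // namespace

// Pure membrane energy/forces entry point for tests (no fluid, no pairs).
// [[Rcpp::export]]
List membrane2d_energy_forces(NumericMatrix pos, int nv, NumericVector l0,
                              NumericVector theta0, NumericVector A0,
                              double kedge, NumericVector kbend, double kA) {
  int n = pos.nrow();
  Params P{};
  P.nv = nv;
  P.ncell = n / nv;
  P.kedge = kedge;
  P.kA = kA;
  std::vector<double> px(n), pz(n), fx(n, 0.0), fz(n, 0.0);
  std::vector<double> th0c(n), th0s(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i, 0);
    pz[i] = pos(i, 1);
    th0c[i] = std::cos(theta0[i]);
    th0s[i] = std::sin(theta0[i]);
  }
  std::vector<double> l0v(l0.begin(), l0.end());
  std::vector<double> A0v(A0.begin(), A0.end());
  std::vector<double> kbv(kbend.begin(), kbend.end());
  std::vector<double> area(P.ncell, 0.0);
  double E = membrane_forces(px, pz, P, l0v, th0c, th0s, A0v, kbv, fx, fz,
                             &area);
  NumericMatrix F(n, 2);
  for (int i = 0; i < n; ++i) {
    F(i, 0) = fx[i];
    F(i, 1) = fz[i];
  }
  return List::create(_["energy"] = E, _["forces"] = F,
                      _["area"] = NumericVector(area.begin(), area.end()));
}

// Morse pairwise forces between two vertex sets (unit test surface).
// [[Rcpp::export]]
List morse_pair_forces(NumericMatrix A, NumericMatrix B, double De,
                       double beta, double r0, double rcut) {
  int na = A.nrow(), nb = B.nrow();
  NumericMatrix FA(na, 2), FB(nb, 2);
  double E = 0.0;
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double dx = A(i, 0) - B(j, 0), dz = A(i, 1) - B(j, 1);
      double r = std::sqrt(dx * dx + dz * dz);
      if (r >= rcut || r <= 1e-12) continue;
      double e1 = std::exp(-beta * (r - r0));
      double e2 = e1 * e1;
      E += De * (e2 - 2.0 * e1);
      double fmag = 2.0 * De * beta * (e2 - e1);  // along r-hat, >0 repulsive
      fmag /= r;
      FA(i, 0) += fmag * dx;
      FA(i, 1) += fmag * dz;
      FB(j, 0) -= fmag * dx;
      FB(j, 1) -= fmag * dz;
    }
  }
  return List::create(_["energy"] = E, _["FA"] = FA, _["FB"] = FB);
}

// [[Rcpp::export]]
List run_reduced2d(List state, List params, NumericVector sched_t,
                   NumericVector sched_U, int n_steps, int record_every,
                   int seed) {
  NumericMatrix pos = clone(as<NumericMatrix>(state["pos"]));
  NumericMatrix vel = clone(as<NumericMatrix>(state["vel"]));
  const int n = pos.nrow();
  Params P{};
  P.nv = as<int>(state["nv"]);
  P.ncell = n / P.nv;
  P.kedge = as<double>(params["kedge"]);
  P.kA = as<double>(params["kA"]);
  P.m = as<double>(params["mass"]);
  P.zeta_v = as<double>(params["zeta_v"]);
  P.kBT = as<double>(params["kBT"]);
  P.dt = as<double>(params["dt"]);
  P.mu = as<double>(params["mu"]);
  P.UL = as<double>(params["UL"]);
  P.aeq = as<double>(params["aeq"]);
  P.L = as<double>(params["L"]);
  P.h = as<double>(params["h"]);
  P.adhesion_on = as<int>(params["adhesion_on"]);
  P.Ks = as<double>(params["Ks"]);
  P.l0b = as<double>(params["l0b"]);
  P.don = as<double>(params["don"]);
  P.doff = as<double>(params["doff"]);
  P.son = as<double>(params["son"]);
  P.soff = as<double>(params["soff"]);
  P.kon0 = as<double>(params["kon0"]);
  P.koff0 = as<double>(params["koff0"]);
  P.agg_on = as<int>(params["agg_on"]);
  P.De = as<double>(params["De"]);
  P.beta = as<double>(params["beta"]);
  P.r0b = as<double>(params["r0b"]);
  P.rcut = as<double>(params["rcut"]);
  P.k_rep = as<double>(params["k_rep"]);
  P.r_rep = as<double>(params["r_rep"]);
  P.k_mac = as<double>(params["k_mac"]);
  P.d_rep = as<double>(params["d_rep"]);
  P.k_wall = as<double>(params["k_wall"]);
  P.d_wall = as<double>(params["d_wall"]);
  P.touch_dist = as<double>(params["touch_dist"]);
  const double vcap = as<double>(params["vcap"]);  // numerical safeguard
  NumericMatrix macs = as<NumericMatrix>(params["macs"]);
  P.nmac = macs.nrow();
  int fluid_on = as<int>(params["fluid_on"]);

  std::vector<double> l0 = as<std::vector<double>>(state["l0"]);
  std::vector<double> theta0 = as<std::vector<double>>(state["theta0"]);
  std::vector<double> A0 = as<std::vector<double>>(state["A0"]);
  std::vector<double> kbend = as<std::vector<double>>(params["kbend"]);
  std::vector<double> Es = as<std::vector<double>>(params["Es"]);
  std::vector<double> th0c(n), th0s(n);
  for (int i = 0; i < n; ++i) {
    th0c[i] = std::cos(theta0[i]);
    th0s[i] = std::sin(theta0[i]);
  }

  IntegerVector bond_on = clone(as<IntegerVector>(state["bond_on"]));
  NumericVector bond_ax = clone(as<NumericVector>(state["bond_ax"]));
  NumericVector bond_az = clone(as<NumericVector>(state["bond_az"]));
  NumericVector bond_t = clone(as<NumericVector>(state["bond_t"]));
  double time = as<double>(state["time"]);
  uint64_t gstep = (uint64_t)as<double>(state["step"]);
  const uint64_t useed = (uint64_t)seed;

  std::vector<double> px(n), pz(n), vx(n), vz(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i, 0);
    pz[i] = pos(i, 1);
    vx[i] = vel(i, 0);
    vz[i] = vel(i, 1);
  }

  // x-bins for inter-cell pair search
  double bw = std::max(P.rcut, P.r_rep);
  if (bw <= 0) bw = 1.0;
  int nbins = std::max(3, (int)std::floor(P.L / bw));
  double binw = P.L / nbins;
  std::vector<int> head(nbins), nxt(n);

  const int nsnap = (record_every > 0) ? n_steps / record_every : 0;
  NumericVector snap_t(nsnap);
  NumericMatrix snap_comx(nsnap, P.ncell), snap_comz(nsnap, P.ncell),
      snap_speed(nsnap, P.ncell), snap_gap(nsnap, P.ncell),
      snap_cluster(nsnap, P.ncell);
  IntegerMatrix snap_nb(nsnap, P.ncell);
  int isnap = 0;

  std::vector<double> gapmin(P.ncell,
                             std::numeric_limits<double>::infinity());
  std::vector<double> gap_now(P.ncell);  // per-step min vertex-cap gap
  std::vector<double> fx(n), fz(n);
  std::vector<int> parent(P.ncell);
  std::vector<double> area_now(P.ncell, 0.0);
  const double dtm = P.dt / P.m;
  const double sigF = (fluid_on && P.zeta_v > 0)
                          ? as<double>(params["sigF"])
                          : 0.0;

  auto uf_find = [&parent](int a) {
    while (parent[a] != a) {
      parent[a] = parent[parent[a]];
      a = parent[a];
    }
    return a;
  };

  for (int s = 0; s < n_steps; ++s) {
    double U = sched_value(sched_t, sched_U, time);
    bool snap_now = (record_every > 0) && ((s + 1) % record_every == 0);
    for (int c = 0; c < P.ncell; ++c) parent[c] = c;

    // ---- stochastic adhesion update at current positions ----
    if (P.adhesion_on) {
      for (int i = 0; i < n; ++i) {
        if (bond_on[i]) {
          double dxa = px[i] - bond_ax[i];
          double dza = pz[i] - bond_az[i];
          double l = std::sqrt(dxa * dxa + dza * dza);
          if (l >= P.doff) {
            bond_on[i] = 0;  // deterministic rupture beyond d_off
          } else {
            double dl = l - P.l0b;
            double koff =
                P.koff0 * std::exp(-P.soff * dl * dl / (2.0 * P.kBT));
            double Poff = 1.0 - std::exp(-koff * P.dt);
            double lam2 = simrng::unif(useed, simrng::STREAM_BOND_DISS,
                                       gstep, (uint64_t)i);
            if (Poff > lam2) bond_on[i] = 0;
          }
        } else if (P.nmac > 0) {
          // nearest macrophage surface point
          double best = std::numeric_limits<double>::infinity();
          double axp = 0, azp = 0;
          for (int mc = 0; mc < P.nmac; ++mc) {
            double dxm = min_image(px[i] - macs(mc, 0), P.L);
            double dzm = pz[i] - macs(mc, 1);
            double dist = std::sqrt(dxm * dxm + dzm * dzm);
            double gap = dist - macs(mc, 2);
            if (gap < best) {
              best = gap;
              double sc = macs(mc, 2) / std::max(dist, 1e-12);
              axp = px[i] - dxm + dxm * sc;
              azp = macs(mc, 1) + dzm * sc;
            }
          }
          double l = std::max(best, 0.0);
          if (l < P.don) {
            double dl = l - P.l0b;
            double kon = P.kon0 * std::exp(-P.son * dl * dl / (2.0 * P.kBT));
            double Pon = 1.0 - std::exp(-kon * P.dt);
            double lam1 = simrng::unif(useed, simrng::STREAM_BOND_FORM,
                                       gstep, (uint64_t)i);
            if (Pon > lam1) {
              bond_on[i] = 1;
              bond_ax[i] = axp;
              bond_az[i] = azp;
              bond_t[i] = time;
            }
          }
        }
      }
    }

    // ---- forces at current positions/velocities ----
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    membrane_forces(px, pz, P, l0, th0c, th0s, A0, kbend, fx, fz, &area_now);

    // walls (soft)
    for (int i = 0; i < n; ++i) {
      if (pz[i] < P.d_wall) fz[i] += P.k_wall * (P.d_wall - pz[i]);
      if (pz[i] > P.h - P.d_wall)
        fz[i] -= P.k_wall * (pz[i] - (P.h - P.d_wall));
    }

    // macrophage sterics + per-cell gap tracking
    std::fill(gap_now.begin(), gap_now.end(),
              std::numeric_limits<double>::infinity());
    if (P.nmac > 0) {
      for (int i = 0; i < n; ++i) {
        int c = i / P.nv;
        for (int mc = 0; mc < P.nmac; ++mc) {
          double dxm = min_image(px[i] - macs(mc, 0), P.L);
          double dzm = pz[i] - macs(mc, 1);
          double dist = std::sqrt(dxm * dxm + dzm * dzm);
          double gap = dist - macs(mc, 2);
          if (gap < gapmin[c]) gapmin[c] = gap;
          if (gap < gap_now[c]) gap_now[c] = gap;
          if (gap < P.d_rep) {
            double fmag = P.k_mac * (P.d_rep - gap) / std::max(dist, 1e-9);
            fx[i] += fmag * dxm;
            fz[i] += fmag * dzm;
          }
        }
      }
    }

    // bond forces
    if (P.adhesion_on) {
      for (int i = 0; i < n; ++i) {
        if (!bond_on[i]) continue;
        double dxa = px[i] - bond_ax[i];
        double dza = pz[i] - bond_az[i];
        double l = std::sqrt(dxa * dxa + dza * dza);
        if (l > 1e-12) {
          double fmag = -P.Ks * (l - P.l0b) / l;
          fx[i] += fmag * dxa;
          fz[i] += fmag * dza;
        }
      }
    }

    // inter-cell pairs via x-bins (steric + optional Morse)
    if (P.ncell > 1) {
      std::fill(head.begin(), head.end(), -1);
      for (int i = 0; i < n; ++i) {
        double xw = px[i] - P.L * std::floor(px[i] / P.L);
        int b = (int)(xw / binw);
        if (b >= nbins) b = nbins - 1;
        if (b < 0) b = 0;
        nxt[i] = head[b];
        head[b] = i;
      }
      double rmax = std::max(P.r_rep, P.agg_on ? P.rcut : 0.0);
      double rmax2 = rmax * rmax;
      for (int b = 0; b < nbins; ++b) {
        for (int db = 0; db <= 1; ++db) {
          int b2 = (b + db) % nbins;
          for (int i = head[b]; i != -1; i = nxt[i]) {
            for (int j = (db == 0) ? nxt[i] : head[b2]; j != -1;
                 j = nxt[j]) {
              int ci = i / P.nv, cj = j / P.nv;
              if (ci == cj) continue;
              double dx = min_image(px[i] - px[j], P.L);
              if (std::fabs(dx) > rmax) continue;
              double dz = pz[i] - pz[j];
              double r2 = dx * dx + dz * dz;
              if (r2 >= rmax2 || r2 < 1e-18) continue;
              double r = std::sqrt(r2);
              double fmag = 0.0;
              if (r < P.r_rep) fmag += P.k_rep * (P.r_rep - r);
              if (P.agg_on && r < P.rcut) {
                double e1 = std::exp(-P.beta * (r - P.r0b));
                fmag += 2.0 * P.De * P.beta * (e1 * e1 - e1);
              }
              if (fmag != 0.0) {
                double fr = fmag / r;
                fx[i] += fr * dx;
                fz[i] += fr * dz;
                fx[j] -= fr * dx;
                fz[j] -= fr * dz;
              }
              if (snap_now && r < P.touch_dist) {
                int ra = uf_find(ci), rb = uf_find(cj);
                if (ra != rb) parent[ra] = rb;
              }
            }
          }
        }
      }
    }

    // fluid coupling: drag to Couette background + thermal noise + lift
    if (fluid_on) {
      double gdot = U / P.h;
      for (int i = 0; i < n; ++i) {
        double ubg = U * pz[i] / P.h;
        fx[i] += P.zeta_v * (ubg - vx[i]) +
                 sigF * simrng::gauss(useed, simrng::STREAM_FLUID, gstep,
                                      (uint64_t)(2 * i));
        fz[i] += P.zeta_v * (0.0 - vz[i]) +
                 sigF * simrng::gauss(useed, simrng::STREAM_FLUID, gstep,
                                      (uint64_t)(2 * i + 1));
      }
      // (deformability lift is applied kinematically after integration:
      // in Stokes flow it is a drift velocity, not an inertial force)
    }

    // ---- integrate (semi-implicit Euler) ----
    for (int i = 0; i < n; ++i) {
      vx[i] += dtm * fx[i];
      vz[i] += dtm * fz[i];
      if (vcap > 0) {
        double sp = std::sqrt(vx[i] * vx[i] + vz[i] * vz[i]);
        if (sp > vcap) {
          vx[i] *= vcap / sp;
          vz[i] *= vcap / sp;
        }
      }
      px[i] += P.dt * vx[i];
      pz[i] += P.dt * vz[i];
    }
    // bounce-back walls
    for (int i = 0; i < n; ++i) {
      if (pz[i] < 0.0) {
        pz[i] = -pz[i];
        vx[i] = -vx[i];
        vz[i] = -vz[i];
      } else if (pz[i] > P.h) {
        pz[i] = 2.0 * P.h - pz[i];
        vx[i] = 2.0 * U - vx[i];
        vz[i] = -vz[i];
      }
    }
    // impermeable macrophage caps: project penetrating vertices back to the
    // surface and absorb the inward normal velocity (prevents tunnelling of
    // fast cells through the rigid cap)
    if (P.nmac > 0) {
      for (int i = 0; i < n; ++i) {
        for (int mc = 0; mc < P.nmac; ++mc) {
          double dxm = min_image(px[i] - macs(mc, 0), P.L);
          double dzm = pz[i] - macs(mc, 1);
          double dist = std::sqrt(dxm * dxm + dzm * dzm);
          if (dist < macs(mc, 2) && dist > 1e-9) {
            double nxm = dxm / dist, nzm = dzm / dist;
            double push = macs(mc, 2) - dist;
            px[i] += push * nxm;
            pz[i] += push * nzm;
            double vn = vx[i] * nxm + vz[i] * nzm;
            if (vn < 0) {
              vx[i] -= vn * nxm;
              vz[i] -= vn * nzm;
            }
          }
        }
      }
    }

    // ---- kinematic deformability-lift drift ----
    // Cross-streamline migration away from surfaces: a Stokes drift
    // velocity v = UL Ca gdot a (a/d)^2 per surface (bottom wall, top wall,
    // caps), applied as a rigid displacement of each cell. It ramps to zero
    // within d < 1 um of a surface (lubrication/contact zone), so bound or
    // touching cells are not torn by it.
    if (fluid_on && P.UL > 0 && U != 0.0) {
      double gd = std::fabs(U / P.h);
      for (int c = 0; c < P.ncell; ++c) {
        int o = c * P.nv;
        double cx = 0, cz = 0;
        for (int i = 0; i < P.nv; ++i) {
          cx += px[o + i];
          cz += pz[o + i];
        }
        cx /= P.nv;
        cz /= P.nv;
        double v0 = P.UL * (P.mu * gd * P.aeq / Es[c]) * gd * P.aeq;
        // decay scale: cell size near plane walls, obstacle scale (2a)
        // near the curved caps whose flow disturbance is longer-ranged
        auto wfun = [&](double d, double s) {
          if (d < 1.0) return 0.0;
          double ramp = (d < 2.0) ? (d - 1.0) : 1.0;
          double r = s / d;
          return ramp * std::min(r * r, 1.0);
        };
        double vx_ = 0.0, vz_ = 0.0;
        // wall lift is confined to the cell-free-layer scale near each
        // wall (fades out between 4 and 6 um): in dilute suspensions the
        // lift-depleted layer is a few microns thick, and cells beyond it
        // keep their streamline
        auto cfl = [](double d) {
          if (d >= 6.0) return 0.0;
          if (d <= 4.0) return 1.0;
          return (6.0 - d) / 2.0;
        };
        vz_ += v0 * cfl(cz) * wfun(cz, P.aeq);
        vz_ -= v0 * cfl(P.h - cz) * wfun(P.h - cz, P.aeq);
        // cap drift gated by the cell-surface gap: in the contact /
        // lubrication zone (any vertex within 1 um of a cap, e.g. a bonded
        // cell) the drift vanishes
        double gate = 1.0;
        if (gap_now[c] < 0.75) gate = 0.0;
        else if (gap_now[c] < 1.5) gate = (gap_now[c] - 0.75) / 0.75;
        if (gate > 0.0) {
          for (int mc = 0; mc < P.nmac; ++mc) {
            double dxm = min_image(cx - macs(mc, 0), P.L);
            double dzm = cz - macs(mc, 1);
            double dist = std::sqrt(dxm * dxm + dzm * dzm);
            // obstacle-scale interaction range: the cap's flow
            // disturbance extends over its own radius
            double dd = std::max(dist - macs(mc, 2), 0.5);
            double rr = macs(mc, 2) / dd;
            double w = gate * v0 * std::min(rr * rr, 1.0);
            vx_ += w * dxm / std::max(dist, 1e-9);
            vz_ += w * dzm / std::max(dist, 1e-9);
          }
        }
        if (vx_ != 0.0 || vz_ != 0.0) {
          for (int i = 0; i < P.nv; ++i) {
            px[o + i] += vx_ * P.dt;
            pz[o + i] += vz_ * P.dt;
          }
        }
      }
    }

    time += P.dt;
    ++gstep;

    if (snap_now) {
      snap_t[isnap] = time;
      for (int c = 0; c < P.ncell; ++c) {
        int o = c * P.nv;
        double cx = 0, cz = 0, cvx = 0, cvz = 0;
        int nb = 0;
        for (int i = 0; i < P.nv; ++i) {
          cx += px[o + i];
          cz += pz[o + i];
          cvx += vx[o + i];
          cvz += vz[o + i];
          nb += bond_on[o + i];
        }
        snap_comx(isnap, c) = cx / P.nv;
        snap_comz(isnap, c) = cz / P.nv;
        snap_speed(isnap, c) = std::sqrt(cvx * cvx + cvz * cvz) / P.nv;
        snap_nb(isnap, c) = nb;
        snap_gap(isnap, c) = gapmin[c];
        snap_cluster(isnap, c) = uf_find(c) + 1;
        gapmin[c] = std::numeric_limits<double>::infinity();
      }
      ++isnap;
    }

    if ((s & 1023) == 0) {
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(px[i]) || !std::isfinite(pz[i]))
          stop("non-finite position at step %d: timestep too large or "
               "unstable configuration",
               (int)gstep);
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    if (!std::isfinite(px[i]) || !std::isfinite(pz[i]) ||
        !std::isfinite(vx[i]) || !std::isfinite(vz[i]))
      stop("non-finite state at end of run: timestep too large");
  }

  for (int i = 0; i < n; ++i) {
    pos(i, 0) = px[i];
    pos(i, 1) = pz[i];
    vel(i, 0) = vx[i];
    vel(i, 1) = vz[i];
  }
  List out_state = List::create(
      _["pos"] = pos, _["vel"] = vel, _["nv"] = P.nv, _["l0"] = state["l0"],
      _["theta0"] = state["theta0"], _["A0"] = state["A0"],
      _["bond_on"] = bond_on, _["bond_ax"] = bond_ax, _["bond_az"] = bond_az,
      _["bond_t"] = bond_t, _["time"] = time, _["step"] = (double)gstep);
  List snaps = List::create(
      _["t"] = snap_t, _["comx"] = snap_comx, _["comz"] = snap_comz,
      _["speed"] = snap_speed, _["nb"] = snap_nb, _["gapmin"] = snap_gap,
      _["cluster"] = snap_cluster);
  return List::create(_["state"] = out_state, _["snapshots"] = snaps,
                      _["area"] = NumericVector(area_now.begin(),
                                                area_now.end()));
}
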