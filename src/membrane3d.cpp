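// Coarse-grained 3D RBC membrane: wormlike-chain + power-law springs on the
// edge network, dihedral-angle bending energy, local (per-triangle) and
// global area penalties, and a global volume penalty. Forces are analytic
// gradients of the energy; consistency is enforced by finite-difference
// tests on random configurations.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct V3 {
  double x, y, z;
};
inline V3 sub(const V3& a, const V3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline V3 cross(const V3& a, const V3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(const V3& a, const V3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }
inline V3 scale(const V3& a, double s) { return {a.x * s, a.y * s, a.z * s}; }

// WLC + POW edge tension; positive = contractile. x = L / Lmax.
inline double edge_tension(double L, double Lmax, double kT_over_p,
                           double kp) {
  double x = L / Lmax;
  double wlc = kT_over_p * (0.25 / ((1.0 - x) * (1.0 - x)) - 0.25 + x);
  return wlc - kp / (L * L);
}

inline double edge_energy(double L, double Lmax, double kT_over_p,
                          double kp) {
  double x = L / Lmax;
  double wlc = kT_over_p * Lmax * (3.0 * x * x - 2.0 * x * x * x) /
               (4.0 * (1.0 - x));
  return wlc + kp / L;
}

}  // namespace

// [[Rcpp::export]]
List membrane3d_forces(NumericMatrix pos, IntegerMatrix edges,
                       IntegerMatrix tris, IntegerMatrix dihed, List params) {
  const int n = pos.nrow();
  const int ne = edges.nrow();
  const int nt = tris.nrow();
  const double kT_over_p = as<double>(params["kT_over_p"]);
  const double kb = as<double>(params["k_bend"]);
  const double kd = as<double>(params["k_area_local"]);
  const double ka = as<double>(params["k_area_global"]);
  const double kv = as<double>(params["k_volume"]);
  NumericVector Lmax = as<NumericVector>(params["Lmax"]);
  NumericVector kp = as<NumericVector>(params["kp"]);
  NumericVector theta0 = as<NumericVector>(params["theta0"]);
  NumericVector At0 = as<NumericVector>(params["At0"]);
  const double A0 = as<double>(params["A0"]);
  const double V0 = as<double>(params["V0"]);

  std::vector<V3> x(n);
  for (int i = 0; i < n; ++i) x[i] = {pos(i, 0), pos(i, 1), pos(i, 2)};
  std::vector<V3> f(n, {0, 0, 0});
  double E_spring = 0, E_bend = 0, E_area = 0, E_vol = 0;

  // springs
  for (int e = 0; e < ne; ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    V3 d = sub(x[a], x[b]);
    double L = norm(d);
    if (L >= Lmax[e])
      stop("edge %d length %.4f exceeds the WLC maximum extension %.4f: "
           "spring model undefined beyond it",
           e + 1, L, (double)Lmax[e]);
    E_spring += edge_energy(L, Lmax[e], kT_over_p, kp[e]);
    double T = edge_tension(L, Lmax[e], kT_over_p, kp[e]);
    V3 g = scale(d, T / L);  // dE/dxa
    f[a].x -= g.x;
    f[a].y -= g.y;
    f[a].z -= g.z;
    f[b].x += g.x;
    f[b].y += g.y;
    f[b].z += g.z;
  }

  // per-triangle areas + normals; local/global area + volume
  double A = 0, V = 0;
  std::vector<V3> tn(nt);
  std::vector<double> ta(nt);
  for (int t = 0; t < nt; ++t) {
    int a = tris(t, 0), b = tris(t, 1), c = tris(t, 2);
    V3 nrm = cross(sub(x[b], x[a]), sub(x[c], x[a]));
    double a2 = norm(nrm);
    tn[t] = scale(nrm, 1.0 / a2);
    ta[t] = 0.5 * a2;
    A += ta[t];
    V += dot(x[a], cross(x[b], x[c])) / 6.0;
  }
  double dAg = A - A0;
  double dV = V - V0;
  double ca = 0.0, cv = 0.0;
  if (ka > 0) {
    E_area += 0.5 * ka * dAg * dAg / A0;
    ca = -ka * dAg / A0;
  }
  if (kv > 0) {
    E_vol += 0.5 * kv * dV * dV / V0;
    cv = -kv * dV / V0;
  }
  for (int t = 0; t < nt; ++t) {
    int a = tris(t, 0), b = tris(t, 1), c = tris(t, 2);
    double dAl = ta[t] - At0[t];
    double cl = ca;
    if (kd > 0) {
      E_area += 0.5 * kd * dAl * dAl / At0[t];
      cl += -kd * dAl / At0[t];
    }
    V3 ga = scale(cross(tn[t], sub(x[c], x[b])), 0.5);
    V3 gb = scale(cross(tn[t], sub(x[a], x[c])), 0.5);
    V3 gc = scale(cross(tn[t], sub(x[b], x[a])), 0.5);
    f[a].x += cl * ga.x;
    f[a].y += cl * ga.y;
    f[a].z += cl * ga.z;
    f[b].x += cl * gb.x;
    f[b].y += cl * gb.y;
    f[b].z += cl * gb.z;
    f[c].x += cl * gc.x;
    f[c].y += cl * gc.y;
    f[c].z += cl * gc.z;
    // volume gradients: d/dxa [a.(b x c)]/6
    V3 va = scale(cross(x[b], x[c]), 1.0 / 6.0);
    V3 vb = scale(cross(x[c], x[a]), 1.0 / 6.0);
    V3 vc = scale(cross(x[a], x[b]), 1.0 / 6.0);
    f[a].x += cv * va.x;
    f[a].y += cv * va.y;
    f[a].z += cv * va.z;
    f[b].x += cv * vb.x;
    f[b].y += cv * vb.y;
    f[b].z += cv * vb.z;
    f[c].x += cv * vc.x;
    f[c].y += cv * vc.y;
    f[c].z += cv * vc.z;
  }

  // bending on dihedrals: columns (a, b, c, d) = edge a-b, opposite c
  // (triangle a,b,c) and d (triangle b,a,d)
  if (kb > 0) {
    for (int e = 0; e < dihed.nrow(); ++e) {
      int a = dihed(e, 0), b = dihed(e, 1), c = dihed(e, 2), d = dihed(e, 3);
      V3 ev = sub(x[b], x[a]);
      double le = norm(ev);
      V3 n1 = cross(sub(x[b], x[a]), sub(x[c], x[a]));
      V3 n2 = cross(sub(x[a], x[b]), sub(x[d], x[b]));
      double n1n = dot(n1, n1), n2n = dot(n2, n2);
      double inv = 1.0 / std::sqrt(n1n * n2n);
      double cth = dot(n1, n2) * inv;
      double sth = dot(cross(n1, n2), ev) * inv / le;
      double th = std::atan2(sth, cth);
      E_bend += kb * (1.0 - std::cos(th - theta0[e]));
      double dEdth = kb * std::sin(th - theta0[e]);
      // dihedral angle gradients: with t3, t4 the edge-line projection
      // parameters of the opposite vertices, grad_c = |e| n1/|n1|^2,
      // grad_d = |e| n2/|n2|^2, and the edge endpoints carry the
      // complementary barycentric weights (translation invariant).
      V3 gc = scale(n1, -le / n1n);
      V3 gd = scale(n2, -le / n2n);
      double t3 = dot(sub(x[c], x[a]), ev) / (le * le);
      double t4 = dot(sub(x[d], x[a]), ev) / (le * le);
      V3 ga = {-(1.0 - t3) * gc.x - (1.0 - t4) * gd.x,
               -(1.0 - t3) * gc.y - (1.0 - t4) * gd.y,
               -(1.0 - t3) * gc.z - (1.0 - t4) * gd.z};
      V3 gb = {-t3 * gc.x - t4 * gd.x, -t3 * gc.y - t4 * gd.y,
               -t3 * gc.z - t4 * gd.z};
      // F = -dE/dx = -dEdth * grad theta
      f[a].x -= dEdth * ga.x;
      f[a].y -= dEdth * ga.y;
      f[a].z -= dEdth * ga.z;
      f[b].x -= dEdth * gb.x;
      f[b].y -= dEdth * gb.y;
      f[b].z -= dEdth * gb.z;
      f[c].x -= dEdth * gc.x;
      f[c].y -= dEdth * gc.y;
      f[c].z -= dEdth * gc.z;
      f[d].x -= dEdth * gd.x;
      f[d].y -= dEdth * gd.y;
      f[d].z -= dEdth * gd.z;
    }
  }

  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) {
    F(i, 0) = f[i].x;
    F(i, 1) = f[i].y;
    F(i, 2) = f[i].z;
  }
  return List::create(
      _["energy"] = E_spring + E_bend + E_area + E_vol, _["forces"] = F,
      _["area"] = A, _["volume"] = V,
      _["parts"] = NumericVector::create(
          _["spring"] = E_spring, _["bend"] = E_bend, _["area"] = E_area,
          _["volume"] = E_vol));
}

// Overdamped relaxation x <- x + (F + Fext) * dt_over_zeta, used by the
// stretch-test harness and equilibrium checks.
// [[Rcpp::export]]
NumericMatrix membrane3d_relax(NumericMatrix pos, IntegerMatrix edges,
                               IntegerMatrix tris, IntegerMatrix dihed,
                               List params, NumericMatrix fext, int n_steps,
                               double dt_over_zeta) {
  NumericMatrix x = clone(pos);
  for (int s = 0; s < n_steps; ++s) {
    List out = membrane3d_forces(x, edges, tris, dihed, params);
    NumericMatrix F = out["forces"];
    for (int i = 0; i < x.nrow(); ++i) {
      x(i, 0) += dt_over_zeta * (F(i, 0) + fext(i, 0));
      x(i, 1) += dt_over_zeta * (F(i, 1) + fext(i, 1));
      x(i, 2) += dt_over_zeta * (F(i, 2) + fext(i, 2));
    }
  }
  return x;
}
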