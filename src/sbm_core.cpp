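// Structure-based-model potential, analytic forces, and Langevin dynamics.
// All quantities in reduced units: kB = 1, mass = 1, lengths in Angstrom.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_set>
using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3(double x_ = 0, double y_ = 0, double z_ = 0) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm2() const { return x * x + y * y + z * z; }
  double norm() const { return std::sqrt(norm2()); }
};

// Topology unpacked from the R-side SBMTopology object (indices 0-based here).
struct Topo {
  std::vector<int> b_i, b_j;                    std::vector<double> r0;
  std::vector<int> a_i, a_j, a_k;               std::vector<double> th0;
  std::vector<int> p_i, p_j, p_k, p_l;          std::vector<double> xi0;
  std::vector<int> d_i, d_j, d_k, d_l;          std::vector<double> phi0;
  std::vector<int> d_bb;        // 1 = backbone class
  std::vector<int> d_on;        // 1 = restrained (constrained flag)
  std::vector<int> c_i, c_j;                    std::vector<double> sigma;
  std::vector<int> nc_i, nc_j;  // non-contact repulsion pairs
  int n_atoms;
};

struct Params {
  double eps_r, eps_theta, eps_xi, eps_phi_bb, eps_phi_sc;
  double eps_contact, eps_nc, sigma_nc;
};

static inline long pair_key(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (long)i * n + j;
}

static Topo unpack_topo(const List& topo) {
  Topo t;
  t.n_atoms = as<int>(topo["n_atoms"]);
  IntegerMatrix B = topo["bonds"];
  NumericVector r0 = topo["r0"];
  for (int k = 0; k < B.nrow(); ++k) {
    t.b_i.push_back(B(k, 0) - 1); t.b_j.push_back(B(k, 1) - 1);
    t.r0.push_back(r0[k]);
  }
  IntegerMatrix A = topo["angles"];
  NumericVector th0 = topo["theta0"];
  for (int k = 0; k < A.nrow(); ++k) {
    t.a_i.push_back(A(k, 0) - 1); t.a_j.push_back(A(k, 1) - 1);
    t.a_k.push_back(A(k, 2) - 1); t.th0.push_back(th0[k]);
  }
  IntegerMatrix P = topo["planars"];
  NumericVector xi0 = topo["xi0"];
  for (int k = 0; k < P.nrow(); ++k) {
    t.p_i.push_back(P(k, 0) - 1); t.p_j.push_back(P(k, 1) - 1);
    t.p_k.push_back(P(k, 2) - 1); t.p_l.push_back(P(k, 3) - 1);
    t.xi0.push_back(xi0[k]);
  }
  IntegerMatrix D = topo["dihedrals"];
  NumericVector phi0 = topo["phi0"];
  IntegerVector bb = topo["dihedral_bb"], on = topo["dihedral_on"];
  for (int k = 0; k < D.nrow(); ++k) {
    t.d_i.push_back(D(k, 0) - 1); t.d_j.push_back(D(k, 1) - 1);
    t.d_k.push_back(D(k, 2) - 1); t.d_l.push_back(D(k, 3) - 1);
    t.phi0.push_back(phi0[k]); t.d_bb.push_back(bb[k]); t.d_on.push_back(on[k]);
  }
  IntegerMatrix C = topo["contacts"];
  NumericVector sg = topo["sigma"];
  for (int k = 0; k < C.nrow(); ++k) {
    t.c_i.push_back(C(k, 0) - 1); t.c_j.push_back(C(k, 1) - 1);
    t.sigma.push_back(sg[k]);
  }
  // Non-contact pairs: every i<j not excluded (bonded/1-3/1-4/contact pairs
  // and explicitly excluded pairs arrive pre-merged from R).
  IntegerMatrix E = topo["exclusions"];
  std::unordered_set<long> excl;
  for (int k = 0; k < E.nrow(); ++k)
    excl.insert(pair_key(E(k, 0) - 1, E(k, 1) - 1, t.n_atoms));
  for (size_t k = 0; k < t.c_i.size(); ++k)
    excl.insert(pair_key(t.c_i[k], t.c_j[k], t.n_atoms));
  for (int i = 0; i < t.n_atoms; ++i)
    for (int j = i + 1; j < t.n_atoms; ++j)
      if (!excl.count(pair_key(i, j, t.n_atoms))) {
        t.nc_i.push_back(i); t.nc_j.push_back(j);
      }
  return t;
}

static Params unpack_params(const List& p) {
  Params q;
  q.eps_r = as<double>(p["eps_r"]);
  q.eps_theta = as<double>(p["eps_theta"]);
  q.eps_xi = as<double>(p["eps_xi"]);
  q.eps_phi_bb = as<double>(p["eps_phi_bb"]);
  q.eps_phi_sc = as<double>(p["eps_phi_sc"]);
  q.eps_contact = as<double>(p["eps_contact"]);
  q.eps_nc = as<double>(p["eps_nc"]);
  q.sigma_nc = as<double>(p["sigma_nc"]);
  return q;
}

// Dihedral angle and its gradient w.r.t. the four atoms.
static double dihedral_angle(const Vec3& x1, const Vec3& x2, const Vec3& x3,
                             const Vec3& x4, Vec3 g[4], bool want_grad) {
  Vec3 b1 = x2 - x1, b2 = x3 - x2, b3 = x4 - x3;
  Vec3 c1 = b1.cross(b2), c2 = b2.cross(b3);
  double nb2 = b2.norm();
  double phi = std::atan2(c1.cross(c2).dot(b2) / nb2, c1.dot(c2));
  if (want_grad) {
    double ic1 = 1.0 / c1.norm2(), ic2 = 1.0 / c2.norm2();
    Vec3 g1 = c1 * (-nb2 * ic1);
    Vec3 g4 = c2 * (nb2 * ic2);
    double s = b1.dot(b2) / (nb2 * nb2), t = b3.dot(b2) / (nb2 * nb2);
    g[0] = g1;
    g[1] = g1 * (-(1.0 + s)) + g4 * t;
    g[2] = g1 * s - g4 * (1.0 + t);
    g[3] = g4;
  }
  return phi;
}

static inline double wrap_pi(double d) {
  while (d > M_PI) d -= 2 * M_PI;
  while (d < -M_PI) d += 2 * M_PI;
  return d;
}

// Fd(phi) = [1 - cos(phi - phi0)] + (1/2)[1 - cos(3(phi - phi0))]
static inline double fd_dihedral(double dphi) {
  return (1.0 - std::cos(dphi)) + 0.5 * (1.0 - std::cos(3.0 * dphi));
}
static inline double fd_dihedral_deriv(double dphi) {
  return std::sin(dphi) + 1.5 * std::sin(3.0 * dphi);
}

// Evaluate potential; accumulate forces (-grad V) into F if not null.
static NumericVector eval_potential(const std::vector<Vec3>& x, const Topo& t,
                                    const Params& p, std::vector<Vec3>* F) {
  double e_bond = 0, e_angle = 0, e_planar = 0, e_dbb = 0, e_dsc = 0,
         e_con = 0, e_nc = 0;
  for (size_t k = 0; k < t.b_i.size(); ++k) {
    Vec3 d = x[t.b_j[k]] - x[t.b_i[k]];
    double r = d.norm(), dr = r - t.r0[k];
    e_bond += p.eps_r * dr * dr;
    if (F) {
      Vec3 f = d * (2.0 * p.eps_r * dr / r);
      (*F)[t.b_i[k]] = (*F)[t.b_i[k]] + f;
      (*F)[t.b_j[k]] = (*F)[t.b_j[k]] - f;
    }
  }
  for (size_t k = 0; k < t.a_i.size(); ++k) {
    const Vec3 &xi = x[t.a_i[k]], &xj = x[t.a_j[k]], &xk = x[t.a_k[k]];
    Vec3 u = xi - xj, v = xk - xj;
    double nu = u.norm(), nv = v.norm();
    double cth = u.dot(v) / (nu * nv);
    cth = std::max(-1.0, std::min(1.0, cth));
    double th = std::acos(cth), dth = th - t.th0[k];
    e_angle += p.eps_theta * dth * dth;
    if (F) {
      double sth = std::sqrt(std::max(1e-12, 1.0 - cth * cth));
      Vec3 uh = u * (1.0 / nu), vh = v * (1.0 / nv);
      Vec3 di = (uh * cth - vh) * (1.0 / (nu * sth));
      Vec3 dk = (vh * cth - uh) * (1.0 / (nv * sth));
      double c = -2.0 * p.eps_theta * dth;  // force = -dV/dtheta * dtheta/dx
      (*F)[t.a_i[k]] = (*F)[t.a_i[k]] + di * c;
      (*F)[t.a_k[k]] = (*F)[t.a_k[k]] + dk * c;
      (*F)[t.a_j[k]] = (*F)[t.a_j[k]] - (di + dk) * c;
    }
  }
  Vec3 g[4];
  for (size_t k = 0; k < t.p_i.size(); ++k) {
    int ia = t.p_i[k], ib = t.p_j[k], ic = t.p_k[k], id = t.p_l[k];
    double xi = dihedral_angle(x[ia], x[ib], x[ic], x[id], g, F != nullptr);
    double dxi = wrap_pi(xi - t.xi0[k]);
    e_planar += p.eps_xi * dxi * dxi;
    if (F) {
      double c = -2.0 * p.eps_xi * dxi;
      (*F)[ia] = (*F)[ia] + g[0] * c; (*F)[ib] = (*F)[ib] + g[1] * c;
      (*F)[ic] = (*F)[ic] + g[2] * c; (*F)[id] = (*F)[id] + g[3] * c;
    }
  }
  for (size_t k = 0; k < t.d_i.size(); ++k) {
    if (!t.d_on[k]) continue;  // linker dihedrals: restraint released
    int ia = t.d_i[k], ib = t.d_j[k], ic = t.d_k[k], id = t.d_l[k];
    double eps = t.d_bb[k] ? p.eps_phi_bb : p.eps_phi_sc;
    double phi = dihedral_angle(x[ia], x[ib], x[ic], x[id], g, F != nullptr);
    double dphi = phi - t.phi0[k];
    double e = eps * fd_dihedral(dphi);
    if (t.d_bb[k]) e_dbb += e; else e_dsc += e;
    if (F) {
      double c = -eps * fd_dihedral_deriv(dphi);
      (*F)[ia] = (*F)[ia] + g[0] * c; (*F)[ib] = (*F)[ib] + g[1] * c;
      (*F)[ic] = (*F)[ic] + g[2] * c; (*F)[id] = (*F)[id] + g[3] * c;
    }
  }
  for (size_t k = 0; k < t.c_i.size(); ++k) {
    Vec3 d = x[t.c_j[k]] - x[t.c_i[k]];
    double r2 = d.norm2(), s2 = t.sigma[k] * t.sigma[k];
    double sr2 = s2 / r2, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
    e_con += p.eps_contact * (sr12 - 2.0 * sr6);
    if (F) {
      // dV/dr * (1/r) = eps * (-12 sr12 + 12 sr6) / r^2
      double c = p.eps_contact * 12.0 * (sr12 - sr6) / r2;  // force = +c*d on j
      (*F)[t.c_j[k]] = (*F)[t.c_j[k]] + d * c;
      (*F)[t.c_i[k]] = (*F)[t.c_i[k]] - d * c;
    }
  }
  double snc2 = p.sigma_nc * p.sigma_nc;
  for (size_t k = 0; k < t.nc_i.size(); ++k) {
    Vec3 d = x[t.nc_j[k]] - x[t.nc_i[k]];
    double r2 = d.norm2();
    double sr2 = snc2 / r2, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
    e_nc += p.eps_nc * sr12;
    if (F) {
      double c = p.eps_nc * 12.0 * sr12 / r2;
      (*F)[t.nc_j[k]] = (*F)[t.nc_j[k]] + d * c;
      (*F)[t.nc_i[k]] = (*F)[t.nc_i[k]] - d * c;
    }
  }
  double total = e_bond + e_angle + e_planar + e_dbb + e_dsc + e_con + e_nc;
  return NumericVector::create(
      _["bond"] = e_bond, _["angle"] = e_angle, _["planar"] = e_planar,
      _["dihedral_bb"] = e_dbb, _["dihedral_sc"] = e_dsc,
      _["contact"] = e_con, _["noncontact"] = e_nc, _["total"] = total);
}

static std::vector<Vec3> mat_to_vec(const NumericMatrix& m) {
  std::vector<Vec3> x(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) x[i] = Vec3(m(i, 0), m(i, 1), m(i, 2));
  return x;
}

// [[Rcpp::export]]
NumericVector cpp_sbm_energy(NumericMatrix xyz, List topo, List params) {
  Topo t = unpack_topo(topo);
  Params p = unpack_params(params);
  std::vector<Vec3> x = mat_to_vec(xyz);
  return eval_potential(x, t, p, nullptr);
}

// [[Rcpp::export]]
NumericMatrix cpp_sbm_forces(NumericMatrix xyz, List topo, List params) {
  Topo t = unpack_topo(topo);
  Params p = unpack_params(params);
  std::vector<Vec3> x = mat_to_vec(xyz);
  std::vector<Vec3> F(x.size());
  eval_potential(x, t, p, &F);
  NumericMatrix out(xyz.nrow(), 3);
  for (int i = 0; i < xyz.nrow(); ++i) {
    out(i, 0) = F[i].x; out(i, 1) = F[i].y; out(i, 2) = F[i].z;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_dihedral_angle(NumericMatrix xyz) {
  Vec3 g[4];
  std::vector<Vec3> x = mat_to_vec(xyz);
  return dihedral_angle(x[0], x[1], x[2], x[3], g, false);
}

// Langevin dynamics, BAOAB splitting. friction = 0 (or thermostat = FALSE)
// degenerates exactly to velocity Verlet (NVE). Uses R's RNG.
// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix xyz, List topo, List params,
                      double temperature, double dt, double friction,
                      int n_steps, int record_every, bool thermostat,
                      double guard, bool init_velocities) {
  Topo t = unpack_topo(topo);
  Params p = unpack_params(params);
  std::vector<Vec3> x = mat_to_vec(xyz);
  int n = (int)x.size();
  std::vector<Vec3> v(n), F(n);
  if (init_velocities && temperature > 0) {
    double s = std::sqrt(temperature);
    for (int i = 0; i < n; ++i)
      v[i] = Vec3(s * norm_rand(), s * norm_rand(), s * norm_rand());
  }
  double c1 = 1.0, c2 = 0.0;
  bool ou = thermostat && friction > 0;
  if (ou) {
    c1 = std::exp(-friction * dt);
    c2 = std::sqrt(std::max(0.0, temperature * (1.0 - c1 * c1)));
  }
  eval_potential(x, t, p, &F);
  int n_frames = n_steps / record_every;
  List frames(n_frames);
  NumericMatrix energies(n_frames, 10);  // 8 potential cols + KE + step
  int fr = 0;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {  // B
      v[i] = v[i] + F[i] * (0.5 * dt);
      x[i] = x[i] + v[i] * (0.5 * dt);  // A
    }
    if (ou)  // O
      for (int i = 0; i < n; ++i)
        v[i] = v[i] * c1 + Vec3(c2 * norm_rand(), c2 * norm_rand(),
                                c2 * norm_rand());
    for (int i = 0; i < n; ++i) x[i] = x[i] + v[i] * (0.5 * dt);  // A
    std::fill(F.begin(), F.end(), Vec3());
    NumericVector e;
    bool record = (step % record_every == 0);
    if (record) e = eval_potential(x, t, p, &F);
    else eval_potential(x, t, p, &F);
    for (int i = 0; i < n; ++i) v[i] = v[i] + F[i] * (0.5 * dt);  // B
    if (step % 100 == 0 || record) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(x[i].x) || !std::isfinite(x[i].y) ||
            !std::isfinite(x[i].z) || std::fabs(x[i].x) > guard ||
            std::fabs(x[i].y) > guard || std::fabs(x[i].z) > guard)
          stop("simulation diverged at step %d (coordinate guard)", step);
    }
    if (record) {
      if (!std::isfinite(e["total"]))
        stop("simulation diverged at step %d (non-finite energy)", step);
      NumericMatrix fm(n, 3);
      double ke = 0;
      for (int i = 0; i < n; ++i) {
        fm(i, 0) = x[i].x; fm(i, 1) = x[i].y; fm(i, 2) = x[i].z;
        ke += 0.5 * v[i].norm2();
      }
      frames[fr] = fm;
      for (int c = 0; c < 8; ++c) energies(fr, c) = e[c];
      energies(fr, 8) = ke;
      energies(fr, 9) = step;
      ++fr;
    }
  }
  return List::create(_["frames"] = frames, _["energies"] = energies);
}
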