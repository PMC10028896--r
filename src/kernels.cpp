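// Compiled kernels for the alchemical potential, forces, Langevin (BAOAB)
// propagation and the replica-exchange swap sweep. The R layer compiles a
// hybrid system into the flat arrays consumed here (see compile_hybrid()).
// Units: nm, kcal/mol, e, amu, ps. R's RNG is used throughout so results
// are reproducible with set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double KCAL_TO_KJ = 4.184;  // kcal/mol -> amu nm^2/ps^2

struct Compiled {
  int n;
  IntegerVector cls;          // 0 env, 1 core, 2 unique_old, 3 unique_new
  NumericVector q_old, q_new, sig_old, sig_new, eps_old, eps_new, mass;
  IntegerVector pi, pj;       // 0-based pair indices (exclusions removed)
  IntegerVector p_lift_old, p_lift_new, p_rest;  // rest: 0 non, 1 inter, 2 rest
  // valence arrays, all 0-based indices; mode: 0 interp, 1 old*(1-l),
  // 2 new*l, 3 static old, 4 static new
  IntegerVector b_i, b_j, b_mode, b_rest;
  NumericVector b_k0, b_k1, b_r0, b_r1;
  IntegerVector a_i, a_j, a_k, a_mode, a_rest;
  NumericVector a_k0, a_k1, a_t0, a_t1;
  IntegerVector t_i, t_j, t_k, t_l, t_mode, t_rest;
  NumericVector t_b0, t_b1, t_p0, t_p1, t_f0, t_f1;
  IntegerVector r_i, r_mode, r_rest;
  NumericVector r_k0, r_k1, r_x0, r_y0, r_z0, r_x1, r_y1, r_z1;
  IntegerVector d_i, d_axis, d_mode, d_rest;
  NumericVector d_b0, d_b1, d_s0, d_s1, d_c0, d_c1, d_t0, d_t1;
  double w_lifting, screen_alpha, coulomb;
};

static Compiled unpack(const List& comp) {
  Compiled c;
  c.n = as<int>(comp["n"]);
  c.cls = comp["class"];
  c.q_old = comp["q_old"]; c.q_new = comp["q_new"];
  c.sig_old = comp["sigma_old"]; c.sig_new = comp["sigma_new"];
  c.eps_old = comp["eps_old"]; c.eps_new = comp["eps_new"];
  c.mass = comp["mass"];
  c.pi = comp["pair_i"]; c.pj = comp["pair_j"];
  c.p_lift_old = comp["pair_lift_old"]; c.p_lift_new = comp["pair_lift_new"];
  c.p_rest = comp["pair_rest"];
  c.b_i = comp["b_i"]; c.b_j = comp["b_j"]; c.b_mode = comp["b_mode"];
  c.b_rest = comp["b_rest"];
  c.b_k0 = comp["b_k0"]; c.b_k1 = comp["b_k1"];
  c.b_r0 = comp["b_r0"]; c.b_r1 = comp["b_r1"];
  c.a_i = comp["a_i"]; c.a_j = comp["a_j"]; c.a_k = comp["a_k"];
  c.a_mode = comp["a_mode"]; c.a_rest = comp["a_rest"];
  c.a_k0 = comp["a_k0"]; c.a_k1 = comp["a_k1"];
  c.a_t0 = comp["a_t0"]; c.a_t1 = comp["a_t1"];
  c.t_i = comp["t_i"]; c.t_j = comp["t_j"]; c.t_k = comp["t_k"];
  c.t_l = comp["t_l"]; c.t_mode = comp["t_mode"]; c.t_rest = comp["t_rest"];
  c.t_b0 = comp["t_b0"]; c.t_b1 = comp["t_b1"];
  c.t_p0 = comp["t_p0"]; c.t_p1 = comp["t_p1"];
  c.t_f0 = comp["t_f0"]; c.t_f1 = comp["t_f1"];
  c.r_i = comp["r_i"]; c.r_mode = comp["r_mode"]; c.r_rest = comp["r_rest"];
  c.r_k0 = comp["r_k0"]; c.r_k1 = comp["r_k1"];
  c.r_x0 = comp["r_x0"]; c.r_y0 = comp["r_y0"]; c.r_z0 = comp["r_z0"];
  c.r_x1 = comp["r_x1"]; c.r_y1 = comp["r_y1"]; c.r_z1 = comp["r_z1"];
  c.d_i = comp["d_i"]; c.d_axis = comp["d_axis"]; c.d_mode = comp["d_mode"];
  c.d_rest = comp["d_rest"];
  c.d_b0 = comp["d_b0"]; c.d_b1 = comp["d_b1"];
  c.d_s0 = comp["d_s0"]; c.d_s1 = comp["d_s1"];
  c.d_c0 = comp["d_c0"]; c.d_c1 = comp["d_c1"];
  c.d_t0 = comp["d_t0"]; c.d_t1 = comp["d_t1"];
  c.w_lifting = as<double>(comp["w_lifting"]);
  c.screen_alpha = as<double>(comp["screening_alpha"]);
  c.coulomb = as<double>(comp["coulomb_constant"]);
  return c;
}

// per-atom interpolated nonbonded parameters at lambda
static inline double q_at(const Compiled& c, int i, double l) {
  switch (c.cls[i]) {
    case 0: return c.q_old[i];
    case 1: return (1 - l) * c.q_old[i] + l * c.q_new[i];
    case 2: return (1 - l) * c.q_old[i];
    default: return l * c.q_new[i];
  }
}
static inline double sig_at(const Compiled& c, int i, double l) {
  switch (c.cls[i]) {
    case 0: return c.sig_old[i];
    case 1: return (1 - l) * c.sig_old[i] + l * c.sig_new[i];
    case 2: return c.sig_old[i];
    default: return c.sig_new[i];
  }
}
static inline double eps_at(const Compiled& c, int i, double l) {
  switch (c.cls[i]) {
    case 0: return c.eps_old[i];
    case 1: return (1 - l) * c.eps_old[i] + l * c.eps_new[i];
    case 2: return (1 - l) * c.eps_old[i];
    default: return l * c.eps_new[i];
  }
}

// mode weights: scale and interpolation fraction for valence parameters
static inline void mode_weights(int mode, double l, double& scale, double& frac) {
  switch (mode) {
    case 0: scale = 1.0; frac = l; break;        // interpolate parameters
    case 1: scale = 1.0 - l; frac = 0.0; break;  // old-only mapped term
    case 2: scale = l; frac = 1.0; break;        // new-only mapped term
    case 3: scale = 1.0; frac = 0.0; break;      // dummy old, always on
    default: scale = 1.0; frac = 1.0; break;     // dummy new, always on
  }
}

static inline double rest_factor(int cls, double srest, double sinter) {
  return cls == 2 ? srest : (cls == 1 ? sinter : 1.0);
}

// accumulate energy (and optionally forces) at one lambda
static double eval_all(const Compiled& c, const NumericMatrix& x, double l,
                       double srest, double sinter, bool want_forces,
                       NumericMatrix* F, double* comp3) {
  double e_el = 0, e_lj = 0, e_val = 0;
  const int npair = c.pi.size();
  for (int p = 0; p < npair; ++p) {
    const int i = c.pi[p], j = c.pj[p];
    double dx = x(i, 0) - x(j, 0), dy = x(i, 1) - x(j, 1), dz = x(i, 2) - x(j, 2);
    double r2 = dx * dx + dy * dy + dz * dz;
    double w = c.w_lifting * (c.p_lift_old[p] * l + c.p_lift_new[p] * (1 - l));
    double s2 = r2 + w * w;
    double qq = q_at(c, i, l) * q_at(c, j, l);
    double ei = eps_at(c, i, l), ej = eps_at(c, j, l);
    double eps = std::sqrt(ei * ej);
    if (qq == 0 && eps == 0) continue;
    double fac = rest_factor(c.p_rest[p], srest, sinter);
    if (s2 < 1e-24) {  // coincident, unlifted, interacting: singular
      e_el = R_PosInf;
      continue;
    }
    double s = std::sqrt(s2);
    double dUds = 0;
    if (qq != 0) {
      double ec;
      if (c.screen_alpha > 0) {
        double as = c.screen_alpha * s;
        double er = std::erfc(as);
        ec = c.coulomb * qq * er / s;
        if (want_forces)
          dUds += -c.coulomb * qq * (er / s2 +
            2.0 * c.screen_alpha * std::exp(-as * as) / (std::sqrt(M_PI) * s));
      } else {
        ec = c.coulomb * qq / s;
        if (want_forces) dUds += -ec / s;
      }
      e_el += fac * ec;
    }
    if (eps > 0) {
      double sig = 0.5 * (sig_at(c, i, l) + sig_at(c, j, l));
      double sr2 = sig * sig / s2;
      double x6 = sr2 * sr2 * sr2;
      e_lj += fac * 4.0 * eps * x6 * (x6 - 1.0);
      if (want_forces) dUds += -24.0 * eps * x6 * (2.0 * x6 - 1.0) / s;
    }
    if (want_forces && dUds != 0) {
      // dU/dr = dU/ds * r/s; force on i = -dU/dr * rhat
      double g = fac * dUds / s;  // = fac * dUds * (r/s) / r
      (*F)(i, 0) -= g * dx; (*F)(i, 1) -= g * dy; (*F)(i, 2) -= g * dz;
      (*F)(j, 0) += g * dx; (*F)(j, 1) += g * dy; (*F)(j, 2) += g * dz;
    }
  }

  // bonds
  for (int t = 0; t < c.b_i.size(); ++t) {
    double scale, frac; mode_weights(c.b_mode[t], l, scale, frac);
    if (scale == 0) continue;
    double k = (1 - frac) * c.b_k0[t] + frac * c.b_k1[t];
    double r0 = (1 - frac) * c.b_r0[t] + frac * c.b_r1[t];
    int i = c.b_i[t], j = c.b_j[t];
    double dx = x(i, 0) - x(j, 0), dy = x(i, 1) - x(j, 1), dz = x(i, 2) - x(j, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double fac = scale * rest_factor(c.b_rest[t], srest, sinter);
    e_val += fac * 0.5 * k * (r - r0) * (r - r0);
    if (want_forces && r > 1e-12) {
      double g = fac * k * (r - r0) / r;
      (*F)(i, 0) -= g * dx; (*F)(i, 1) -= g * dy; (*F)(i, 2) -= g * dz;
      (*F)(j, 0) += g * dx; (*F)(j, 1) += g * dy; (*F)(j, 2) += g * dz;
    }
  }

  // angles
  for (int t = 0; t < c.a_i.size(); ++t) {
    double scale, frac; mode_weights(c.a_mode[t], l, scale, frac);
    if (scale == 0) continue;
    double k = (1 - frac) * c.a_k0[t] + frac * c.a_k1[t];
    double t0 = (1 - frac) * c.a_t0[t] + frac * c.a_t1[t];
    int i = c.a_i[t], j = c.a_j[t], m = c.a_k[t];
    double u[3] = {x(i,0)-x(j,0), x(i,1)-x(j,1), x(i,2)-x(j,2)};
    double v[3] = {x(m,0)-x(j,0), x(m,1)-x(j,1), x(m,2)-x(j,2)};
    double nu = std::sqrt(u[0]*u[0]+u[1]*u[1]+u[2]*u[2]);
    double nv = std::sqrt(v[0]*v[0]+v[1]*v[1]+v[2]*v[2]);
    if (nu < 1e-12 || nv < 1e-12) continue;
    double cosang = (u[0]*v[0]+u[1]*v[1]+u[2]*v[2]) / (nu * nv);
    cosang = std::max(-1.0, std::min(1.0, cosang));
    double th = std::acos(cosang);
    double fac = scale * rest_factor(c.a_rest[t], srest, sinter);
    e_val += fac * 0.5 * k * (th - t0) * (th - t0);
    if (want_forces) {
      double sinth = std::sqrt(std::max(1e-12, 1.0 - cosang * cosang));
      double dUdth = fac * k * (th - t0);
      // dtheta/du and dtheta/dv
      for (int d = 0; d < 3; ++d) {
        double dcos_du = v[d] / (nu * nv) - cosang * u[d] / (nu * nu);
        double dcos_dv = u[d] / (nu * nv) - cosang * v[d] / (nv * nv);
        double gi = dUdth * (-1.0 / sinth) * dcos_du;
        double gm = dUdth * (-1.0 / sinth) * dcos_dv;
        (*F)(i, d) -= gi;
        (*F)(m, d) -= gm;
        (*F)(j, d) += gi + gm;
      }
    }
  }

  // torsions: U = barrier * (1 + cos(n phi - phase))
  for (int t = 0; t < c.t_i.size(); ++t) {
    double scale, frac; mode_weights(c.t_mode[t], l, scale, frac);
    if (scale == 0) continue;
    double bar = (1 - frac) * c.t_b0[t] + frac * c.t_b1[t];
    double per = (1 - frac) * c.t_p0[t] + frac * c.t_p1[t];
    double pha = (1 - frac) * c.t_f0[t] + frac * c.t_f1[t];
    int ai = c.t_i[t], aj = c.t_j[t], ak = c.t_k[t], al = c.t_l[t];
    double b1[3] = {x(aj,0)-x(ai,0), x(aj,1)-x(ai,1), x(aj,2)-x(ai,2)};
    double b2[3] = {x(ak,0)-x(aj,0), x(ak,1)-x(aj,1), x(ak,2)-x(aj,2)};
    double b3[3] = {x(al,0)-x(ak,0), x(al,1)-x(ak,1), x(al,2)-x(ak,2)};
    double n1[3] = {b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2],
                    b1[0]*b2[1]-b1[1]*b2[0]};
    double n2[3] = {b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2],
                    b2[0]*b3[1]-b2[1]*b3[0]};
    double n1sq = n1[0]*n1[0]+n1[1]*n1[1]+n1[2]*n1[2];
    double n2sq = n2[0]*n2[0]+n2[1]*n2[1]+n2[2]*n2[2];
    double nb2 = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
    if (n1sq < 1e-18 || n2sq < 1e-18 || nb2 < 1e-12) continue;  // degenerate
    double m1[3] = {n1[1]*b2[2]-n1[2]*b2[1], n1[2]*b2[0]-n1[0]*b2[2],
                    n1[0]*b2[1]-n1[1]*b2[0]};
    double xv = n1[0]*n2[0]+n1[1]*n2[1]+n1[2]*n2[2];
    double yv = (m1[0]*n2[0]+m1[1]*n2[1]+m1[2]*n2[2]) / nb2;
    double phi = std::atan2(yv, xv);
    double fac = scale * rest_factor(c.t_rest[t], srest, sinter);
    e_val += fac * bar * (1.0 + std::cos(per * phi - pha));
    if (want_forces) {
      double dUdphi = -fac * bar * per * std::sin(per * phi - pha);
      // dphi/dr for the atan2 convention above (standard result)
      double s12 = (b1[0]*b2[0]+b1[1]*b2[1]+b1[2]*b2[2]) / (nb2 * nb2);
      double s32 = (b3[0]*b2[0]+b3[1]*b2[1]+b3[2]*b2[2]) / (nb2 * nb2);
      double dpdi[3], dpdl[3];
      for (int d = 0; d < 3; ++d) {
        dpdi[d] = nb2 * n1[d] / n1sq;
        dpdl[d] = -nb2 * n2[d] / n2sq;
      }
      for (int d = 0; d < 3; ++d) {
        double dpdj = -(1.0 + s12) * dpdi[d] + s32 * dpdl[d];
        double dpdk = s12 * dpdi[d] - (1.0 + s32) * dpdl[d];
        (*F)(ai, d) -= dUdphi * dpdi[d];
        (*F)(aj, d) -= dUdphi * dpdj;
        (*F)(ak, d) -= dUdphi * dpdk;
        (*F)(al, d) -= dUdphi * dpdl[d];
      }
    }
  }

  // positional restraints
  for (int t = 0; t < c.r_i.size(); ++t) {
    double scale, frac; mode_weights(c.r_mode[t], l, scale, frac);
    if (scale == 0) continue;
    double k = (1 - frac) * c.r_k0[t] + frac * c.r_k1[t];
    double px = (1 - frac) * c.r_x0[t] + frac * c.r_x1[t];
    double py = (1 - frac) * c.r_y0[t] + frac * c.r_y1[t];
    double pz = (1 - frac) * c.r_z0[t] + frac * c.r_z1[t];
    int i = c.r_i[t];
    double dx = x(i, 0) - px, dy = x(i, 1) - py, dz = x(i, 2) - pz;
    double fac = scale * rest_factor(c.r_rest[t], srest, sinter);
    e_val += fac * 0.5 * k * (dx * dx + dy * dy + dz * dz);
    if (want_forces) {
      (*F)(i, 0) -= fac * k * dx;
      (*F)(i, 1) -= fac * k * dy;
      (*F)(i, 2) -= fac * k * dz;
    }
  }

  // double wells: U = B (s~^2-1)^2 + tilt * s~, s~ = (x - center)/s0
  for (int t = 0; t < c.d_i.size(); ++t) {
    double scale, frac; mode_weights(c.d_mode[t], l, scale, frac);
    if (scale == 0) continue;
    double B = (1 - frac) * c.d_b0[t] + frac * c.d_b1[t];
    double s0 = (1 - frac) * c.d_s0[t] + frac * c.d_s1[t];
    double ce = (1 - frac) * c.d_c0[t] + frac * c.d_c1[t];
    double ti = (1 - frac) * c.d_t0[t] + frac * c.d_t1[t];
    int i = c.d_i[t], ax = c.d_axis[t];
    double s = (x(i, ax) - ce) / s0;
    double fac = scale * rest_factor(c.d_rest[t], srest, sinter);
    e_val += fac * (B * (s * s - 1.0) * (s * s - 1.0) + ti * s);
    if (want_forces) {
      double dUds = fac * (4.0 * B * s * (s * s - 1.0) + ti) / s0;
      (*F)(i, ax) -= dUds;
    }
  }

  if (comp3) { comp3[0] = e_el; comp3[1] = e_lj; comp3[2] = e_val; }
  return e_el + e_lj + e_val;
}

// [[Rcpp::export]]
NumericVector cpp_energy(List comp, NumericMatrix x, double lambda,
                         double srest, double sinter) {
  Compiled c = unpack(comp);
  double parts[3];
  double tot = eval_all(c, x, lambda, srest, sinter, false, nullptr, parts);
  return NumericVector::create(_["electrostatics"] = parts[0],
                               _["sterics"] = parts[1],
                               _["valence"] = parts[2],
                               _["total"] = tot);
}

// [[Rcpp::export]]
NumericVector cpp_state_energies(List comp, NumericMatrix x,
                                 NumericVector lambdas, NumericVector srest,
                                 NumericVector sinter) {
  Compiled c = unpack(comp);
  const int K = lambdas.size();
  NumericVector out(K);
  for (int k = 0; k < K; ++k) {
    out[k] = eval_all(c, x, lambdas[k], srest[k], sinter[k], false, nullptr,
                      nullptr);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(List comp, NumericMatrix x, double lambda,
                         double srest, double sinter) {
  Compiled c = unpack(comp);
  NumericMatrix F(x.nrow(), 3);
  eval_all(c, x, lambda, srest, sinter, true, &F, nullptr);
  return F;
}

// BAOAB Langevin integrator; kT in kcal/mol, dt in ps, friction in 1/ps.
// Returns updated positions and velocities. Uses R's RNG.
// [[Rcpp::export]]
List cpp_baoab(List comp, NumericMatrix x0, NumericMatrix v0, int n_steps,
               double dt, double friction, double kT, double lambda,
               double srest, double sinter) {
  Compiled c = unpack(comp);
  const int n = x0.nrow();
  NumericMatrix x = clone(x0), v = clone(v0);
  NumericMatrix F(n, 3);
  const double kT_md = kT * KCAL_TO_KJ;
  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);
  std::fill(F.begin(), F.end(), 0.0);
  eval_all(c, x, lambda, srest, sinter, true, &F, nullptr);
  for (int s = 0; s < n_steps; ++s) {
    for (int i = 0; i < n; ++i) {
      double im = KCAL_TO_KJ * dt * 0.5 / c.mass[i];
      for (int d = 0; d < 3; ++d) v(i, d) += im * F(i, d);
    }
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) x(i, d) += 0.5 * dt * v(i, d);
    for (int i = 0; i < n; ++i) {
      double sd = std::sqrt(kT_md / c.mass[i]);
      for (int d = 0; d < 3; ++d)
        v(i, d) = c1 * v(i, d) + c2 * sd * norm_rand();
    }
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) x(i, d) += 0.5 * dt * v(i, d);
    std::fill(F.begin(), F.end(), 0.0);
    eval_all(c, x, lambda, srest, sinter, true, &F, nullptr);
    for (int i = 0; i < n; ++i) {
      double im = KCAL_TO_KJ * dt * 0.5 / c.mass[i];
      for (int d = 0; d < 3; ++d) v(i, d) += im * F(i, d);
    }
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        if (!std::isfinite(x(i, d)))
          stop("non-finite coordinate during propagation (step %d)", s + 1);
  }
  return List::create(_["x"] = x, _["v"] = v);
}

// Full replica-exchange loop in compiled code: per iteration, propagate
// every replica at its current state with BAOAB, evaluate reduced
// potentials at all states (plus the two dU/dlambda stencil points), then
// perform a Metropolis swap sweep. Uses R's RNG throughout; the draw order
// (per-replica propagation noise, then swap uniforms) defines the seed
// contract. States recorded are those each replica was propagated at.
// [[Rcpp::export]]
List cpp_rex_run(List comp, NumericMatrix x0, NumericVector lambdas,
                 NumericVector srest,
                 NumericVector sinter, NumericVector lam_lo,
                 NumericVector lam_hi, NumericVector srest_lo,
                 NumericVector sinter_lo, NumericVector srest_hi,
                 NumericVector sinter_hi, int n_iter, int n_steps, double dt,
                 double friction, double kT, int n_attempts,
                 bool store_configs) {
  Compiled c = unpack(comp);
  const int K = lambdas.size();
  const int n = x0.nrow();
  const double kT_md = kT * KCAL_TO_KJ;
  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);

  // every replica starts at x0 with fresh Maxwell-Boltzmann velocities
  std::vector<NumericMatrix> X(K), V(K);
  for (int r = 0; r < K; ++r) {
    X[r] = clone(x0);
    NumericMatrix v(n, 3);
    for (int i = 0; i < n; ++i) {
      double sd = std::sqrt(kT_md / c.mass[i]);
      for (int d = 0; d < 3; ++d) v(i, d) = sd * norm_rand();
    }
    V[r] = v;
  }

  NumericVector u_out((R_xlen_t)K * K * n_iter);
  IntegerMatrix states(n_iter, K);
  NumericMatrix dudl(n_iter, K);
  NumericVector configs(store_configs ? (R_xlen_t)n * 3 * K * n_iter : 0);
  IntegerVector perm(K);
  for (int r = 0; r < K; ++r) perm[r] = r + 1;
  long accepted = 0;

  NumericMatrix F(n, 3);
  for (int it = 0; it < n_iter; ++it) {
    for (int r = 0; r < K; ++r) {
      int k = perm[r] - 1;
      double lam = lambdas[k], sr = srest[k], si = sinter[k];
      NumericMatrix& x = X[r];
      NumericMatrix& v = V[r];
      std::fill(F.begin(), F.end(), 0.0);
      eval_all(c, x, lam, sr, si, true, &F, nullptr);
      for (int s = 0; s < n_steps; ++s) {
        for (int i = 0; i < n; ++i) {
          double im = KCAL_TO_KJ * dt * 0.5 / c.mass[i];
          for (int d = 0; d < 3; ++d) v(i, d) += im * F(i, d);
        }
        for (int i = 0; i < n; ++i)
          for (int d = 0; d < 3; ++d) x(i, d) += 0.5 * dt * v(i, d);
        for (int i = 0; i < n; ++i) {
          double sd = std::sqrt(kT_md / c.mass[i]);
          for (int d = 0; d < 3; ++d)
            v(i, d) = c1 * v(i, d) + c2 * sd * norm_rand();
        }
        for (int i = 0; i < n; ++i)
          for (int d = 0; d < 3; ++d) x(i, d) += 0.5 * dt * v(i, d);
        std::fill(F.begin(), F.end(), 0.0);
        eval_all(c, x, lam, sr, si, true, &F, nullptr);
        for (int i = 0; i < n; ++i) {
          double im = KCAL_TO_KJ * dt * 0.5 / c.mass[i];
          for (int d = 0; d < 3; ++d) v(i, d) += im * F(i, d);
        }
      }
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          if (!std::isfinite(x(i, d)))
            stop("non-finite coordinate during propagation (iteration %d)",
                 it + 1);
      // reduced potentials at all states + dU/dlambda stencil
      for (int kk = 0; kk < K; ++kk) {
        double e = eval_all(c, x, lambdas[kk], srest[kk], sinter[kk], false,
                            nullptr, nullptr);
        u_out[(R_xlen_t)it * K * K + (R_xlen_t)r * K + kk] = e / kT;
      }
      double e_lo = eval_all(c, x, lam_lo[k], srest_lo[k], sinter_lo[k],
                             false, nullptr, nullptr);
      double e_hi = eval_all(c, x, lam_hi[k], srest_hi[k], sinter_hi[k],
                             false, nullptr, nullptr);
      dudl(it, r) = (e_hi - e_lo) / (lam_hi[k] - lam_lo[k]);
      states(it, r) = perm[r];
      if (store_configs) {
        R_xlen_t base = ((R_xlen_t)it * K + r) * (R_xlen_t)n * 3;
        for (int d = 0; d < 3; ++d)
          for (int i = 0; i < n; ++i)
            configs[base + (R_xlen_t)d * n + i] = x(i, d);
      }
    }
    // swap sweep on u[k, r] of this iteration (kT units)
    if (K >= 2) {
      for (int t = 0; t < n_attempts; ++t) {
        int a = (int)(unif_rand() * K); if (a == K) a = K - 1;
        int b = (int)(unif_rand() * (K - 1)); if (b == K - 1) b = K - 2;
        if (b >= a) b += 1;
        int i = perm[a] - 1, j = perm[b] - 1;
        R_xlen_t ca = (R_xlen_t)it * K * K + (R_xlen_t)a * K;
        R_xlen_t cb = (R_xlen_t)it * K * K + (R_xlen_t)b * K;
        double delta = (u_out[ca + j] + u_out[cb + i]) -
                       (u_out[ca + i] + u_out[cb + j]);
        if (delta <= 0.0 || unif_rand() < std::exp(-delta)) {
          perm[a] = j + 1; perm[b] = i + 1;
          ++accepted;
        }
      }
    }
  }
  List xs(K), vs(K);
  for (int r = 0; r < K; ++r) { xs[r] = X[r]; vs[r] = V[r]; }
  return List::create(_["u"] = u_out, _["states"] = states,
                      _["dudl"] = dudl, _["configs"] = configs,
                      _["x_final"] = xs, _["v_final"] = vs,
                      _["accepted"] = (double)accepted,
                      _["perm_final"] = perm);
}

// Metropolis swap sweep over random replica pairs. u is K x K (state x
// replica) in reduced units; perm[r] is the 1-based state of replica r.
// [[Rcpp::export]]
List cpp_swap_sweep(NumericMatrix u, IntegerVector perm, int n_attempts) {
  const int K = perm.size();
  IntegerVector p = clone(perm);
  int accepted = 0;
  if (K >= 2) {
    for (int t = 0; t < n_attempts; ++t) {
      int a = (int)(unif_rand() * K); if (a == K) a = K - 1;
      int b = (int)(unif_rand() * (K - 1)); if (b == K - 1) b = K - 2;
      if (b >= a) b += 1;
      int i = p[a] - 1, j = p[b] - 1;
      double delta = (u(j, a) + u(i, b)) - (u(i, a) + u(j, b));
      if (delta <= 0.0 || unif_rand() < std::exp(-delta)) {
        p[a] = j + 1; p[b] = i + 1;
        ++accepted;
      }
    }
  }
  return List::create(_["perm"] = p, _["accepted"] = accepted);
}
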