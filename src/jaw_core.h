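#ifndef POSSELT_JAW_CORE_H
#define POSSELT_JAW_CORE_H

#include <RcppArmadillo.h>

// Surrogate jaw dynamics shared by the forward-dynamics wrappers and the
// SAC training loop. Units: lengths mm, velocities mm/s, forces N, mass kg.
// The mid-incisal point is a 3-DOF point mass; muscles are point-to-point
// Hill-type springs pulling the point toward fixed skull-frame anchors.

namespace posselt {

constexpr double MM_PER_M = 1000.0;

struct JawCore {
  arma::mat anchors;     // n_mus x 3
  arma::vec f_max, l_opt, v_max, w_len, k_passive;
  arma::mat lig_anchors; // n_lig x 3
  arma::vec lig_rest, lig_slack, lig_E, lig_A;
  double mass;           // kg
  double damping;        // N s / mm
  double gravity;        // m / s^2
  double a_hill;         // force-velocity curvature
  double fv_cap;         // lengthening force cap
};

inline JawCore core_from_list(const Rcpp::List& m) {
  JawCore c;
  c.anchors     = Rcpp::as<arma::mat>(m["anchors"]);
  c.f_max       = Rcpp::as<arma::vec>(m["f_max"]);
  c.l_opt       = Rcpp::as<arma::vec>(m["l_opt"]);
  c.v_max       = Rcpp::as<arma::vec>(m["v_max"]);
  c.w_len       = Rcpp::as<arma::vec>(m["w_len"]);
  c.k_passive   = Rcpp::as<arma::vec>(m["k_passive"]);
  c.lig_anchors = Rcpp::as<arma::mat>(m["lig_anchors"]);
  c.lig_rest    = Rcpp::as<arma::vec>(m["lig_rest"]);
  c.lig_slack   = Rcpp::as<arma::vec>(m["lig_slack"]);
  c.lig_E       = Rcpp::as<arma::vec>(m["lig_E"]);
  c.lig_A       = Rcpp::as<arma::vec>(m["lig_A"]);
  c.mass        = Rcpp::as<double>(m["mass"]);
  c.damping     = Rcpp::as<double>(m["damping"]);
  c.gravity     = Rcpp::as<double>(m["gravity"]);
  c.a_hill      = Rcpp::as<double>(m["a_hill"]);
  c.fv_cap      = Rcpp::as<double>(m["fv_cap"]);
  return c;
}

// Active force-length: quadratic, peak 1 at l_norm = 1, support [1-w, 1+w].
inline double fl_curve(double l_norm, double w) {
  const double d = (l_norm - 1.0) / w;
  const double f = 1.0 - d * d;
  return f > 0.0 ? f : 0.0;
}

// Force-velocity: Hill hyperbola for shortening (v_norm > 0), linear branch
// capped at fv_cap for lengthening, C1 at v_norm = 0.
inline double fv_curve(double v_norm, double a, double cap) {
  if (v_norm >= 1.0) return 0.0;
  if (v_norm >= 0.0) return (1.0 - v_norm) / (1.0 + v_norm / a);
  const double slope = 1.0 + 1.0 / a;
  const double f = 1.0 - slope * v_norm;
  return f < cap ? f : cap;
}

inline double dfv_dvnorm(double v_norm, double a, double cap) {
  if (v_norm >= 1.0) return 0.0;
  if (v_norm >= 0.0) {
    const double den = 1.0 + v_norm / a;
    return -((1.0 / a) * (1.0 - v_norm) / (den * den) + 1.0 / den);
  }
  const double slope = 1.0 + 1.0 / a;
  return (1.0 - slope * v_norm) < cap ? -slope : 0.0;
}

// Muscle + ligament + gravity force on the mid-incisal point (no viscous
// damping term). Fills per-muscle tensions; optionally the velocity Jacobian
// d F / d v (symmetric, negative semi-definite) used by the implicit step.
inline arma::vec net_force_core(const JawCore& c, const arma::vec& P,
                                const arma::vec& v, const arma::vec& e,
                                arma::vec& tensions, arma::mat* dFdv = nullptr) {
  const arma::uword n = c.anchors.n_rows;
  arma::vec F(3, arma::fill::zeros);
  tensions.set_size(n);
  if (dFdv) dFdv->zeros(3, 3);
  for (arma::uword i = 0; i < n; ++i) {
    arma::vec d = c.anchors.row(i).t() - P;
    const double len = arma::norm(d);
    if (len < 1e-9) { tensions(i) = 0.0; continue; }  // coincident: drop
    const arma::vec u = d / len;
    const double l_norm = len / c.l_opt(i);
    const double v_mus = arma::dot(u, v);              // shortening positive
    const double v_norm = v_mus / c.v_max(i);
    const double fl = fl_curve(l_norm, c.w_len(i));
    const double fv = fv_curve(v_norm, c.a_hill, c.fv_cap);
    const double stretch = l_norm - 1.0;
    const double fp = stretch > 0.0 ? c.k_passive(i) * stretch * stretch : 0.0;
    double t = c.f_max(i) * (e(i) * fl * fv + fp);
    if (t < 0.0) t = 0.0;
    tensions(i) = t;
    F += t * u;
    if (dFdv) {
      const double dT = c.f_max(i) * e(i) * fl *
        dfv_dvnorm(v_norm, c.a_hill, c.fv_cap) / c.v_max(i);
      *dFdv += dT * (u * u.t());
    }
  }
  for (arma::uword j = 0; j < c.lig_anchors.n_rows; ++j) {
    arma::vec d = c.lig_anchors.row(j).t() - P;
    const double len = arma::norm(d);
    if (len < 1e-9) continue;
    const double l0 = c.lig_rest(j) + c.lig_slack(j);
    const double ext = len - l0;
    if (ext > 0.0) {
      const double k = c.lig_E(j) * c.lig_A(j) / l0;   // N / mm
      F += (k * ext / len) * d;
    }
  }
  F(2) -= c.mass * c.gravity;                          // gravity, N
  return F;
}

// One semi-implicit (symplectic) Euler step. Viscous damping and the
// velocity-dependent Hill force-velocity term are treated implicitly in the
// velocity update (Newton on the 3x3 system); the position update uses the
// new velocity. Reduces to
//   v' = (v + dt F(P, v, e)/m) / (1 + dt c/m),  P' = P + dt v'
// when the muscle forces are velocity-independent.
inline void step_core(const JawCore& c, arma::vec& P, arma::vec& v,
                      const arma::vec& e, double dt, arma::vec& tensions) {
  const double inv_m = MM_PER_M / c.mass;              // (mm/s^2) per N
  const double beta = dt * c.damping * inv_m;
  arma::mat dFdv(3, 3);
  // explicit predictor
  arma::vec F = net_force_core(c, P, v, e, tensions, &dFdv);
  arma::vec vn = (v + dt * inv_m * F) / (1.0 + beta);
  // Newton corrector on g(vn) = (1+beta) vn - v - dt/m F(P, vn) = 0
  for (int it = 0; it < 3; ++it) {
    F = net_force_core(c, P, vn, e, tensions, &dFdv);
    arma::vec g = (1.0 + beta) * vn - v - dt * inv_m * F;
    arma::mat J = (1.0 + beta) * arma::eye(3, 3) - dt * inv_m * dFdv;
    arma::vec dv = arma::solve(J, g, arma::solve_opts::fast);
    vn -= dv;
    if (arma::norm(dv) < 1e-12) break;
  }
  F = net_force_core(c, P, vn, e, tensions);           // tensions at new v
  v = vn;
  P += dt * v;
}

}  // namespace posselt

#endif
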