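// [[Rcpp::depends(RcppArmadillo)]]
#include "jaw_core.h"

using namespace Rcpp;
using posselt::JawCore;

// [[Rcpp::export]]
List cpp_net_force(List core, arma::vec P, arma::vec v, arma::vec e,
                   bool include_damping = true) {
  JawCore c = posselt::core_from_list(core);
  arma::vec tensions;
  arma::vec F = posselt::net_force_core(c, P, v, e, tensions);
  if (include_damping) F -= c.damping * v;
  return List::create(_["force"] = F, _["tensions"] = tensions);
}

// [[Rcpp::export]]
List cpp_step_n(List core, arma::vec P, arma::vec v, arma::vec e,
                double dt, int n, int record_every = 0) {
  JawCore c = posselt::core_from_list(core);
  arma::vec tensions;
  arma::mat traj;
  int n_rec = 0;
  if (record_every > 0) {
    traj.set_size(n / record_every + 1, 6);
  }
  for (int k = 0; k < n; ++k) {
    posselt::step_core(c, P, v, e, dt, tensions);
    if (!P.is_finite() || !v.is_finite())
      stop("integration failure: non-finite state at substep %d", k + 1);
    if (record_every > 0 && ((k + 1) % record_every == 0)) {
      traj(n_rec, 0) = P(0); traj(n_rec, 1) = P(1); traj(n_rec, 2) = P(2);
      traj(n_rec, 3) = v(0); traj(n_rec, 4) = v(1); traj(n_rec, 5) = v(2);
      ++n_rec;
    }
  }
  List out = List::create(_["P"] = P, _["v"] = v, _["tensions"] = tensions);
  if (record_every > 0) out["traj"] = traj.rows(0, n_rec > 0 ? n_rec - 1 : 0);
  return out;
}

// [[Rcpp::export]]
List cpp_equilibrium(List core, arma::vec e, arma::vec P0, arma::vec v0,
                     double dt, double tol, double max_time) {
  JawCore c = posselt::core_from_list(core);
  arma::vec P = P0, v = v0, tensions;
  double t = 0.0;
  // require the speed to stay below tol for a short dwell so transient
  // zero-crossings of |v| do not count as convergence
  const int dwell_needed = 50;
  int dwell = 0;
  while (t < max_time) {
    posselt::step_core(c, P, v, e, dt, tensions);
    t += dt;
    if (!P.is_finite() || !v.is_finite())
      stop("integration failure: non-finite state at t=%f", t);
    if (arma::norm(v) < tol) {
      if (++dwell >= dwell_needed)
        return List::create(_["P"] = P, _["v"] = v, _["converged"] = true,
                            _["time"] = t);
    } else {
      dwell = 0;
    }
  }
  return List::create(_["P"] = P, _["v"] = v, _["converged"] = false,
                      _["time"] = t);
}
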