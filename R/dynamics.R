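#' Net force on the mid-incisal point
#'
#' Sums the Hill-type muscle pulls (each directed from the mid-incisal point
#' toward its skull-frame anchor), the passive ligament pulls, gravity along
#' -z and the viscous damping term `-damping * velocity`. Muscle length is
#' the anchor distance; muscle shortening velocity is the rate of decrease of
#' that distance.
#'
#' @param model a [generate_jaw_model()] object.
#' @param state a [jaw_state()].
#' @param include_damping include the viscous term (default `TRUE`).
#' @return A list with `force` (3D, N) and `tensions` (per-muscle, N).
#' @export
net_force <- function(model, state, include_damping = TRUE) {
  stopifnot(inherits(model, "jaw_model"), inherits(state, "jaw_state"))
  res <- cpp_net_force(.jaw_core(model), state$position, state$velocity,
                       state$excitations, include_damping)
  list(force = as.numeric(res$force), tensions = as.numeric(res$tensions))
}

#' Advance the jaw state by semi-implicit Euler steps
#'
#' Symplectic update: the velocity is advanced first with the
#' velocity-dependent terms (viscous damping and the Hill force-velocity
#' factor) treated implicitly, then the position uses the new velocity.
#' For velocity-independent muscle forces this reduces to
#' `v' = (v + dt F/m) / (1 + dt c/m)`, `P' = P + dt v'`. Excitations are
#' held constant.
#'
#' @param model a `jaw_model`.
#' @param state a `jaw_state`.
#' @param dt timestep (s), default 0.001.
#' @param n_steps number of substeps.
#' @return The new `jaw_state` with per-muscle `tensions` attached as an
#'   attribute.
#' @export
step_physics <- function(model, state, dt = 0.001, n_steps = 1L) {
  stopifnot(dt > 0, n_steps >= 1)
  res <- cpp_step_n(.jaw_core(model), state$position, state$velocity,
                    state$excitations, dt, as.integer(n_steps))
  out <- jaw_state(res$P, res$v, state$excitations)
  attr(out, "tensions") <- as.numeric(res$tensions)
  out
}

#' Equilibrium position under constant excitations
#'
#' Steps the physics from the rest pose (or `state`) under constant
#' excitations until the speed stays below `tol`, and returns the settled
#' mid-incisal position.
#'
#' @param model a `jaw_model`.
#' @param excitations vector of 24 excitations in `[0, 1]`.
#' @param tol convergence tolerance on the speed (mm/s).
#' @param max_time maximum simulated time (s).
#' @param dt timestep (s).
#' @param state optional starting `jaw_state` (default: rest, zero
#'   excitation).
#' @return 3D position (mm). Signals an error if `max_time` is reached while
#'   the speed is still above `tol`.
#' @export
equilibrium_position <- function(model, excitations, tol = 0.05,
                                 max_time = 6, dt = 0.001, state = NULL) {
  stopifnot(all(excitations >= 0), all(excitations <= 1))
  if (is.null(state)) state <- jaw_state(excitations = excitations)
  res <- cpp_equilibrium(.jaw_core(model), excitations, state$position,
                         state$velocity, dt, tol, max_time)
  if (!isTRUE(res$converged))
    stop("equilibrium search did not converge within ", max_time,
         " s (|v| = ", signif(sqrt(sum(res$v^2)), 3), " mm/s)")
  as.numeric(res$P)
}

#' Simulate a trajectory under a piecewise-constant excitation schedule
#'
#' @param model a `jaw_model`.
#' @param excitation_matrix one row of 24 excitations per control interval.
#' @param substeps physics substeps per control interval.
#' @param dt timestep (s).
#' @param state starting `jaw_state` (default rest).
#' @return A data frame with columns `t_s`, `x_mm`, `y_mm`, `z_mm`,
#'   `e_1` .. `e_24`, one row per control interval (state after the
#'   interval's substeps).
#' @export
simulate_trajectory <- function(model, excitation_matrix, substeps = 20L,
                                dt = 0.001, state = NULL) {
  excitation_matrix <- as.matrix(excitation_matrix)
  stopifnot(ncol(excitation_matrix) == nrow(model$muscles))
  if (is.null(state)) state <- jaw_state()
  core <- .jaw_core(model)
  n <- nrow(excitation_matrix)
  pos <- matrix(NA_real_, n, 3)
  P <- state$position; v <- state$velocity
  for (i in seq_len(n)) {
    res <- cpp_step_n(core, P, v, excitation_matrix[i, ], dt,
                      as.integer(substeps))
    P <- res$P; v <- res$v
    pos[i, ] <- P
  }
  out <- data.frame(t_s = seq_len(n) * substeps * dt,
                    x_mm = pos[, 1], y_mm = pos[, 2], z_mm = pos[, 3])
  e <- as.data.frame(excitation_matrix)
  names(e) <- paste0("e_", seq_len(ncol(e)))
  cbind(out, e)
}
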