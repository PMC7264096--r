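#' Hill-type muscle parameter set
#'
#' Parameters of one point-to-point Hill-type actuator. Tension along the
#' muscle axis is
#' \deqn{T = f_{max}\,(a\, f_l(l/l_{opt})\, f_v(v/v_{max}) + f_p(l/l_{opt}))}
#' with activation \eqn{a \in [0,1]}, the quadratic active force-length curve
#' \eqn{f_l}, the Hill force-velocity curve \eqn{f_v} (shortening positive)
#' and a quadratic passive term \eqn{f_p = k_p \max(0, l/l_{opt}-1)^2}.
#'
#' @param name short label, e.g. `"LSM"`.
#' @param side `"left"` or `"right"`.
#' @param pair_id integer linking bilateral partners.
#' @param f_max maximum isometric tension (N).
#' @param l_opt optimal fiber length (mm).
#' @param v_max maximum shortening velocity (mm/s).
#' @param w_len width of the active force-length curve (dimensionless, in
#'   (0, 1)).
#' @param k_passive passive stiffness scale (fraction of `f_max` per unit
#'   normalized stretch squared).
#' @param origin 3D anchor point in the skull frame (mm).
#' @param role_tag one of `"elevator"`, `"depressor"`, `"protruder"`,
#'   `"lateral"`; used by the envelope pattern generator only.
#' @return An object of class `"hill_muscle_params"` (a named list).
#' @export
hill_muscle_params <- function(name, side, pair_id, f_max, l_opt, v_max,
                               w_len = 0.56, k_passive = 0.05,
                               origin = c(0, 0, 0), role_tag = "elevator") {
  side <- match.arg(side, c("left", "right"))
  role_tag <- match.arg(role_tag,
                        c("elevator", "depressor", "protruder", "lateral"))
  stopifnot(f_max > 0, l_opt > 0, v_max > 0, w_len > 0, w_len < 1,
            k_passive >= 0, length(origin) == 3, all(is.finite(origin)))
  structure(list(name = name, side = side, pair_id = as.integer(pair_id),
                 f_max = f_max, l_opt = l_opt, v_max = v_max, w_len = w_len,
                 k_passive = k_passive, origin = as.numeric(origin),
                 role_tag = role_tag),
            class = "hill_muscle_params")
}

#' Temporomandibular ligament parameter set
#'
#' A passive point-to-point spring with slack: tension is exactly zero up to
#' `rest_length + slack_offset` and linear-elastic beyond, with stiffness
#' `elastic_modulus * cross_section / (rest_length + slack_offset)` (N/mm).
#'
#' @param anchor 3D skull-frame anchor (mm).
#' @param rest_length anchor-to-jaw-point distance at the rest (closed) pose
#'   (mm).
#' @param slack_offset extra slack beyond the rest pose (mm); default 7.5.
#' @param elastic_modulus Young's modulus (MPa = N/mm^2); default 2.45.
#' @param cross_section effective cross-sectional area (mm^2).
#' @return An object of class `"ligament_params"`.
#' @export
ligament_params <- function(anchor, rest_length, slack_offset = 7.5,
                            elastic_modulus = 2.45, cross_section = 25) {
  stopifnot(length(anchor) == 3, rest_length > 0, slack_offset >= 0,
            elastic_modulus > 0, cross_section > 0)
  structure(list(anchor = as.numeric(anchor), rest_length = rest_length,
                 slack_offset = slack_offset,
                 elastic_modulus = elastic_modulus,
                 cross_section = cross_section),
            class = "ligament_params")
}

#' Active force-length curve
#'
#' Quadratic curve `max(0, 1 - ((l_norm - 1) / w_len)^2)`: 1 at the optimal
#' length, zero outside `[1 - w_len, 1 + w_len]`, symmetric about 1.
#'
#' @param l_norm normalized fiber length `l / l_opt` (>= 0). Vectorized.
#' @param w_len curve width.
#' @return Scalar(s) in `[0, 1]`.
#' @export
active_force_length <- function(l_norm, w_len = 0.56) {
  if (any(!is.finite(l_norm)) || any(l_norm < 0))
    stop("invalid geometry: negative or non-finite normalized length")
  pmax(0, 1 - ((l_norm - 1) / w_len)^2)
}

#' Force-velocity curve
#'
#' Hill hyperbola `(1 - v_norm) / (1 + v_norm / a_hill)` for shortening
#' (`0 <= v_norm < 1`), zero at and above the maximum shortening velocity,
#' and a linear lengthening branch capped at `cap` that matches the
#' shortening slope at zero velocity (C1 continuity).
#'
#' @param v_norm normalized velocity `v / v_max`, shortening positive.
#'   Vectorized.
#' @param a_hill curvature constant of the shortening hyperbola.
#' @param cap force cap on the lengthening branch.
#' @return Non-negative scalar(s), at most `cap`.
#' @export
force_velocity <- function(v_norm, a_hill = 0.25, cap = 1.5) {
  out <- numeric(length(v_norm))
  sh <- v_norm >= 0 & v_norm < 1
  out[sh] <- (1 - v_norm[sh]) / (1 + v_norm[sh] / a_hill)
  ln <- v_norm < 0
  out[ln] <- pmin(cap, 1 - (1 + 1 / a_hill) * v_norm[ln])
  out
}

#' Hill-type muscle tension
#'
#' @param p a [hill_muscle_params()] object.
#' @param activation contractile activation in `[0, 1]` (the excitation, under
#'   the identity excitation-to-activation mapping).
#' @param length current fiber length (mm).
#' @param velocity current shortening velocity (mm/s, shortening positive).
#' @param a_hill,cap force-velocity curve constants.
#' @return Tension in N (always >= 0; muscles only pull).
#' @export
muscle_tension <- function(p, activation, length, velocity = 0,
                           a_hill = 0.25, cap = 1.5) {
  if (!all(is.finite(c(activation, length, velocity))))
    stop("non-finite input to muscle_tension")
  stopifnot(activation >= 0, activation <= 1, length >= 0)
  l_norm <- length / p$l_opt
  fl <- active_force_length(l_norm, p$w_len)
  fv <- force_velocity(velocity / p$v_max, a_hill, cap)
  fp <- p$k_passive * pmax(0, l_norm - 1)^2
  pmax(0, p$f_max * (activation * fl * fv + fp))
}

#' Ligament tension with slack
#'
#' @param p a [ligament_params()] object.
#' @param current_length current anchor-to-jaw-point distance (mm, > 0).
#' @return Tension in N: zero at or below `rest_length + slack_offset`,
#'   linear-elastic beyond.
#' @export
ligament_tension <- function(p, current_length) {
  stopifnot(all(current_length > 0))
  l0 <- p$rest_length + p$slack_offset
  k <- p$elastic_modulus * p$cross_section / l0
  pmax(0, k * (current_length - l0))
}
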