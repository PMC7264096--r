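#' @useDynLib posselt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm setNames coef predict residuals simulate cor
#' @importFrom utils write.csv read.csv head tail
NULL

# Base left-side muscle layout of the surrogate. Anchors are skull-frame
# points (mm) relative to the mid-incisal rest position (x lateral-right,
# y anterior, z superior). Each muscle pulls the mid-incisal point toward its
# anchor; the two lateral-pterygoid compartments anchor contralaterally so a
# left-side exciter produces rightward (contralateral) motion, as in the
# physiological laterotrusion pattern.
.muscle_base <- function() {
  tab <- data.frame(
    name = c("LAT", "LMT", "LPT", "LSM", "LDM", "LMP",
             "LAD", "LGH", "LAM", "LPM", "LILP", "LSLP"),
    role = c(rep("elevator", 6), rep("depressor", 4), "protruder", "lateral"),
    f_max = c(160, 140, 120, 190, 120, 150, 22, 20, 20, 21, 3, 4),
    ox = c(-45, -48, -50, -48, -45, -32, -10, -6, -18, -25, 4, 40),
    oy = c(-20, -35, -55, -12, -25, -20, -35, -40, -30, -48, 58, 28),
    oz = c(150, 148, 140, 135, 138, 130, -90, -85, -88, -80, -35, -2),
    stringsAsFactors = FALSE)
  tab$pair_id <- seq_len(nrow(tab))
  tab$side <- "left"
  tab
}

# rest-pose fiber stretch (l / l_opt at the closed pose) and base passive
# stiffness scale per functional role
.role_stretch <- c(elevator = 1.50, depressor = 1.02,
                   protruder = 1.25, lateral = 1.00)
.role_kbase <- c(elevator = 0.04, depressor = 0.02,
                 protruder = 0.06, lateral = 0.03)

#' Generate a surrogate jaw model
#'
#' Builds the seeded parametric description of the muscle-driven jaw
#' surrogate: 24 Hill-type point-to-point actuators in 12 bilateral pairs,
#' two passive temporomandibular ligament springs with slack, gravity and
#' viscous damping acting on a 200 g point mass at the lower mid-incisal
#' point. The left side is laid out per functional role; the right side is
#' its mirror image across the sagittal plane, optionally perturbed to model
#' left-right asymmetry. A calibration step solves for the passive-term
#' scales of the elevator and depressor/protruder groups so that the net
#' passive + gravity force at the rest (maximum intercuspation) pose is
#' exactly zero: with zero excitation the jaw stays closed, and passive
#' recoil closes it from opened poses.
#'
#' @param seed integer seed; the model is deterministic given the seed.
#' @param asymmetry_scale relative perturbation applied to right-side anchors
#'   and maximum tensions (uniform in `[-s, s]`), in `[0, 0.1]`.
#' @param mass jaw mass (kg).
#' @param damping translational viscous damping (N s/mm); `NULL` (default)
#'   picks near-critical damping for the closed-jaw linearization.
#' @param gravity gravitational acceleration (m/s^2), along -z.
#' @param slack_offset ligament slack beyond the rest pose (mm).
#' @param lig_modulus ligament Young's modulus (MPa).
#' @param lig_area ligament effective cross-section (mm^2).
#' @param w_len active force-length width for all muscles.
#' @param a_hill force-velocity curvature constant.
#' @param fv_cap lengthening force cap.
#' @return An object of class `"jaw_model"`.
#' @export
generate_jaw_model <- function(seed = 1L, asymmetry_scale = 0.02,
                               mass = 0.2, damping = NULL, gravity = 9.81,
                               slack_offset = 7.5, lig_modulus = 2.45,
                               lig_area = 30, w_len = 0.56,
                               a_hill = 0.25, fv_cap = 1.5) {
  stopifnot(asymmetry_scale >= 0, asymmetry_scale <= 0.1, mass > 0)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  left <- .muscle_base()
  right <- left
  right$side <- "right"
  right$name <- sub("^L", "R", right$name)
  right$ox <- -right$ox
  if (asymmetry_scale > 0) {
    u_anchor <- runif(nrow(right), -asymmetry_scale, asymmetry_scale)
    u_fmax <- runif(nrow(right), -asymmetry_scale, asymmetry_scale)
    right$ox <- right$ox * (1 + u_anchor)
    right$oy <- right$oy * (1 + u_anchor)
    right$oz <- right$oz * (1 + u_anchor)
    right$f_max <- right$f_max * (1 + u_fmax)
  }
  mus <- rbind(left, right)
  rest_len <- sqrt(mus$ox^2 + mus$oy^2 + mus$oz^2)
  mus$l_opt <- rest_len / .role_stretch[mus$role]
  mus$v_max <- 8 * mus$l_opt
  mus$w_len <- w_len
  mus$k_base <- .role_kbase[mus$role]

  lig <- data.frame(side = c("left", "right"),
                    ax = c(-48, 48), ay = c(-75, -75), az = c(32, 32))
  if (asymmetry_scale > 0) {
    u <- runif(1, -asymmetry_scale, asymmetry_scale)
    lig[2, c("ax", "ay", "az")] <- lig[2, c("ax", "ay", "az")] * (1 + u)
  }
  lig$rest_length <- sqrt(lig$ax^2 + lig$ay^2 + lig$az^2)
  lig$slack_offset <- slack_offset
  lig$elastic_modulus <- lig_modulus
  lig$cross_section <- lig_area

  # --- rest-pose calibration -------------------------------------------
  # Solve a 3x3 linear system for multiplicative scales on the passive
  # stiffness of (left elevators, right elevators, depressors+protruders)
  # so the net passive + gravity force at the origin vanishes.
  u_hat <- cbind(mus$ox, mus$oy, mus$oz) / rest_len
  t_base <- mus$f_max * mus$k_base *
    pmax(0, .role_stretch[mus$role] - 1)^2
  grp <- ifelse(mus$role == "elevator",
                ifelse(mus$side == "left", "elL", "elR"), "dp")
  grp[mus$role == "lateral"] <- "lat"
  col_of <- function(g) colSums((t_base * u_hat)[grp == g, , drop = FALSE])
  M <- cbind(col_of("elL"), col_of("elR"), col_of("dp"))
  f_other <- col_of("lat") + c(0, 0, -mass * gravity)
  scales <- tryCatch(solve(M, -f_other), error = function(e) NULL)
  if (is.null(scales) || any(!is.finite(scales)) || any(scales <= 0))
    stop("rest-pose calibration failed: no positive passive-scale solution")
  s_map <- c(elL = scales[1], elR = scales[2], dp = scales[3], lat = 1)
  mus$k_passive <- mus$k_base * s_map[grp]

  model <- structure(list(
    muscles = mus[, c("name", "side", "pair_id", "role", "f_max", "l_opt",
                      "v_max", "w_len", "k_passive", "ox", "oy", "oz")],
    ligaments = lig,
    mass = mass, gravity = gravity,
    rest_position = c(0, 0, 0),
    asymmetry_scale = asymmetry_scale,
    seed = as.integer(seed),
    a_hill = a_hill, fv_cap = fv_cap,
    damping = NA_real_), class = "jaw_model")

  model$damping <- if (is.null(damping)) .critical_damping(model) else damping
  model
}

# plain-matrix representation handed to the C++ core
.jaw_core <- function(model) {
  m <- model$muscles
  list(anchors = cbind(m$ox, m$oy, m$oz),
       f_max = m$f_max, l_opt = m$l_opt, v_max = m$v_max,
       w_len = m$w_len, k_passive = m$k_passive,
       lig_anchors = cbind(model$ligaments$ax, model$ligaments$ay,
                           model$ligaments$az),
       lig_rest = model$ligaments$rest_length,
       lig_slack = model$ligaments$slack_offset,
       lig_E = model$ligaments$elastic_modulus,
       lig_A = model$ligaments$cross_section,
       mass = model$mass,
       damping = if (is.na(model$damping)) 0 else model$damping,
       gravity = model$gravity,
       a_hill = model$a_hill, fv_cap = model$fv_cap)
}

# near-critical damping for the closed-jaw linearization: c = 2 sqrt(k m)
# with k the largest eigenvalue of the passive stiffness at rest (N/mm) and
# the mass expressed in N s^2/mm
.critical_damping <- function(model) {
  core <- .jaw_core(model)
  e0 <- rep(0, nrow(model$muscles))
  h <- 1e-4
  K <- matrix(0, 3, 3)
  for (j in 1:3) {
    dp <- dm <- rep(0, 3)
    dp[j] <- h; dm[j] <- -h
    fp <- cpp_net_force(core, dp, rep(0, 3), e0, FALSE)$force
    fm <- cpp_net_force(core, dm, rep(0, 3), e0, FALSE)$force
    K[, j] <- -(fp - fm) / (2 * h)
  }
  K <- (K + t(K)) / 2
  k_max <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (k_max <= 0) stop("rest pose is not a stable passive equilibrium")
  2 * sqrt(k_max * model$mass / 1000)
}

#' Jaw state
#'
#' @param position 3D mid-incisal position (mm, origin at rest/ICP).
#' @param velocity 3D velocity (mm/s).
#' @param excitations vector of 24 neural excitations in `[0, 1]`.
#' @return An object of class `"jaw_state"`.
#' @export
jaw_state <- function(position = c(0, 0, 0), velocity = c(0, 0, 0),
                      excitations = rep(0, 24)) {
  stopifnot(length(position) == 3, length(velocity) == 3,
            all(is.finite(c(position, velocity, excitations))),
            all(excitations >= 0), all(excitations <= 1))
  structure(list(position = as.numeric(position),
                 velocity = as.numeric(velocity),
                 excitations = as.numeric(excitations)),
            class = "jaw_state")
}

#' @export
print.jaw_model <- function(x, ...) {
  cat("Surrogate jaw model (seed ", x$seed, ")\n", sep = "")
  cat("  ", nrow(x$muscles), " Hill-type muscles in ",
      length(unique(x$muscles$pair_id)), " bilateral pairs\n", sep = "")
  cat("  mass ", x$mass * 1000, " g, damping ",
      signif(x$damping, 4), " N s/mm, asymmetry ",
      x$asymmetry_scale, "\n", sep = "")
  cat("  ligaments: slack ", x$ligaments$slack_offset[1], " mm, E ",
      x$ligaments$elastic_modulus[1], " MPa\n", sep = "")
  invisible(x)
}

#' Write / read a jaw model as a YAML config
#'
#' Serializes every muscle and ligament parameter (lengths mm, forces N,
#' moduli MPa) so a model round-trips exactly through the plain-text config.
#'
#' @param model a `jaw_model`.
#' @param path file path.
#' @return `write_jaw_model` returns `path` invisibly; `read_jaw_model`
#'   returns the reconstructed `jaw_model`.
#' @export
write_jaw_model <- function(model, path) {
  obj <- list(
    seed = model$seed, asymmetry_scale = model$asymmetry_scale,
    mass = model$mass, gravity = model$gravity, damping = model$damping,
    a_hill = model$a_hill, fv_cap = model$fv_cap,
    rest_position = model$rest_position,
    muscles = lapply(seq_len(nrow(model$muscles)), function(i) {
      m <- model$muscles[i, ]
      list(name = m$name, side = m$side, pair_id = m$pair_id, role = m$role,
           f_max = m$f_max, l_opt = m$l_opt, v_max = m$v_max,
           w_len = m$w_len, k_passive = m$k_passive,
           origin = c(m$ox, m$oy, m$oz))
    }),
    ligaments = lapply(seq_len(nrow(model$ligaments)), function(i) {
      l <- model$ligaments[i, ]
      list(side = l$side, anchor = c(l$ax, l$ay, l$az),
           rest_length = l$rest_length, slack_offset = l$slack_offset,
           elastic_modulus = l$elastic_modulus,
           cross_section = l$cross_section)
    }))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_jaw_model
#' @export
read_jaw_model <- function(path) {
  obj <- yaml::read_yaml(path)
  mus <- do.call(rbind, lapply(obj$muscles, function(m)
    data.frame(name = m$name, side = m$side, pair_id = m$pair_id,
               role = m$role, f_max = m$f_max, l_opt = m$l_opt,
               v_max = m$v_max, w_len = m$w_len, k_passive = m$k_passive,
               ox = m$origin[1], oy = m$origin[2], oz = m$origin[3],
               stringsAsFactors = FALSE)))
  lig <- do.call(rbind, lapply(obj$ligaments, function(l)
    data.frame(side = l$side, ax = l$anchor[1], ay = l$anchor[2],
               az = l$anchor[3], rest_length = l$rest_length,
               slack_offset = l$slack_offset,
               elastic_modulus = l$elastic_modulus,
               cross_section = l$cross_section, stringsAsFactors = FALSE)))
  structure(list(muscles = mus, ligaments = lig, mass = obj$mass,
                 gravity = obj$gravity,
                 rest_position = as.numeric(obj$rest_position),
                 asymmetry_scale = obj$asymmetry_scale,
                 seed = as.integer(obj$seed), a_hill = obj$a_hill,
                 fv_cap = obj$fv_cap, damping = obj$damping),
            class = "jaw_model")
}
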