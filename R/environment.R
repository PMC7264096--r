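#' Reward weights for the three-term mastication reward
#'
#' @param w_u target-reaching weight (log-distance term).
#' @param w_r force-regularization weight (on the Euclidean norm of the
#'   24-muscle tension vector, N).
#' @param w_s symmetry weight (on the L1 gap between left and right
#'   excitation sub-vectors).
#' @param epsilon distance floor (mm) preventing an infinite reward at zero
#'   distance.
#' @return An object of class `"reward_weights"`.
#' @export
reward_weights <- function(w_u = 1, w_r = 0.5, w_s = 10, epsilon = 1e-3) {
  stopifnot(w_u >= 0, w_r >= 0, w_s >= 0, epsilon > 0)
  structure(list(w_u = w_u, w_r = w_r, w_s = w_s, epsilon = epsilon),
            class = "reward_weights")
}

#' Episode settings
#'
#' @param max_steps maximum actions per episode (T).
#' @param success_radius target proximity ending an episode (mm); default
#'   0.1 mm (100 micrometers).
#' @param substeps physics substeps per action.
#' @param dt physics timestep (s).
#' @return An object of class `"episode_config"`.
#' @export
episode_config <- function(max_steps = 100L, success_radius = 0.1,
                           substeps = 20L, dt = 0.001) {
  stopifnot(max_steps >= 1, success_radius > 0, substeps >= 1, dt > 0)
  structure(list(max_steps = as.integer(max_steps),
                 success_radius = success_radius,
                 substeps = as.integer(substeps), dt = dt),
            class = "episode_config")
}

#' Three-term mastication reward
#'
#' \deqn{r = -w_u \log(\lVert \hat P - P\rVert_2 + \epsilon)
#'          - w_r \lVert f \rVert_2
#'          - w_s \lVert e^l - e^r \rVert_1}
#' where \eqn{P} is the mid-incisal position after the action, \eqn{f} the
#' vector of muscle tensions (N) and \eqn{e^l, e^r} the left/right
#' excitation sub-vectors matched by bilateral pair.
#'
#' @param position 3D mid-incisal position after the action (mm).
#' @param target desired position (mm).
#' @param excitations excitation vector ordered left pairs then right pairs
#'   (the model convention: muscles 1..n/2 left, n/2+1..n right, partners at
#'   offset n/2).
#' @param tensions per-muscle tensions after the action (N).
#' @param weights a [reward_weights()] object.
#' @return Scalar reward.
#' @export
mastication_reward <- function(position, target, excitations, tensions,
                               weights = reward_weights()) {
  n <- length(excitations)
  stopifnot(n %% 2 == 0, length(tensions) == n)
  half <- n / 2
  dist <- sqrt(sum((target - position)^2))
  asym <- sum(abs(excitations[1:half] - excitations[(half + 1):n]))
  -weights$w_u * log(dist + weights$epsilon) -
    weights$w_r * sqrt(sum(tensions^2)) -
    weights$w_s * asym
}

#' Sample a training target inside the envelope
#'
#' With probability 1/2 the target is a convex combination of all eight
#' end-points with uniform weights renormalized to sum one; otherwise two
#' end-points are drawn uniformly with replacement and a uniform convex
#' combination of the two is taken. Targets therefore always lie inside (or
#' on) the envelope hull, and in 0.5 x 1/8 = 6.25% of episodes the target is
#' exactly an end-point (both draws equal).
#'
#' @param endpoints an `envelope_endpoints` object.
#' @return 3D target (mm).
#' @export
sample_target <- function(endpoints) {
  pts <- endpoints$points
  if (runif(1) < 0.5) {
    w <- runif(8)
    w <- w / sum(w)
    as.numeric(t(pts) %*% w)
  } else {
    i <- sample.int(8, 2, replace = TRUE)
    lambda <- runif(1)
    as.numeric(lambda * pts[i[1], ] + (1 - lambda) * pts[i[2], ])
  }
}

#' Reaching environment over the jaw surrogate
#'
#' A gym-style episodic environment: `reset()` places the jaw at rest (ICP)
#' with zero excitations and samples a fresh target; `step(action)` clips
#' the per-muscle excitation deltas to +/- 10% of the excitation range,
#' applies them, advances the physics by `substeps` timesteps and returns
#' the observation, the three-term reward, the termination flag (target
#' within `success_radius`, or `max_steps` actions) and an info list. The
#' observation is `c(excitations, position, velocity, target)` with
#' positions normalized by the envelope half-extents and velocities by
#' 100 mm/s (length 24 + 9 = 33).
#'
#' @param model a `jaw_model`.
#' @param endpoints an `envelope_endpoints` for the model.
#' @param weights a [reward_weights()].
#' @param cfg an [episode_config()].
#' @param action_bound per-step excitation delta bound.
#' @return An object of class `"jaw_env"`: a list of closures
#'   `reset(target = NULL, state = NULL)`, `step(action)`, `state()`,
#'   `target()` and `episode_log()` (a data frame with one row per step:
#'   episode, step, distance_mm, reward, force_norm_N, L1_asym, ready for
#'   [write.csv()]), plus the configuration fields.
#' @export
jaw_env <- function(model, endpoints, weights = reward_weights(),
                    cfg = episode_config(), action_bound = 0.1) {
  stopifnot(inherits(model, "jaw_model"),
            inherits(endpoints, "envelope_endpoints"))
  mus <- model$muscles
  n <- nrow(mus)
  half <- n / 2
  # bilateral pairing contract: left block then right block, matched order
  stopifnot(all(mus$side[1:half] == "left"),
            all(mus$side[(half + 1):n] == "right"),
            all(mus$pair_id[1:half] == mus$pair_id[(half + 1):n]))
  core <- .jaw_core(model)
  pos_scale <- apply(abs(endpoints$points), 2, max)
  pos_scale[pos_scale < 1] <- 1
  vel_scale <- 100

  e <- rep(0, n); P <- model$rest_position; v <- c(0, 0, 0)
  tgt <- NULL; steps <- 0L
  episode <- 0L
  log_rows <- list()

  obs <- function() c(e, P / pos_scale, v / vel_scale, tgt / pos_scale)

  reset <- function(target = NULL, state = NULL) {
    if (is.null(state)) {
      e <<- rep(0, n); P <<- model$rest_position; v <<- c(0, 0, 0)
    } else {
      e <<- state$excitations; P <<- state$position
      v <<- state$velocity
    }
    steps <<- 0L
    episode <<- episode + 1L
    tgt <<- if (is.null(target)) sample_target(endpoints)
            else as.numeric(target)
    obs()
  }

  step <- function(action) {
    stopifnot(!is.null(tgt))
    a <- pmin(pmax(action, -action_bound), action_bound)
    e <<- pmin(pmax(e + a, 0), 1)
    res <- cpp_step_n(core, P, v, e, cfg$dt, cfg$substeps)
    P <<- as.numeric(res$P); v <<- as.numeric(res$v)
    nf <- cpp_net_force(core, P, v, e, FALSE)
    tensions <- as.numeric(nf$tensions)
    r <- mastication_reward(P, tgt, e, tensions, weights)
    steps <<- steps + 1L
    dist <- sqrt(sum((tgt - P)^2))
    done <- (dist < cfg$success_radius) || (steps >= cfg$max_steps)
    log_rows[[length(log_rows) + 1]] <<- c(episode, steps, dist, r,
                                           sqrt(sum(tensions^2)),
                                           sum(abs(e[1:half] -
                                                   e[(half + 1):n])))
    list(observation = obs(), reward = r, done = done,
         info = list(distance = dist, tensions = tensions,
                     force_norm = sqrt(sum(tensions^2)),
                     asym = sum(abs(e[1:half] - e[(half + 1):n])),
                     success = dist < cfg$success_radius,
                     steps = steps))
  }

  episode_log <- function() {
    if (length(log_rows) == 0)
      return(data.frame(episode = integer(), step = integer(),
                        distance_mm = numeric(), reward = numeric(),
                        force_norm_N = numeric(), L1_asym = numeric()))
    m <- do.call(rbind, log_rows)
    data.frame(episode = as.integer(m[, 1]), step = as.integer(m[, 2]),
               distance_mm = m[, 3], reward = m[, 4],
               force_norm_N = m[, 5], L1_asym = m[, 6])
  }

  structure(list(reset = reset, step = step,
                 state = function() jaw_state(P, v, e),
                 target = function() tgt,
                 episode_log = episode_log,
                 model = model, endpoints = endpoints, weights = weights,
                 cfg = cfg, action_bound = action_bound, n_muscles = n,
                 obs_dim = n + 9L, pos_scale = pos_scale,
                 vel_scale = vel_scale),
            class = "jaw_env")
}
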