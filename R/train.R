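#' Train a Soft Actor-Critic motor-control policy on the jaw surrogate
#'
#' The main fitting function of the package. Runs episodic reaching
#' training: each episode starts at rest (maximum intercuspation) with a
#' target sampled inside the envelope of motion; the agent adjusts the 24
#' muscle excitations in capped increments, receiving the three-term reward
#' (log-distance, force regularization, bilateral symmetry). After every
#' environment step one critic and one actor gradient update are applied
#' from a uniformly drawn replay batch, followed by the EMA target update.
#'
#' @param model a [generate_jaw_model()]; default model with seed 1.
#' @param endpoints precomputed [compute_envelope()] for `model` (computed
#'   if `NULL`).
#' @param weights a [reward_weights()].
#' @param cfg an [episode_config()].
#' @param sac a [sac_config()].
#' @param total_steps environment interactions to train for.
#' @param seed integer seed controlling initialization, exploration noise,
#'   target sampling and replay sampling; runs are fully reproducible.
#' @param stats_every record update statistics every this many steps.
#' @param random_steps initial environment steps driven by uniform random
#'   actions before the policy takes over (warm-up exploration; gradient
#'   updates still begin once the buffer holds one batch).
#' @param verbose print a short progress summary.
#' @return An object of class `"jaw_sac"` with components `weights` (all
#'   five parameter sets), `stats` (per-episode and per-update data
#'   frames), the configurations, and the (internal) live agent. Methods:
#'   [print()], [summary()], [coef()], [predict()], [simulate()],
#'   [residuals()], [plot()].
#' @export
jaw_sac <- function(model = NULL, endpoints = NULL,
                    weights = reward_weights(), cfg = episode_config(),
                    sac = sac_config(), total_steps = 30000, seed = 1L,
                    stats_every = 500L, random_steps = 2000L,
                    verbose = FALSE) {
  if (is.null(model)) model <- generate_jaw_model(seed = 1L)
  if (is.null(endpoints)) endpoints <- compute_envelope(model)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  env <- jaw_env(model, endpoints, weights, cfg)
  agent <- sac_agent(env$obs_dim, env$n_muscles, sac,
                     buffer_capacity = min(sac$buffer_capacity,
                                           total_steps + 1))
  res <- cpp_sac_train(agent$ptr, .jaw_core(model), endpoints$points,
                       env$pos_scale, env$vel_scale,
                       unclass(weights), unclass(cfg),
                       as.integer(total_steps), agent$config$batch_size,
                       agent$config$batch_size, as.integer(stats_every),
                       agent$config$updates_per_env_step,
                       as.integer(min(random_steps, total_steps)))
  episodes <- as.data.frame(res$episodes)
  names(episodes) <- c("episode", "steps", "return", "final_distance_mm",
                       "success")
  updates <- as.data.frame(res$updates)
  names(updates) <- c("env_step", "critic_loss", "actor_objective",
                      "entropy", "lr")
  fit <- structure(list(
    agent = agent,
    weights = cpp_sac_get_weights(agent$ptr),
    model = model, endpoints = endpoints,
    reward_weights = weights, episode_cfg = cfg, sac_cfg = sac,
    total_steps = as.integer(total_steps), seed = as.integer(seed),
    stats = list(episodes = episodes, updates = updates),
    call = match.call()), class = "jaw_sac")
  if (verbose) print(fit)
  fit
}

# live pointer for a fitted object (rebuilds after deserialization)
.fit_ptr <- function(object) {
  .agent_ptr(object$agent, object$weights)
}

#' Policy action for an observation or a (state, target) pair
#'
#' @param object a fitted `jaw_sac`.
#' @param observation a 33-vector (or matrix of columns) as produced by the
#'   environment; alternatively supply `state` and `target`.
#' @param state a [jaw_state()] (used with `target`).
#' @param target 3D target (mm).
#' @param deterministic use the distribution mode (inference default).
#' @param ... unused.
#' @return The excitation-delta action vector (or matrix).
#' @export
predict.jaw_sac <- function(object, observation = NULL, state = NULL,
                            target = NULL, deterministic = TRUE, ...) {
  if (is.null(observation)) {
    stopifnot(!is.null(state), !is.null(target))
    ps <- .fit_pos_scale(object)
    observation <- c(state$excitations, state$position / ps,
                     state$velocity / 100, target / ps)
  }
  ptr <- .fit_ptr(object)
  res <- cpp_sac_act(ptr, .as_col(observation, object$agent$obs_dim),
                     deterministic)
  drop(res$action)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fit_pos_scale <- function(object) {
  ps <- apply(abs(object$endpoints$points), 2, max)
  ps[ps < 1] <- 1
  ps
}

#' @export
print.jaw_sac <- function(x, ...) {
  cat("Soft Actor-Critic mastication policy\n")
  cat("  trained", x$total_steps, "env steps, seed", x$seed, "\n")
  cat("  reward weights: w_u", x$reward_weights$w_u,
      "w_r", x$reward_weights$w_r, "w_s", x$reward_weights$w_s, "\n")
  ep <- x$stats$episodes
  if (nrow(ep) > 0) {
    last <- tail(ep, max(1, round(nrow(ep) / 10)))
    cat("  episodes:", nrow(ep),
        " final-distance (last 10%): median",
        signif(stats::median(last$final_distance_mm), 3), "mm, success rate",
        signif(mean(last$success), 3), "\n")
  }
  invisible(x)
}

#' @export
summary.jaw_sac <- function(object, protocol = NULL, ...) {
  ev <- evaluate_policy(object, protocol = protocol)
  out <- list(fit = object, metrics = ev$metrics,
              final_distances = ev$final_distances)
  class(out) <- "summary.jaw_sac"
  out
}

#' @export
print.summary.jaw_sac <- function(x, ...) {
  print(x$fit)
  cat("\nEvaluation (deterministic policy, standard protocol):\n")
  print(x$metrics)
  cat("mean final distance:", signif(mean(x$final_distances), 4), "mm\n")
  invisible(x)
}

#' @export
coef.jaw_sac <- function(object, ...) object$weights

#' Final target distances over the evaluation protocol
#'
#' @param object a fitted `jaw_sac`.
#' @param protocol an [evaluation_protocol()]; default standard 21 targets.
#' @param ... unused.
#' @return Numeric vector of final Euclidean distances (mm), one per
#'   protocol target.
#' @export
residuals.jaw_sac <- function(object, protocol = NULL, ...) {
  ev <- evaluate_policy(object, protocol = protocol,
                        include_agility = FALSE)
  ev$final_distances
}

#' Simulate deterministic reaching rollouts
#'
#' @param object a fitted `jaw_sac`.
#' @param nsim number of rollouts per target.
#' @param seed seed (affects only stochastic policies).
#' @param targets matrix of 3D targets (default: the 8 envelope
#'   end-points).
#' @param deterministic use the policy mode.
#' @param ... unused.
#' @return List of rollout records (data frames with time, position,
#'   excitations, tensions, distance).
#' @export
simulate.jaw_sac <- function(object, nsim = 1, seed = NULL, targets = NULL,
                             deterministic = TRUE, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(targets)) targets <- object$endpoints$points
  targets <- matrix(as.numeric(targets), ncol = 3)
  env <- jaw_env(object$model, object$endpoints, object$reward_weights,
                 object$episode_cfg)
  pol <- .policy_fun(object, deterministic)
  out <- list()
  for (i in seq_len(nrow(targets)))
    for (k in seq_len(nsim))
      out[[length(out) + 1]] <-
        .rollout(pol, env, targets[i, ])$record
  out
}

#' Learning-curve plot
#'
#' @param x a fitted `jaw_sac`.
#' @param which `"distance"` (per-episode final distance, log scale) or
#'   `"return"`.
#' @param ... passed to [plot()].
#' @export
plot.jaw_sac <- function(x, which = c("distance", "return"), ...) {
  which <- match.arg(which)
  ep <- x$stats$episodes
  if (nrow(ep) == 0) stop("no episode statistics recorded")
  if (which == "distance") {
    graphics::plot(ep$episode, pmax(ep$final_distance_mm, 1e-3), log = "y",
                   type = "p", pch = 16, cex = 0.4, col = "grey50",
                   xlab = "episode", ylab = "final distance (mm)", ...)
    k <- max(5, round(nrow(ep) / 40))
    med <- stats::filter(ep$final_distance_mm, rep(1 / k, k), sides = 2)
    graphics::lines(ep$episode, pmax(med, 1e-3), col = "firebrick", lwd = 2)
  } else {
    graphics::plot(ep$episode, ep$return, type = "l", col = "grey40",
                   xlab = "episode", ylab = "episode return", ...)
  }
  invisible(x)
}

# policy closure observation -> action used by rollout helpers
.policy_fun <- function(object, deterministic = TRUE) {
  if (is.function(object)) return(object)
  ptr <- .fit_ptr(object)
  obs_dim <- object$agent$obs_dim
  function(obs) drop(cpp_sac_act(ptr, matrix(obs, ncol = 1),
                                 deterministic)$action)
}
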