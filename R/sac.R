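#' Soft Actor-Critic hyper-parameters
#'
#' Defaults follow the training setup used throughout: discount 0.99,
#' entropy temperature 0.3 (fixed, no automatic tuning), target smoothing
#' 0.005, replay capacity 1e6, batches of 256 uniformly drawn samples,
#' learning rate decaying exponentially from 0.001 at rate 0.999995 per
#' update with floor 0.0004, Xavier-initialized multi-layer perceptrons
#' with two hidden layers of width 256, and one gradient update per
#' environment step.
#'
#' @param gamma reward discount.
#' @param alpha entropy temperature.
#' @param tau EMA coefficient for the target critics.
#' @param buffer_capacity replay buffer capacity.
#' @param batch_size samples per gradient update.
#' @param lr_start,lr_floor,lr_decay learning-rate schedule
#'   `max(lr_floor, lr_start * lr_decay^n_updates)`.
#' @param hidden hidden-layer width of policy and critics.
#' @param updates_per_env_step gradient updates per environment step.
#' @return An object of class `"sac_config"`.
#' @export
sac_config <- function(gamma = 0.99, alpha = 0.3, tau = 0.005,
                       buffer_capacity = 1e6, batch_size = 256,
                       lr_start = 0.001, lr_floor = 0.0004,
                       lr_decay = 0.999995, hidden = 256,
                       updates_per_env_step = 1) {
  stopifnot(gamma > 0, gamma <= 1, tau > 0, tau <= 1, alpha >= 0,
            buffer_capacity >= 1, batch_size >= 1, hidden >= 1,
            lr_start > 0, lr_floor > 0, lr_floor <= lr_start,
            lr_decay > 0, lr_decay <= 1, updates_per_env_step >= 1)
  structure(list(gamma = gamma, alpha = alpha, tau = tau,
                 buffer_capacity = buffer_capacity,
                 batch_size = as.integer(batch_size),
                 lr_start = lr_start, lr_floor = lr_floor,
                 lr_decay = lr_decay, hidden = as.integer(hidden),
                 updates_per_env_step = as.integer(updates_per_env_step)),
            class = "sac_config")
}

#' Learning-rate schedule
#'
#' `max(lr_floor, lr_start * lr_decay^n_updates)`: exponential decay with a
#' floor, monotonically non-increasing.
#'
#' @param n_updates update count (vectorized).
#' @param lr_start,lr_floor,lr_decay schedule constants.
#' @return Learning rate(s).
#' @export
lr_schedule <- function(n_updates, lr_start = 0.001, lr_floor = 0.0004,
                        lr_decay = 0.999995) {
  pmax(lr_floor, lr_start * lr_decay^n_updates)
}

#' Create a Soft Actor-Critic agent
#'
#' Initializes the Gaussian policy (two 256-wide rectified hidden layers
#' with parallel mean / log-standard-deviation heads), twin critics, their
#' EMA target copies (Xavier initialization, via the R RNG: seed with
#' [set.seed()]), Adam optimizer state and the replay ring buffer. The
#' returned agent has reference semantics: update operations modify it in
#' place.
#'
#' @param obs_dim observation length (33 for the default 24-muscle jaw).
#' @param act_dim action length (24).
#' @param config a [sac_config()].
#' @param action_bound tanh squashing bound on each action component.
#' @param buffer_capacity optional override of the replay capacity (e.g.
#'   the planned number of environment steps).
#' @return An object of class `"sac_agent"`.
#' @export
sac_agent <- function(obs_dim, act_dim, config = sac_config(),
                      action_bound = 0.1, buffer_capacity = NULL) {
  cap <- as.integer(min(if (is.null(buffer_capacity)) config$buffer_capacity
                        else buffer_capacity, 2^31 - 1))
  ptr <- cpp_sac_new(as.integer(obs_dim), as.integer(act_dim),
                     config$hidden, config$gamma, config$alpha, config$tau,
                     config$lr_start, config$lr_floor, config$lr_decay,
                     action_bound, cap)
  structure(list(ptr = ptr, obs_dim = as.integer(obs_dim),
                 act_dim = as.integer(act_dim), config = config,
                 action_bound = action_bound, buffer_capacity = cap),
            class = "sac_agent")
}

# rebuild the external pointer from stored weights (after deserialization)
.agent_ptr <- function(agent, weights = NULL) {
  if (cpp_ptr_valid(agent$ptr)) return(agent$ptr)
  if (is.null(weights))
    stop("agent pointer invalid and no weights available to rebuild")
  fresh <- sac_agent(agent$obs_dim, agent$act_dim, agent$config,
                     agent$action_bound, agent$buffer_capacity)
  cpp_sac_set_weights(fresh$ptr, weights)
  fresh$ptr
}

.as_col <- function(x, d) {
  x <- as.matrix(x)
  if (nrow(x) != d && ncol(x) == d) x <- t(x)
  stopifnot(nrow(x) == d)
  x
}

#' Sample an action from the policy
#'
#' Stochastic mode draws `a = bound * tanh(mu + sigma * xi)` with standard
#' normal `xi` (the reparameterization trick); the log-probability includes
#' the tanh change-of-variables correction. Deterministic mode returns the
#' distribution mode `bound * tanh(mu)`.
#'
#' @param agent a [sac_agent()].
#' @param obs observation vector or matrix (one column per observation).
#' @param deterministic use the mode instead of sampling.
#' @return List with `action` (act_dim x n) and `log_prob` (length n).
#' @export
sample_action <- function(agent, obs, deterministic = FALSE) {
  res <- cpp_sac_act(agent$ptr, .as_col(obs, agent$obs_dim), deterministic)
  list(action = res$action, log_prob = as.numeric(res$logp))
}

#' Clipped double-Q value
#'
#' @param agent a `sac_agent`.
#' @param s,a observation(s) and action(s), columns as samples.
#' @param target use the EMA target critics.
#' @return `min(Q1(s,a), Q2(s,a))` per sample.
#' @export
min_double_q <- function(agent, s, a, target = FALSE) {
  res <- cpp_sac_q(agent$ptr, .as_col(s, agent$obs_dim),
                   .as_col(a, agent$act_dim), target)
  as.numeric(res$qmin)
}

#' Soft state value under the target critics
#'
#' Samples `a' ~ pi(.|s')` and returns
#' `min(Qbar1, Qbar2)(s', a') - alpha * log pi(a'|s')`.
#'
#' @param agent a `sac_agent`.
#' @param s_next next observation(s), columns as samples.
#' @return Soft value per sample.
#' @export
soft_value <- function(agent, s_next) {
  as.numeric(cpp_sac_soft_value(agent$ptr, .as_col(s_next, agent$obs_dim)))
}

#' One critic gradient step
#'
#' Regresses both critics onto the Bellman target
#' `y = r + gamma (1 - done) * (min Qbar(s', a') - alpha log pi(a'|s'))`
#' by mean squared error with one Adam step at the scheduled learning rate,
#' and advances the update counter.
#'
#' @param agent a `sac_agent`.
#' @param batch list with elements `s`, `a`, `s_next` (columns as samples),
#'   `r`, `done`.
#' @return The summed MSE loss of the two critics (computed before the
#'   parameter step).
#' @export
critic_update <- function(agent, batch) {
  stopifnot(length(batch$r) >= 1)
  cpp_sac_critic_update(agent$ptr, .as_col(batch$s, agent$obs_dim),
                        .as_col(batch$a, agent$act_dim),
                        .as_col(batch$s_next, agent$obs_dim),
                        as.numeric(batch$r), as.numeric(batch$done))
}

#' One actor gradient step
#'
#' Maximizes `E[min Q(s, a~) - alpha log pi(a~|s)]` with reparameterized
#' actions; one Adam step at the scheduled learning rate.
#'
#' @param agent a `sac_agent`.
#' @param batch list with element `s` (columns as samples).
#' @return The objective estimate (higher is better).
#' @export
actor_update <- function(agent, batch) {
  cpp_sac_actor_update(agent$ptr, .as_col(batch$s, agent$obs_dim), FALSE)
}

#' Exponential moving average update of the target critics
#'
#' `theta_bar <- tau * theta + (1 - tau) * theta_bar`, elementwise.
#'
#' @param agent a `sac_agent`.
#' @param tau override of the configured smoothing coefficient.
#' @return The agent, invisibly.
#' @export
update_targets <- function(agent, tau = NULL) {
  cpp_sac_update_targets(agent$ptr, if (is.null(tau)) -1 else tau)
  invisible(agent)
}

#' Store a transition in the replay buffer
#'
#' @param agent a `sac_agent`.
#' @param s,a,s_next,r,done the transition; `done` should flag success
#'   terminations only (timeouts bootstrap).
#' @return The agent, invisibly.
#' @export
store_transition <- function(agent, s, a, s_next, r, done) {
  cpp_sac_store(agent$ptr, as.numeric(s), as.numeric(a), as.numeric(s_next),
                r, as.numeric(done))
  invisible(agent)
}

#' @export
print.sac_agent <- function(x, ...) {
  info <- cpp_sac_info(x$ptr)
  cat("SAC agent: obs", info$obs_dim, "-> act", info$act_dim,
      "(hidden", info$hidden, "x2)\n")
  cat("  alpha", info$alpha, "gamma", info$gamma, "tau", info$tau,
      "bound", info$bound, "\n")
  cat("  updates", info$n_updates, "lr", signif(info$lr, 6),
      "buffer", info$buffer_size, "/", info$buffer_capacity, "\n")
  invisible(x)
}
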