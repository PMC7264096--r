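test_that("policy actions respect the tanh bound in both modes", {
  ag <- toy_agent(obs_dim = 6, act_dim = 4)
  set.seed(2)
  obs <- matrix(rnorm(6 * 50), 6, 50)
  s <- sample_action(ag, obs)
  expect_true(all(abs(s$action) <= 0.1))
  d <- sample_action(ag, obs, deterministic = TRUE)
  expect_true(all(abs(d$action) <= 0.1))
  # degenerate sigma: stochastic draw equals the mode
  w <- posselt:::cpp_sac_get_weights(ag$ptr)
  w$policy$ls$W[] <- 0
  w$policy$ls$b[] <- -20
  posselt:::cpp_sac_set_weights(ag$ptr, w)
  s2 <- sample_action(ag, obs)
  d2 <- sample_action(ag, obs, deterministic = TRUE)
  expect_equal(s2$action, d2$action, tolerance = 1e-6)
})

test_that("log-probability matches a numerical density estimate in 1-D", {
  ag <- toy_agent(obs_dim = 1, act_dim = 1, hidden = 8, seed = 7)
  o1 <- matrix(0.3)
  pp <- posselt:::cpp_sac_policy_params(ag$ptr, o1)
  mu <- pp$mu[1, 1]; sigma <- pp$sigma[1, 1]
  set.seed(8)
  draws <- replicate(30000, sample_action(ag, o1)$action[1, 1])
  # analytic density of t = tanh(mu + sigma xi) at the histogram midpoints,
  # mapped to the action scale a = 0.1 t
  dens_t <- function(t) {
    z <- atanh(t)
    stats::dnorm(z, mu, sigma) / (1 - t^2)
  }
  h <- hist(draws / 0.1, breaks = seq(-1, 1, length.out = 41), plot = FALSE)
  keep <- h$density > 0
  expect_gt(cor(h$density[keep], dens_t(h$mids)[keep]), 0.98)
  # reported log-probability equals the analytic log-density at the sample
  set.seed(9)
  s <- sample_action(ag, o1)
  t_val <- s$action[1, 1] / 0.1
  expect_equal(s$log_prob, log(dens_t(t_val)), tolerance = 1e-6)
})

test_that("clipped double-Q is the elementwise minimum of the critics", {
  ag <- toy_agent(obs_dim = 5, act_dim = 3)
  set.seed(10)
  S <- matrix(rnorm(5 * 40), 5, 40)
  A <- matrix(runif(3 * 40, -0.1, 0.1), 3, 40)
  q <- posselt:::cpp_sac_q(ag$ptr, S, A, FALSE)
  expect_equal(as.numeric(q$qmin), pmin(as.numeric(q$q1),
                                        as.numeric(q$q2)))
  expect_true(all(min_double_q(ag, S, A) <= as.numeric(q$q1) + 1e-12))
  expect_true(all(min_double_q(ag, S, A) <= as.numeric(q$q2) + 1e-12))
})

test_that("soft value reduces to the min target critic when alpha = 0", {
  ag <- toy_agent(obs_dim = 4, act_dim = 2, alpha = 0)
  # force a deterministic policy so the sampled a' is the mode
  w <- posselt:::cpp_sac_get_weights(ag$ptr)
  w$policy$ls$W[] <- 0; w$policy$ls$b[] <- -20
  posselt:::cpp_sac_set_weights(ag$ptr, w)
  set.seed(12)
  S2 <- matrix(rnorm(4 * 10), 4, 10)
  mode_a <- sample_action(ag, S2, deterministic = TRUE)$action
  expect_equal(soft_value(ag, S2),
               min_double_q(ag, S2, mode_a, target = TRUE),
               tolerance = 1e-8)
})

test_that("critic loss on terminal transitions equals the hand-computed MSE", {
  ag <- toy_agent(obs_dim = 3, act_dim = 2, hidden = 6, seed = 21)
  # two terminal transitions: y = r exactly, no bootstrap, no sampling
  S <- matrix(c(0.1, -0.2, 0.3, 0.5, 0.4, -0.1), 3, 2)
  A <- matrix(c(0.05, -0.02, 0.01, 0.08), 2, 2)
  S2 <- matrix(0, 3, 2)
  r <- c(1.5, -2.0)
  q <- posselt:::cpp_sac_q(ag$ptr, S, A, FALSE)
  expected <- mean((as.numeric(q$q1) - r)^2) + mean((as.numeric(q$q2) - r)^2)
  loss <- critic_update(ag, list(s = S, a = A, s_next = S2, r = r,
                                 done = c(1, 1)))
  expect_equal(loss, expected, tolerance = 1e-10)
  expect_error(critic_update(ag, list(s = S[, 0], a = A[, 0],
                                      s_next = S2[, 0], r = numeric(0),
                                      done = numeric(0))), "empty|length")
})

test_that("a batch already at its target leaves the critics unchanged", {
  ag <- toy_agent(obs_dim = 3, act_dim = 2, hidden = 6, seed = 22)
  S <- matrix(c(0.3, 0.1, -0.4), 3, 1)
  A <- matrix(c(0.02, -0.06), 2, 1)
  y <- as.numeric(posselt:::cpp_sac_q(ag$ptr, S, A, FALSE)$q1)
  w_before <- posselt:::cpp_sac_get_weights(ag$ptr)
  # use q1's own output as reward on a terminal transition: q1 has zero
  # error, so its parameters must not move
  loss <- critic_update(ag, list(s = S, a = A, s_next = S,
                                 r = y, done = 1))
  w_after <- posselt:::cpp_sac_get_weights(ag$ptr)
  expect_equal(w_after$q1$l1$W, w_before$q1$l1$W, tolerance = 1e-12)
  expect_equal(w_after$q1$l3$b, w_before$q1$l3$b, tolerance = 1e-12)
})

test_that("critic and actor gradients agree with finite differences", {
  ag <- toy_agent(obs_dim = 5, act_dim = 3, hidden = 12, seed = 42)
  set.seed(42)
  S <- matrix(rnorm(5 * 4), 5, 4)
  A <- matrix(runif(3 * 4, -0.1, 0.1), 3, 4)
  y <- rnorm(4)
  g <- posselt:::cpp_sac_critic_grads_y(ag$ptr, S, A, y)
  th1 <- posselt:::cpp_sac_get_flat(ag$ptr, "q1")
  th2 <- posselt:::cpp_sac_get_flat(ag$ptr, "q2")
  full <- c(th1, th2)
  idx <- sort(sample(seq_along(full), 12))
  h <- 1e-6
  for (k in idx) {
    pert <- full; pert[k] <- pert[k] + h
    posselt:::cpp_sac_set_flat(ag$ptr, "q1", pert[seq_along(th1)])
    posselt:::cpp_sac_set_flat(ag$ptr, "q2", pert[-seq_along(th1)])
    lp <- posselt:::cpp_sac_critic_loss_y(ag$ptr, S, A, y)
    pert[k] <- pert[k] - 2 * h
    posselt:::cpp_sac_set_flat(ag$ptr, "q1", pert[seq_along(th1)])
    posselt:::cpp_sac_set_flat(ag$ptr, "q2", pert[-seq_along(th1)])
    lm <- posselt:::cpp_sac_critic_loss_y(ag$ptr, S, A, y)
    posselt:::cpp_sac_set_flat(ag$ptr, "q1", th1)
    posselt:::cpp_sac_set_flat(ag$ptr, "q2", th2)
    expect_equal((lp - lm) / (2 * h), g[k], tolerance = 1e-5)
  }
  gp <- posselt:::cpp_sac_actor_grads(ag$ptr, S)
  thp <- posselt:::cpp_sac_get_flat(ag$ptr, "policy")
  for (k in sort(sample(seq_along(thp), 12))) {
    pert <- thp; pert[k] <- pert[k] + h
    posselt:::cpp_sac_set_flat(ag$ptr, "policy", pert)
    lp <- posselt:::cpp_sac_actor_loss(ag$ptr, S)
    pert[k] <- pert[k] - 2 * h
    posselt:::cpp_sac_set_flat(ag$ptr, "policy", pert)
    lm <- posselt:::cpp_sac_actor_loss(ag$ptr, S)
    posselt:::cpp_sac_set_flat(ag$ptr, "policy", thp)
    expect_equal((lp - lm) / (2 * h), gp[k], tolerance = 1e-5)
  }
})

test_that("entropy pressure grows sigma under a constant critic", {
  ag <- toy_agent(obs_dim = 3, act_dim = 2, hidden = 6, seed = 30,
                  alpha = 5)
  w <- posselt:::cpp_sac_get_weights(ag$ptr)
  for (nm in c("q1", "q2")) {
    for (l in c("l1", "l2", "l3")) {
      w[[nm]][[l]]$W[] <- 0
      w[[nm]][[l]]$b[] <- 0
    }
  }
  w$policy$ls$W[] <- 0
  w$policy$ls$b[] <- -2          # start well below the entropy-optimal sigma
  posselt:::cpp_sac_set_weights(ag$ptr, w)
  probe <- matrix(c(0.2, -0.1, 0.4), 3, 1)
  sig0 <- mean(posselt:::cpp_sac_policy_params(ag$ptr, probe)$sigma)
  set.seed(30)
  S <- matrix(rnorm(3 * 32), 3, 32)
  for (k in 1:100) actor_update(ag, list(s = S))
  sig1 <- mean(posselt:::cpp_sac_policy_params(ag$ptr, probe)$sigma)
  expect_gt(sig1, sig0)
})

test_that("EMA target update matches its closed form", {
  ag <- toy_agent(obs_dim = 3, act_dim = 2, hidden = 6, seed = 31)
  w <- posselt:::cpp_sac_get_weights(ag$ptr)
  q1W <- w$q1$l2$W; qt1W <- w$qt1$l2$W
  update_targets(ag, tau = 0.005)
  w2 <- posselt:::cpp_sac_get_weights(ag$ptr)
  expect_equal(w2$qt1$l2$W, 0.005 * q1W + 0.995 * qt1W, tolerance = 1e-14)
  # tau = 1 copies, tau -> 0 freezes
  update_targets(ag, tau = 1)
  w3 <- posselt:::cpp_sac_get_weights(ag$ptr)
  expect_equal(w3$qt1$l2$W, w3$q1$l2$W, tolerance = 1e-14)
  before <- posselt:::cpp_sac_get_weights(ag$ptr)$qt2$l1$W
  update_targets(ag, tau = 1e-300)
  expect_equal(posselt:::cpp_sac_get_weights(ag$ptr)$qt2$l1$W, before,
               tolerance = 1e-14)
})

test_that("learning-rate schedule decays exponentially to its floor", {
  expect_equal(lr_schedule(0), 0.001)
  expect_equal(lr_schedule(1e5), max(4e-4, 1e-3 * 0.999995^1e5),
               tolerance = 1e-12)
  n <- seq(0, 5e5, by = 5e4)
  lr <- lr_schedule(n)
  expect_true(all(diff(lr) <= 0))
  expect_true(all(lr >= 4e-4))
  expect_equal(lr_schedule(1e7), 4e-4)
})

test_that("replay ring buffer evicts the oldest entries", {
  ag <- toy_agent(obs_dim = 2, act_dim = 1, hidden = 4, cap = 10)
  for (r in 1:13)
    store_transition(ag, c(0, 0), 0.01, c(0, 0), r, 0)
  stored <- sort(posselt:::cpp_sac_buffer_rewards(ag$ptr))
  expect_length(stored, 10)
  expect_equal(stored, 4:13)
})

test_that("training is reproducible and respects the warm-up rule", {
  m <- test_model(0)
  env0 <- test_envelope(0)
  cfg <- sac_config(hidden = 16, batch_size = 32)
  f1 <- jaw_sac(m, env0, sac = cfg, total_steps = 20, seed = 5)
  expect_equal(f1$weights$n_updates, 0)   # fewer steps than a batch
  f2 <- jaw_sac(m, env0, sac = cfg, total_steps = 300, seed = 5)
  f3 <- jaw_sac(m, env0, sac = cfg, total_steps = 300, seed = 5)
  expect_equal(f2$weights$policy$mu$W, f3$weights$policy$mu$W,
               tolerance = 1e-14)
  expect_gt(f2$weights$n_updates, 0)
  # a seed change moves the parameters
  f4 <- jaw_sac(m, env0, sac = cfg, total_steps = 300, seed = 6)
  expect_false(isTRUE(all.equal(f2$weights$policy$mu$W,
                                f4$weights$policy$mu$W)))
})
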