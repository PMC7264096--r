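test_that("three-term reward matches direct arithmetic", {
  w <- reward_weights(w_u = 1, w_r = 0, w_s = 0, epsilon = 1e-3)
  e_sym <- rep(0.2, 24)
  # at the target with zero tensions: r = -log(epsilon)
  expect_equal(mastication_reward(c(1, 2, 3), c(1, 2, 3), e_sym,
                                  rep(0, 24), w),
               -log(1e-3), tolerance = 1e-12)
  # unit distance, vanishing epsilon: r ~ -log(1) = 0
  w0 <- reward_weights(w_u = 1, w_r = 0, w_s = 0, epsilon = 1e-12)
  expect_equal(mastication_reward(c(0, 0, 0), c(1, 0, 0), e_sym,
                                  rep(0, 24), w0), 0, tolerance = 1e-9)
  # full three-term example: -log(2.001) - 0.5 * 3 - 10 * 0.2
  w3 <- reward_weights(w_u = 1, w_r = 0.5, w_s = 10, epsilon = 1e-3)
  e <- rep(0, 24); e[1] <- 0.2                  # one unmatched left muscle
  tens <- rep(0, 24); tens[1] <- 3              # ||f||_2 = 3
  expect_equal(mastication_reward(c(0, 0, 0), c(2, 0, 0), e, tens, w3),
               -log(2.001) - 1.5 - 2.0, tolerance = 1e-12)
})

test_that("reward is strictly decreasing in distance, force and asymmetry", {
  w <- reward_weights(w_u = 1, w_r = 0.5, w_s = 10)
  e_sym <- rep(0.1, 24)
  r_d <- vapply(c(0.5, 1, 2, 5, 10), function(d)
    mastication_reward(c(0, 0, 0), c(d, 0, 0), e_sym, rep(1, 24), w),
    numeric(1))
  expect_true(all(diff(r_d) < 0))
  r_f <- vapply(c(0, 1, 3, 9), function(f)
    mastication_reward(c(0, 0, 0), c(1, 0, 0), e_sym, rep(f, 24), w),
    numeric(1))
  expect_true(all(diff(r_f) < 0))
  r_s <- vapply(c(0, 0.1, 0.3, 0.8), function(g) {
    e <- e_sym; e[1] <- e[1] + g
    mastication_reward(c(0, 0, 0), c(1, 0, 0), e, rep(1, 24), w)
  }, numeric(1))
  expect_true(all(diff(r_s) < 0))
  # with w_r = w_s = 0 only distance matters
  w_d <- reward_weights(w_u = 1, w_r = 0, w_s = 0)
  e_any <- runif(24)
  expect_equal(
    mastication_reward(c(0, 0, 0), c(1, 1, 0), e_any, runif(24), w_d),
    mastication_reward(c(0, 0, 0), c(1, 1, 0), rep(0, 24), rep(9, 24), w_d))
})

test_that("sampled targets always lie inside the envelope hull", {
  env <- test_envelope(0)
  set.seed(123)
  tgts <- t(replicate(2000, sample_target(env)))
  expect_true(all(hull_contains(env$hull, tgts, tol = 1e-6)))
})

test_that("environment reset starts at rest with a fresh target", {
  m <- test_model(0)
  env <- jaw_env(m, test_envelope(0))
  set.seed(9)
  obs <- env$reset()
  expect_length(obs, 33)
  expect_equal(obs[1:24], rep(0, 24))            # excitations
  expect_equal(obs[25:27], c(0, 0, 0))           # position at rest
  expect_equal(obs[28:30], c(0, 0, 0))           # velocity
  t1 <- env$target()
  set.seed(9)
  env$reset()
  expect_identical(env$target(), t1)             # rng-determined target
})

test_that("action deltas are clipped to +/-0.1 and excitations stay in [0,1]", {
  m <- test_model(0)
  env <- jaw_env(m, test_envelope(0))
  env$reset(target = c(0, 5, -10))
  a <- rep(0, 24); a[1] <- 0.15; a[2] <- -0.4
  env$step(a)
  s <- env$state()
  expect_equal(s$excitations[1], 0.1)            # clipped to +0.1
  expect_equal(s$excitations[2], 0)              # clipped, then floor at 0
  # saturated channel stays at 1
  for (k in 1:15) env$step(rep(0.1, 24))
  expect_equal(env$state()$excitations, rep(1, 24))
  set.seed(31)
  env$reset(target = c(0, 5, -10))
  for (k in 1:30) env$step(runif(24, -0.3, 0.3))
  e <- env$state()$excitations
  expect_true(all(e >= 0 & e <= 1))
})

test_that("episodes terminate exactly on proximity or at step 100", {
  m <- test_model(0)
  env <- jaw_env(m, test_envelope(0))
  # target at rest: first step already within the 0.1 mm radius
  env$reset(target = c(0, 0, 0))
  st <- env$step(rep(0, 24))
  expect_true(st$done)
  expect_true(st$info$success)
  expect_lt(st$info$distance, 0.1)
  # unreachable target: runs to exactly max_steps
  env$reset(target = c(0, 5, -10))
  n <- 0
  repeat {
    st <- env$step(rep(0, 24))
    n <- n + 1
    if (st$done) break
  }
  expect_equal(n, 100)
  expect_false(st$info$success)
  # done flag flips exactly at the success radius boundary
  cfg <- episode_config()
  expect_equal(cfg$success_radius, 0.1)
  expect_equal(cfg$max_steps, 100L)
})

test_that("rewards reported by the environment match the reward function", {
  m <- test_model(0)
  env <- jaw_env(m, test_envelope(0))
  env$reset(target = c(0, 3, -8))
  a <- rep(0, 24); a[7:10] <- 0.05
  st <- env$step(a)
  s <- env$state()
  expect_equal(st$reward,
               mastication_reward(s$position, c(0, 3, -8), s$excitations,
                                  st$info$tensions, env$weights),
               tolerance = 1e-12)
})

test_that("the environment keeps a per-step episode log", {
  m <- test_model(0)
  env <- jaw_env(m, test_envelope(0))
  env$reset(target = c(0, 4, -9))
  for (k in 1:5) env$step(rep(0.02, 24))
  env$reset(target = c(0, 2, -5))
  for (k in 1:3) env$step(rep(0, 24))
  log <- env$episode_log()
  expect_identical(names(log), c("episode", "step", "distance_mm",
                                 "reward", "force_norm_N", "L1_asym"))
  expect_equal(nrow(log), 8)
  expect_equal(log$episode, c(rep(1L, 5), rep(2L, 3)))
  expect_equal(log$step, c(1:5, 1:3))
  expect_true(all(log$distance_mm >= 0))
})
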