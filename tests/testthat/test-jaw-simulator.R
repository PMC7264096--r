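test_that("model generation is deterministic and seed-sensitive", {
  m1 <- generate_jaw_model(seed = 3, asymmetry_scale = 0.02)
  m2 <- generate_jaw_model(seed = 3, asymmetry_scale = 0.02)
  m3 <- generate_jaw_model(seed = 4, asymmetry_scale = 0.02)
  expect_identical(m1$muscles, m2$muscles)
  expect_identical(m1$ligaments, m2$ligaments)
  expect_false(isTRUE(all.equal(
    m1$muscles$f_max[m1$muscles$side == "right"],
    m3$muscles$f_max[m3$muscles$side == "right"])))
})

test_that("zero asymmetry gives exact mirror anchors and bilateral pairing", {
  m <- test_model(0)
  left <- m$muscles[m$muscles$side == "left", ]
  right <- m$muscles[m$muscles$side == "right", ]
  expect_equal(nrow(m$muscles), 24)
  expect_identical(left$pair_id, right$pair_id)
  expect_equal(left$ox, -right$ox)
  expect_equal(left$oy, right$oy)
  expect_equal(left$oz, right$oz)
  expect_equal(left$f_max, right$f_max)
  # perturbation stays within the configured asymmetry bound
  ma <- generate_jaw_model(seed = 5, asymmetry_scale = 0.05)
  la <- ma$muscles[ma$muscles$side == "left", ]
  ra <- ma$muscles[ma$muscles$side == "right", ]
  expect_true(all(abs(ra$f_max / la$f_max - 1) <= 0.05 + 1e-12))
})

test_that("rest pose is a calibrated passive equilibrium", {
  m <- test_model(0)
  f <- net_force(m, jaw_state())
  expect_lt(sqrt(sum(f$force^2)), 1e-9)
  expect_equal(equilibrium_position(m, rep(0, 24)), c(0, 0, 0),
               tolerance = 1e-6)
  # also with asymmetry: the calibration absorbs the perturbation
  ma <- test_model(0.02)
  fa <- net_force(ma, jaw_state())
  expect_lt(sqrt(sum(fa$force^2)), 1e-9)
})

test_that("physics stepping: fixed point, free fall, energy dissipation", {
  m <- test_model(0)
  s0 <- jaw_state()
  s1 <- step_physics(m, s0, n_steps = 10)
  expect_equal(s1$position, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(s1$velocity, c(0, 0, 0), tolerance = 1e-12)

  # free fall: symplectic Euler accumulates exactly n dt g
  fp <- free_point_model(damping = 0)
  n <- 250
  s <- step_physics(fp, jaw_state(), dt = 0.001, n_steps = n)
  expect_equal(s$velocity[3], -n * 0.001 * 9.81 * 1000, tolerance = 1e-9)

  # released near equilibrium, kinetic energy dies out
  s <- jaw_state(position = c(0.5, -0.5, -1))
  ke <- numeric(50)
  for (k in 1:50) {
    s <- step_physics(m, s, n_steps = 20)
    ke[k] <- 0.5 * m$mass * sum((s$velocity / 1000)^2)
  }
  expect_lt(max(tail(ke, 10)), max(ke[1:10]) * 1e-3 + 1e-15)
})

test_that("long rollouts under constant patterns stay finite and bounded", {
  m <- test_model(0)
  pats <- envelope_patterns()
  for (nm in c("MO", "PR", "RL")) {
    e <- pattern_excitations(m, pats[[nm]])
    res <- step_physics(m, jaw_state(excitations = e), n_steps = 1e5)
    expect_true(all(is.finite(c(res$position, res$velocity))))
    expect_lt(max(abs(res$position)), 200)
  }
})

test_that("identical inputs give bit-identical trajectories", {
  m <- test_model(0)
  e <- pattern_excitations(m, c(depressor = 0.3))
  r1 <- step_physics(m, jaw_state(excitations = e), n_steps = 500)
  r2 <- step_physics(m, jaw_state(excitations = e), n_steps = 500)
  expect_identical(r1$position, r2$position)
  expect_identical(r1$velocity, r2$velocity)
})

test_that("mirrored excitations keep the sagittal plane invariant", {
  m <- test_model(0)
  set.seed(7)
  s <- jaw_state()
  max_x <- 0
  for (blk in 1:10) {
    e_half <- runif(12)
    e <- c(e_half, e_half)            # left block == right block
    s <- jaw_state(s$position, s$velocity, e)
    s <- step_physics(m, s, n_steps = 1000)
    max_x <- max(max_x, abs(s$position[1]))
  }
  expect_lt(max_x, 1e-9)
})

test_that("equilibrium search honours tolerance semantics", {
  m <- test_model(0)
  expect_error(
    equilibrium_position(m, pattern_excitations(m, c(depressor = 1)),
                         tol = 1e-9, max_time = 0.01),
    "did not converge")
  p <- equilibrium_position(m, rep(0, 24), tol = Inf, max_time = 1)
  expect_equal(p, c(0, 0, 0), tolerance = 1e-6)
})

test_that("envelope end-points have the Posselt-like geometry", {
  m <- test_model(0)
  env <- test_envelope(0)
  pts <- env$points
  expect_identical(rownames(pts),
                   c("ICP", "E", "PR", "LL", "RL", "RCP", "R", "MO"))
  expect_equal(pts["ICP", ], c(0, 0, 0), tolerance = 1e-6,
               ignore_attr = TRUE)
  # mirror symmetry of laterotrusion on the symmetric model
  expect_equal(unname(pts["LL", 1]), -unname(pts["RL", 1]),
               tolerance = 1e-6)
  expect_equal(unname(pts["LL", 2:3]), unname(pts["RL", 2:3]),
               tolerance = 1e-6)
  # opening inferior, protrusion anterior
  expect_lt(pts["MO", 3], pts["ICP", 3])
  expect_gt(pts["PR", 2], pts["ICP", 2])
  expect_gt(env$volume, 0)
})

test_that("jaw model round-trips through the YAML config", {
  m <- test_model(0.02)
  path <- tempfile(fileext = ".yaml")
  write_jaw_model(m, path)
  m2 <- read_jaw_model(path)
  expect_equal(m2$muscles$f_max, m$muscles$f_max, tolerance = 1e-12)
  expect_equal(m2$muscles$k_passive, m$muscles$k_passive, tolerance = 1e-12)
  expect_equal(m2$ligaments, m$ligaments, tolerance = 1e-12)
  expect_equal(m2$damping, m$damping, tolerance = 1e-12)
  # the reconstructed model produces identical forces
  st <- jaw_state(position = c(1, -2, -5),
                  excitations = rep(0.2, 24))
  expect_equal(net_force(m2, st)$force, net_force(m, st)$force,
               tolerance = 1e-10)
  unlink(path)
})

test_that("trajectory export uses the documented CSV schema", {
  m <- test_model(0)
  em <- matrix(rep(pattern_excitations(m, c(depressor = 0.2)), 5),
               nrow = 5, byrow = TRUE)
  df <- simulate_trajectory(m, em, substeps = 10)
  expect_identical(names(df)[1:4], c("t_s", "x_mm", "y_mm", "z_mm"))
  expect_identical(names(df)[5:28], paste0("e_", 1:24))
  expect_equal(nrow(df), 5)
  expect_equal(df$t_s, (1:5) * 0.01)
})
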