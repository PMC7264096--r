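# fabricate a rollout record with given per-step excitations and tensions
fake_record <- function(e_mat, f_mat, pos = NULL) {
  n <- nrow(e_mat)
  if (is.null(pos)) pos <- matrix(0, n, 3)
  df <- data.frame(t_s = seq_len(n) * 0.02, x_mm = pos[, 1],
                   y_mm = pos[, 2], z_mm = pos[, 3],
                   distance_mm = rep(1, n))
  e <- as.data.frame(e_mat); names(e) <- paste0("e_", seq_len(ncol(e_mat)))
  f <- as.data.frame(f_mat); names(f) <- paste0("f_", seq_len(ncol(f_mat)))
  cbind(df, e, f)
}

test_that("range of motion identities: reference, degenerate, scaling", {
  env <- test_envelope(0)
  expect_equal(range_of_motion(env$points, env), 100, tolerance = 1e-6)
  expect_equal(range_of_motion(matrix(1, 1, 3), env), 0)
  ctr <- colMeans(env$points)
  halfway <- sweep(sweep(env$points, 2, ctr), 1, 0.5, "*")
  halfway <- sweep(halfway, 2, ctr, "+")
  expect_equal(range_of_motion(halfway, env), 12.5, tolerance = 1e-6)
})

test_that("metabolic efficiency is the inverse pooled mean tension", {
  e <- matrix(0.1, 10, 24)
  f2 <- matrix(2, 10, 24)              # constant 2 N everywhere
  expect_equal(metabolic_efficiency(fake_record(e, f2)), 0.5,
               tolerance = 1e-12)
  # homogeneity: doubling tensions halves ME
  expect_equal(metabolic_efficiency(fake_record(e, 2 * f2)), 0.25,
               tolerance = 1e-12)
  # pooled two-episode oracle: steps weighted, not episodes
  f_a <- matrix(1, 4, 24); f_b <- matrix(4, 8, 24)
  recs <- list(fake_record(matrix(0, 4, 24), f_a),
               fake_record(matrix(0, 8, 24), f_b))
  expect_equal(metabolic_efficiency(recs), 1 / mean(c(rep(1, 4), rep(4, 8))),
               tolerance = 1e-12)
  # all-zero tensions: capped sentinel with flag
  me0 <- metabolic_efficiency(fake_record(e, 0 * f2))
  expect_true(isTRUE(attr(me0, "capped")))
})

test_that("accuracy averages distances before inverting", {
  expect_equal(as.numeric(accuracy(c(0.5, 0.5, 0.5))), 2, tolerance = 1e-12)
  expect_equal(as.numeric(accuracy(c(1, 3))), 0.5, tolerance = 1e-12)
  set.seed(6)
  d21 <- runif(21, 0.1, 5)
  expect_equal(as.numeric(accuracy(d21)), 1 / mean(d21), tolerance = 1e-12)
  expect_true(isTRUE(attr(accuracy(rep(0, 5)), "capped")))
})

test_that("symmetry inverts the pooled L1 excitation gap with a floor", {
  # constant gap 0.2: one left channel offset by 0.2
  e <- matrix(0, 6, 24); e[, 1] <- 0.2
  expect_equal(symmetry(fake_record(e, matrix(0, 6, 24))), 5,
               tolerance = 1e-12)
  # hand-built 3-step trace
  e3 <- matrix(0, 3, 24)
  e3[1, 2] <- 0.4; e3[2, 14] <- 0.1; e3[3, 5] <- 0.25
  gaps <- c(0.4, 0.1, 0.25)
  expect_equal(symmetry(fake_record(e3, matrix(0, 3, 24))),
               1 / mean(gaps), tolerance = 1e-12)
  # perfectly symmetric trace hits the floored cap
  sym <- symmetry(fake_record(matrix(0.3, 5, 24), matrix(0, 5, 24)))
  expect_equal(sym, 1e6)
})

test_that("agility is inverse traversal time and flags failures", {
  ag <- agility(list(times_s = c(0.8, 1.2), reached = c(TRUE, TRUE)))
  expect_equal(as.numeric(ag), 0.5, tolerance = 1e-12)
  expect_false(isTRUE(attr(ag, "failed")))
  # an extra waypoint can only increase total time
  ag3 <- agility(list(times_s = c(0.8, 1.2, 0.5),
                      reached = c(TRUE, TRUE, TRUE)))
  expect_lt(as.numeric(ag3), as.numeric(ag))
  agf <- agility(list(times_s = c(0.8, 2.0), reached = c(TRUE, FALSE)))
  expect_true(isTRUE(attr(agf, "failed")))
})

test_that("ME and Sym are order-independent across episode concatenation", {
  set.seed(8)
  e1 <- matrix(runif(12 * 24), 12, 24); f1 <- matrix(runif(12 * 24), 12, 24)
  e2 <- matrix(runif(30 * 24), 30, 24); f2 <- matrix(runif(30 * 24), 30, 24)
  recs <- list(fake_record(e1, f1), fake_record(e2, f2))
  pooled <- list(fake_record(rbind(e1, e2), rbind(f1, f2)))
  expect_equal(metabolic_efficiency(recs), metabolic_efficiency(pooled),
               tolerance = 1e-12)
  expect_equal(symmetry(recs), symmetry(pooled), tolerance = 1e-12)
})

test_that("evaluation protocol targets lie inside the reference hull", {
  env <- test_envelope(0)
  proto <- evaluation_protocol(env)
  expect_equal(nrow(proto$targets), 21)
  expect_true(all(hull_contains(env$hull, proto$targets, tol = 1e-6)))
  # deterministic for a fixed seed
  proto2 <- evaluation_protocol(env)
  expect_identical(proto$targets, proto2$targets)
})

test_that("evaluate_policy on a scripted zero policy gives the rest-pose metrics", {
  m <- test_model(0)
  env0 <- test_envelope(0)
  env <- jaw_env(m, env0)
  proto <- evaluation_protocol(env0, n_face = 2, n_interior = 2)
  ev <- evaluate_policy(scripted_policy(rep(0, 24)), env, proto,
                        include_agility = FALSE)
  # the jaw never leaves rest: accuracy equals 1 / mean(rest-to-target)
  d <- sqrt(rowSums(proto$targets^2))
  d[d < 0.1] <- sqrt(sum(proto$targets["ICP", ]^2))
  expect_equal(as.numeric(ev$metrics$Ac_per_mm),
               1 / mean(ev$final_distances), tolerance = 1e-12)
  expect_equal(ev$metrics$mean_final_distance_mm, mean(ev$final_distances))
  expect_lt(ev$metrics$ROM_percent, 1)
  expect_true(all(is.finite(unlist(ev$metrics[c("ROM_percent", "ME_per_N",
                                                "Ac_per_mm", "Sym")]))))
})

test_that("metrics report serializes with sentinel flags", {
  rep0 <- structure(list(ROM_percent = 42.1,
                         ME_per_N = structure(1e6, capped = TRUE),
                         Ag_per_s = structure(0.4, failed = FALSE),
                         Ac_per_mm = 2.5, Sym = 7,
                         mean_final_distance_mm = 0.4, n_targets = 21),
                    class = "metrics_report")
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  write_metrics_report(rep0, jp, cp)
  j <- jsonlite::read_json(jp)
  expect_true(j$ME_capped)
  expect_equal(j$ROM_percent, 42.1)
  df <- read.csv(cp)
  expect_equal(df$Ac_per_mm, 2.5)
  unlink(c(jp, cp))
})
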