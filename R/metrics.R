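#' Evaluation protocol: targets and agility traversal
#'
#' The standard protocol uses 21 targets: the 8 envelope end-points, the
#' centroid of the end-points, and 12 seeded points on hull faces and in
#' the interior. The agility traversal visits
#' ICP, MO, E, RL, E, LL, E, PR, ICP in order with a 1 mm reach radius.
#'
#' @param endpoints an `envelope_endpoints`.
#' @param n_face,n_interior numbers of face / interior sample targets.
#' @param seed seed for the sampled targets.
#' @param reach_radius agility waypoint radius (mm).
#' @param waypoints traversal labels (rows of `endpoints$points`).
#' @return An object of class `"evaluation_protocol"`: list with `targets`
#'   (n x 3), `labels`, `waypoints`, `reach_radius`.
#' @export
evaluation_protocol <- function(endpoints, n_face = 6, n_interior = 6,
                                seed = 1L, reach_radius = 1.0,
                                waypoints = c("ICP", "MO", "E", "RL", "E",
                                              "LL", "E", "PR", "ICP")) {
  pts <- endpoints$points
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  centroid <- colMeans(pts)
  faces <- endpoints$hull$faces
  face_pts <- t(vapply(seq_len(n_face), function(i) {
    f <- faces[sample.int(nrow(faces), 1), ]
    w <- runif(3); w <- w / sum(w)
    as.numeric(t(pts[f, ]) %*% w)
  }, numeric(3)))
  int_pts <- t(vapply(seq_len(n_interior), function(i) {
    w <- runif(8); w <- w / sum(w)
    as.numeric(t(pts) %*% w)
  }, numeric(3)))
  targets <- rbind(pts, centroid, face_pts, int_pts)
  labels <- c(rownames(pts), "centroid",
              paste0("face", seq_len(n_face)),
              paste0("interior", seq_len(n_interior)))
  stopifnot(all(waypoints %in% rownames(pts)))
  structure(list(targets = targets, labels = labels,
                 waypoints = waypoints, reach_radius = reach_radius),
            class = "evaluation_protocol")
}

# run one deterministic episode toward `target`; returns the per-step
# record and summary fields
.rollout <- function(policy_fun, env, target, start_state = NULL,
                     reach_radius = NULL) {
  obs <- env$reset(target = target, state = start_state)
  T_max <- env$cfg$max_steps
  n <- env$n_muscles
  rec <- matrix(NA_real_, T_max, 5 + 2 * n)
  reached_at <- NA_integer_
  radius <- if (is.null(reach_radius)) env$cfg$success_radius
            else reach_radius
  steps <- 0L
  repeat {
    a <- policy_fun(obs)
    st <- env$step(a)
    steps <- steps + 1L
    s <- env$state()
    rec[steps, ] <- c(steps * env$cfg$substeps * env$cfg$dt,
                      s$position, st$info$distance, s$excitations,
                      st$info$tensions)
    if (is.na(reached_at) && st$info$distance < radius)
      reached_at <- steps
    obs <- st$observation
    if (st$done || steps >= T_max) break
  }
  rec <- rec[seq_len(steps), , drop = FALSE]
  colnames(rec) <- c("t_s", "x_mm", "y_mm", "z_mm", "distance_mm",
                     paste0("e_", seq_len(n)), paste0("f_", seq_len(n)))
  list(record = structure(as.data.frame(rec),
                          final_distance = rec[steps, "distance_mm"],
                          reached_at = reached_at,
                          timeout = is.na(reached_at)),
       final_distance = rec[steps, "distance_mm"],
       reached_at = reached_at, steps = steps,
       time_s = steps * env$cfg$substeps * env$cfg$dt)
}

#' Range of motion
#'
#' Percentage of the reference envelope hull volume achieved by the convex
#' hull of all visited mid-incisal positions.
#'
#' @param achieved n x 3 matrix of visited positions (mm).
#' @param endpoints the reference `envelope_endpoints`.
#' @return ROM in percent; degenerate achieved sets give 0.
#' @export
range_of_motion <- function(achieved, endpoints) {
  stopifnot(endpoints$volume > 0)
  achieved <- matrix(as.numeric(achieved), ncol = 3)
  if (nrow(achieved) < 4) return(0)
  vol <- suppressWarnings(convex_hull_volume(achieved))
  100 * vol / endpoints$volume
}

.pooled_steps <- function(records, cols) {
  do.call(rbind, lapply(records, function(r) as.matrix(r[, cols,
                                                         drop = FALSE])))
}

#' Metabolic efficiency
#'
#' Inverse of the time-averaged mean muscle tension, pooled over every step
#' of the supplied rollouts: `ME = [ mean_t( mean_i f_it ) ]^-1` (1/N).
#'
#' @param records list of rollout records (data frames with `f_*` columns).
#' @param cap sentinel value reported when all tensions are zero.
#' @return ME in 1/N, with attribute `capped` when the sentinel applies.
#' @export
metabolic_efficiency <- function(records, cap = 1e6) {
  if (is.data.frame(records)) records <- list(records)
  f <- .pooled_steps(records, grep("^f_", names(records[[1]])))
  stopifnot(nrow(f) >= 1)
  denom <- mean(rowMeans(f))
  if (denom <= 0) return(structure(cap, capped = TRUE))
  1 / denom
}

#' Agility
#'
#' Inverse of the total simulated time needed to visit the waypoints in
#' order, each within the reach radius. Unreached waypoints contribute
#' their episode timeout and set the `failed` attribute.
#'
#' @param traversal result of a waypoint traversal as returned by
#'   [evaluate_policy()] (list with `times_s` and `reached` per leg), or a
#'   numeric vector of per-leg times with a logical `reached` attribute.
#' @return Agility in 1/s, attribute `failed` if any waypoint was missed.
#' @export
agility <- function(traversal) {
  if (is.list(traversal) && !is.null(traversal$times_s)) {
    times <- traversal$times_s
    reached <- traversal$reached
  } else {
    times <- as.numeric(traversal)
    reached <- attr(traversal, "reached") %||% rep(TRUE, length(times))
  }
  total <- sum(times)
  structure(1 / total, failed = any(!reached))
}

#' Accuracy
#'
#' Inverse of the mean final Euclidean distance to the target over
#' evaluation episodes (distances are averaged first, then inverted).
#'
#' @param final_distances numeric vector of final distances (mm).
#' @param cap sentinel for a zero mean distance.
#' @return Accuracy in 1/mm.
#' @export
accuracy <- function(final_distances, cap = 1e6) {
  stopifnot(length(final_distances) >= 1)
  m <- mean(final_distances)
  if (m <= 0) return(structure(cap, capped = TRUE))
  1 / m
}

#' Symmetry
#'
#' Inverse of the pooled time-average of the L1 gap between left and right
#' excitation sub-vectors; the denominator is floored at `eps` so perfectly
#' symmetric traces report the capped maximum.
#'
#' @param records list of rollout records with `e_*` columns (first half
#'   left, second half right, matched by bilateral pair).
#' @param eps denominator floor.
#' @return Symmetry (dimensionless).
#' @export
symmetry <- function(records, eps = 1e-6) {
  if (is.data.frame(records)) records <- list(records)
  e <- .pooled_steps(records, grep("^e_", names(records[[1]])))
  half <- ncol(e) / 2
  gaps <- rowSums(abs(e[, seq_len(half), drop = FALSE] -
                      e[, half + seq_len(half), drop = FALSE]))
  1 / max(mean(gaps), eps)
}

#' Evaluate a trained policy on the standard protocol
#'
#' Runs one deterministic episode to every protocol target, plus the
#' ordered agility traversal, and assembles the five performance metrics:
#' range of motion (ROM, % of the reference hull), metabolic efficiency
#' (ME, 1/N), agility (Ag, 1/s), accuracy (Ac, 1/mm) and symmetry (Sym).
#'
#' @param policy a fitted [jaw_sac()] object, or a function
#'   `observation -> action` (e.g. a scripted policy).
#' @param env a [jaw_env()]; defaults to the fitted object's environment.
#' @param protocol an [evaluation_protocol()]; defaults to the standard
#'   21-target protocol for the environment's envelope.
#' @param include_agility run the waypoint traversal.
#' @return An object of class `"policy_evaluation"`: list with `metrics`
#'   (a `metrics_report`), `records` (per-target rollout data frames) and
#'   `traversal`.
#' @export
evaluate_policy <- function(policy, env = NULL, protocol = NULL,
                            include_agility = TRUE) {
  if (inherits(policy, "jaw_sac")) {
    if (is.null(env))
      env <- jaw_env(policy$model, policy$endpoints,
                     policy$reward_weights, policy$episode_cfg)
    pol <- .policy_fun(policy, deterministic = TRUE)
  } else {
    stopifnot(is.function(policy), !is.null(env))
    pol <- policy
  }
  if (is.null(protocol)) protocol <- evaluation_protocol(env$endpoints)

  records <- list()
  finals <- numeric(nrow(protocol$targets))
  for (i in seq_len(nrow(protocol$targets))) {
    ro <- .rollout(pol, env, protocol$targets[i, ])
    rec <- ro$record
    rec$target_label <- protocol$labels[i]
    records[[i]] <- rec
    finals[i] <- ro$final_distance
  }
  names(records) <- protocol$labels

  traversal <- NULL
  if (include_agility) {
    wp <- protocol$waypoints
    times <- numeric(length(wp) - 1)
    reached <- logical(length(wp) - 1)
    state <- NULL
    trav_records <- list()
    for (k in seq_along(times)) {
      tgt <- env$endpoints$points[wp[k + 1], ]
      ro <- .rollout(pol, env, tgt, start_state = state,
                     reach_radius = protocol$reach_radius)
      times[k] <- if (is.na(ro$reached_at))
        env$cfg$max_steps * env$cfg$substeps * env$cfg$dt
      else ro$reached_at * env$cfg$substeps * env$cfg$dt
      reached[k] <- !is.na(ro$reached_at)
      trav_records[[k]] <- ro$record
      state <- env$state()
    }
    traversal <- list(legs = paste(head(wp, -1), wp[-1], sep = "->"),
                      times_s = times, reached = reached,
                      records = trav_records)
  }

  all_pos <- .pooled_steps(records, c("x_mm", "y_mm", "z_mm"))
  rom <- range_of_motion(all_pos, env$endpoints)
  report <- structure(list(
    ROM_percent = rom,
    ME_per_N = metabolic_efficiency(records),
    Ag_per_s = if (include_agility) agility(traversal) else NA_real_,
    Ac_per_mm = accuracy(finals),
    Sym = symmetry(records),
    mean_final_distance_mm = mean(finals),
    n_targets = length(finals)), class = "metrics_report")
  structure(list(metrics = report, records = records,
                 traversal = traversal, final_distances = finals),
            class = "policy_evaluation")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Masticatory performance metrics\n")
  cat(sprintf("  ROM  %8.2f %% of reference hull\n", x$ROM_percent))
  cat(sprintf("  ME   %8.4f 1/N%s\n", x$ME_per_N,
              if (isTRUE(attr(x$ME_per_N, "capped"))) " (capped)" else ""))
  if (!is.na(x$Ag_per_s))
    cat(sprintf("  Ag   %8.4f 1/s%s\n", x$Ag_per_s,
                if (isTRUE(attr(x$Ag_per_s, "failed")))
                  " (traversal incomplete)" else ""))
  cat(sprintf("  Ac   %8.4f 1/mm%s\n", x$Ac_per_mm,
              if (isTRUE(attr(x$Ac_per_mm, "capped"))) " (capped)" else ""))
  cat(sprintf("  Sym  %8.4f\n", x$Sym))
  cat(sprintf("  mean final distance %.4f mm over %d targets\n",
              x$mean_final_distance_mm, x$n_targets))
  invisible(x)
}

#' Serialize a metrics report
#'
#' @param report a `metrics_report`.
#' @param json_path,csv_path output paths (`NULL` to skip). Sentinel-capped
#'   values are written as the capped value with an explicit flag column.
#' @return Invisibly, the paths written.
#' @export
write_metrics_report <- function(report, json_path = NULL, csv_path = NULL) {
  flat <- list(ROM_percent = as.numeric(report$ROM_percent),
               ME_per_N = as.numeric(report$ME_per_N),
               ME_capped = isTRUE(attr(report$ME_per_N, "capped")),
               Ag_per_s = as.numeric(report$Ag_per_s),
               Ag_failed = isTRUE(attr(report$Ag_per_s, "failed")),
               Ac_per_mm = as.numeric(report$Ac_per_mm),
               Ac_capped = isTRUE(attr(report$Ac_per_mm, "capped")),
               Sym = as.numeric(report$Sym),
               mean_final_distance_mm = report$mean_final_distance_mm,
               n_targets = report$n_targets)
  written <- character()
  if (!is.null(json_path)) {
    jsonlite::write_json(flat, json_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, json_path)
  }
  if (!is.null(csv_path)) {
    write.csv(as.data.frame(flat), csv_path, row.names = FALSE)
    written <- c(written, csv_path)
  }
  invisible(written)
}
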