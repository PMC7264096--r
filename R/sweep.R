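#' Specification of a reward-coefficient sweep
#'
#' Defaults mirror the coefficient studies: seven force-regularization
#' values `w_r` in {0, 0.1, 0.25, 0.5, 1, 2, 5} (with `w_s = 0`), and six
#' symmetry values `w_s` in {0, 1, 5, 10, 20, 50} trained with `w_r = 0.5`.
#'
#' @param coefficient `"w_r"` or `"w_s"`.
#' @param values coefficient values; one model is trained per (value,
#'   seed).
#' @param fixed named list of the non-swept reward coefficients.
#' @param seeds training seeds (replicates per value).
#' @param total_steps training budget per model (environment steps).
#' @param sac a [sac_config()] used for every model.
#' @return An object of class `"sweep_spec"`.
#' @export
sweep_spec <- function(coefficient = c("w_r", "w_s"), values = NULL,
                       fixed = NULL, seeds = 1L, total_steps = 30000,
                       sac = sac_config()) {
  coefficient <- match.arg(coefficient)
  if (is.null(values))
    values <- if (coefficient == "w_r") c(0, 0.1, 0.25, 0.5, 1, 2, 5)
              else c(0, 1, 5, 10, 20, 50)
  if (is.null(fixed))
    fixed <- if (coefficient == "w_r") list(w_u = 1, w_s = 0)
             else list(w_u = 1, w_r = 0.5)
  stopifnot(length(values) >= 2, total_steps > 0)
  structure(list(coefficient = coefficient, values = values, fixed = fixed,
                 seeds = as.integer(seeds),
                 total_steps = as.integer(total_steps), sac = sac),
            class = "sweep_spec")
}

#' Pearson correlation with a degenerate-variance guard
#'
#' @param x,y numeric vectors.
#' @return The Pearson correlation; exactly 0 with attribute
#'   `degenerate = TRUE` when either input has zero variance.
#' @export
pearson_or_zero <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(0, degenerate = TRUE))
  stats::cor(x, y, method = "pearson")
}

#' Run a reward-coefficient sweep
#'
#' Trains one model per (coefficient value, seed), evaluates each with the
#' standard protocol, and computes the Pearson correlation of each
#' performance metric against the swept coefficient (pooled over seeds).
#' Models whose training diverges are recorded and excluded from the
#' correlations with a warning.
#'
#' @param spec a [sweep_spec()].
#' @param model a `jaw_model` shared by all runs.
#' @param endpoints its envelope (computed if `NULL`).
#' @param cfg an [episode_config()].
#' @param protocol an [evaluation_protocol()] (standard if `NULL`).
#' @param verbose print one line per trained model.
#' @return An object of class `"sweep_result"`: list with `table` (one row
#'   per value x seed: metrics and status) and `correlations` (named
#'   vector).
#' @export
run_sweep <- function(spec, model = NULL, endpoints = NULL,
                      cfg = episode_config(), protocol = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (is.null(model)) model <- generate_jaw_model(seed = 1L)
  if (is.null(endpoints)) endpoints <- compute_envelope(model)
  if (is.null(protocol)) protocol <- evaluation_protocol(endpoints)
  rows <- list()
  for (val in spec$values) {
    for (sd in spec$seeds) {
      wl <- spec$fixed
      wl[[spec$coefficient]] <- val
      w <- reward_weights(w_u = wl$w_u %||% 1, w_r = wl$w_r %||% 0,
                          w_s = wl$w_s %||% 0)
      fit <- tryCatch(
        jaw_sac(model, endpoints, weights = w, cfg = cfg, sac = spec$sac,
                total_steps = spec$total_steps, seed = sd),
        error = function(e) e)
      if (inherits(fit, "error")) {
        warning("training diverged for ", spec$coefficient, " = ", val,
                ", seed ", sd, ": ", conditionMessage(fit))
        rows[[length(rows) + 1]] <- data.frame(
          value = val, seed = sd, ROM = NA, ME = NA, Ag = NA, Ac = NA,
          Sym = NA, mean_final_distance_mm = NA, diverged = TRUE)
        next
      }
      ev <- evaluate_policy(fit, protocol = protocol)
      mr <- ev$metrics
      rows[[length(rows) + 1]] <- data.frame(
        value = val, seed = sd, ROM = as.numeric(mr$ROM_percent),
        ME = as.numeric(mr$ME_per_N), Ag = as.numeric(mr$Ag_per_s),
        Ac = as.numeric(mr$Ac_per_mm), Sym = as.numeric(mr$Sym),
        mean_final_distance_mm = mr$mean_final_distance_mm,
        diverged = FALSE)
      if (verbose)
        cat(sprintf("%s = %-5g seed %d: ROM %.1f%%  ME %.3f  Ac %.2f\n",
                    spec$coefficient, val, sd, mr$ROM_percent,
                    mr$ME_per_N, mr$Ac_per_mm))
    }
  }
  tab <- do.call(rbind, rows)
  ok <- !tab$diverged
  cors <- vapply(c("ME", "ROM", "Ac", "Ag", "Sym"), function(mname)
    as.numeric(pearson_or_zero(tab$value[ok], tab[[mname]][ok])),
    numeric(1))
  structure(list(table = tab, correlations = cors,
                 coefficient = spec$coefficient, spec = spec),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Sweep over", x$coefficient, "(", nrow(x$table), "models )\n")
  print(x$table, row.names = FALSE)
  cat("\nPearson correlations vs", x$coefficient, ":\n")
  print(round(x$correlations, 3))
  invisible(x)
}

#' Record excitation traces for canonical jaw movements
#'
#' Runs the five canonical movements (opening ICP to MO, closing MO to E,
#' right laterotrusion E to RL and back, protrusion E to PR) under the
#' deterministic policy, starting each movement from the previous
#' end-point's canonical pose, and records the per-step excitations of all
#' 24 channels.
#'
#' @param object a fitted `jaw_sac`.
#' @param movements character vector of `"FROM->TO"` labels among the
#'   envelope end-points.
#' @return A data frame with columns `movement`, `step`, `t_s`,
#'   `e_1` .. `e_24` (all in `[0, 1]`).
#' @export
record_excitation_traces <- function(object,
                                     movements = c("ICP->MO", "MO->E",
                                                   "E->RL", "RL->E",
                                                   "E->PR")) {
  stopifnot(inherits(object, "jaw_sac"))
  env <- jaw_env(object$model, object$endpoints, object$reward_weights,
                 object$episode_cfg)
  pol <- .policy_fun(object, deterministic = TRUE)
  pats <- envelope_patterns()
  out <- list()
  for (mv in movements) {
    ft <- strsplit(mv, "->", fixed = TRUE)[[1]]
    stopifnot(length(ft) == 2, all(ft %in% rownames(object$endpoints$points)))
    start <- jaw_state(position = object$endpoints$points[ft[1], ],
                       excitations = pattern_excitations(object$model,
                                                         pats[[ft[1]]]))
    ro <- .rollout(pol, env, object$endpoints$points[ft[2], ],
                   start_state = start)
    rec <- ro$record
    df <- cbind(data.frame(movement = mv, step = seq_len(nrow(rec)),
                           t_s = rec$t_s),
                rec[, grep("^e_", names(rec)), drop = FALSE])
    out[[mv]] <- df
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
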