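#' Canonical excitation patterns for the envelope end-points
#'
#' Constant excitation patterns, defined on functional roles and individual
#' muscles, whose equilibria realise the eight labeled extremes of the
#' Posselt-style envelope of motion: maximum intercuspation (ICP),
#' edge-to-edge (E), maximum protrusion (PR), maximum left/right
#' laterotrusion (LL/RL), retruded contact position (RCP), end of pure
#' rotational opening (R) and maximum mouth opening (MO).
#'
#' Each pattern is a named numeric vector; names are muscle names, sides
#' (`"left"`/`"right"`) combined with roles as `side.role`, or plain roles.
#' [pattern_excitations()] resolves them against a model's muscle table
#' (muscle name first, then `side.role`, then role).
#'
#' @return A named list of eight patterns.
#' @export
envelope_patterns <- function() {
  list(
    ICP = c(),
    E   = c(depressor = 0.002, protruder = 0.12),
    PR  = c(protruder = 0.8, lateral = 0.25),
    LL  = c(right.lateral = 1.0, depressor = 0.005),
    RL  = c(left.lateral = 1.0, depressor = 0.005),
    RCP = c(LPT = 0.015, RPT = 0.015, depressor = 0.004),
    R   = c(depressor = 0.035, LPT = 0.015, RPT = 0.015),
    MO  = c(depressor = 1.0)
  )
}

#' Resolve a named excitation pattern to a 24-vector
#'
#' @param model a `jaw_model`.
#' @param pattern named numeric vector (see [envelope_patterns()]).
#' @return Excitation vector ordered as the model's muscle table.
#' @export
pattern_excitations <- function(model, pattern) {
  m <- model$muscles
  e <- rep(0, nrow(m))
  for (key in names(pattern)) {
    val <- pattern[[key]]
    hit <- m$name == key
    if (!any(hit)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      hit <- if (length(parts) == 2)
        m$side == parts[1] & m$role == parts[2]
      else m$role == key
    }
    if (!any(hit)) stop("pattern key matches no muscle: ", key)
    e[hit] <- val
  }
  e
}

#' Compute the envelope of motion end-points
#'
#' Drives the jaw to equilibrium under each of the eight canonical constant
#' excitation patterns and records the settled mid-incisal positions,
#' together with the volume of their convex hull.
#'
#' @param model a `jaw_model`.
#' @param patterns pattern list as from [envelope_patterns()].
#' @param tol,max_time,dt passed to [equilibrium_position()].
#' @return An object of class `"envelope_endpoints"`: a list with `points`
#'   (8 x 3 matrix, labeled rows), `hull` (faces/normals/offsets from
#'   [convex_hull_3d()]) and `volume` (mm^3). Degenerate hulls are an error:
#'   such a model cannot be trained.
#' @export
compute_envelope <- function(model, patterns = envelope_patterns(),
                             tol = 0.05, max_time = 6, dt = 0.001) {
  pts <- t(vapply(patterns, function(p) {
    equilibrium_position(model, pattern_excitations(model, p),
                         tol = tol, max_time = max_time, dt = dt)
  }, numeric(3)))
  hull <- convex_hull_3d(pts)
  if (hull$degenerate || hull$volume <= 0)
    stop("degenerate envelope hull (volume <= 0): model unusable")
  structure(list(points = pts, hull = hull, volume = hull$volume),
            class = "envelope_endpoints")
}

#' @export
print.envelope_endpoints <- function(x, ...) {
  cat("Envelope of motion: 8 end-points, hull volume ",
      signif(x$volume, 5), " mm^3\n", sep = "")
  print(round(x$points, 2))
  invisible(x)
}

#' Export envelope end-points as CSV and the hull as an OFF polyhedron
#'
#' @param env an `envelope_endpoints` object.
#' @param csv_path,off_path output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
export_envelope <- function(env, csv_path = NULL, off_path = NULL) {
  written <- character()
  if (!is.null(csv_path)) {
    df <- data.frame(label = rownames(env$points),
                     x_mm = env$points[, 1], y_mm = env$points[, 2],
                     z_mm = env$points[, 3])
    write.csv(df, csv_path, row.names = FALSE)
    written <- c(written, csv_path)
  }
  if (!is.null(off_path)) {
    faces <- env$hull$faces
    con <- file(off_path, "w")
    on.exit(close(con))
    writeLines("OFF", con)
    writeLines(sprintf("%d %d 0", nrow(env$points), nrow(faces)), con)
    apply(env$points, 1, function(p)
      writeLines(paste(p, collapse = " "), con))
    apply(faces, 1, function(f)
      writeLines(paste(c(3, f - 1), collapse = " "), con))
    written <- c(written, off_path)
  }
  invisible(written)
}
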