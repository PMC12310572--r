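#' Simulation settings
#'
#' @param horizon Final time of the integration window (default 50).
#' @param rel_tol,abs_tol Adaptive solver tolerances (defaults 1e-8, 1e-10).
#' @param convergence_radius Max-norm distance to a vertex counting as
#'   converged (default 1e-3; must lie in (0, 0.5)).
#' @param max_extension Number of horizon doublings allowed when the
#'   trajectory has not converged at the end of the window (default 0: report
#'   unconverged rather than extrapolate).
#' @param save_dt Spacing of saved output times (default 0.1).
#' @return A list of class `sim_settings`.
#' @export
sim_settings <- function(horizon = 50, rel_tol = 1e-8, abs_tol = 1e-10,
                         convergence_radius = 1e-3, max_extension = 0,
                         save_dt = 0.1) {
  if (!is.numeric(horizon) || horizon <= 0) {
    abort("horizon must be > 0", class = "trigame_validation_error")
  }
  if (rel_tol <= 0 || abs_tol <= 0) {
    abort("solver tolerances must be > 0", class = "trigame_validation_error")
  }
  if (convergence_radius <= 0 || convergence_radius >= 0.5) {
    abort("convergence_radius must lie in (0, 0.5)",
          class = "trigame_validation_error")
  }
  structure(list(horizon = horizon, rel_tol = rel_tol, abs_tol = abs_tol,
                 convergence_radius = convergence_radius,
                 max_extension = max_extension, save_dt = save_dt),
            class = "sim_settings")
}

#' Integrate the replicator system
#'
#' Adaptive-step integration (Dormand-Prince 4/5 via [deSolve::ode()]) of the
#' three-population replicator dynamics from an initial strategy state.
#' Floating-point excursions outside the unit cube are clamped back; an
#' excursion larger than `10 * (rel_tol + abs_tol)` -- the local error scale -- is treated as an integration failure,
#' not round-off, and raises an error carrying the last valid state.
#'
#' @param params A [game_params()] object.
#' @param initial Initial state: numeric (x, y, z) in \[0,1\]^3
#'   (default c(0.5, 0.5, 0.5)).
#' @param settings A [sim_settings()] object (or arguments via `...`).
#' @param ... Passed to [sim_settings()] when `settings` is NULL.
#' @return An object of class `game_trajectory`: `$path` (tibble `t, x, y, z`),
#'   `$converged`, `$limit_vertex` (label or NA), `$params`, `$settings`.
#'   [tidy()] returns the path, [glance()] a one-row verdict.
#' @examples
#' sc <- baseline_scenarios()
#' tr <- simulate_game(sc$scenario1, sc$initial)
#' glance(tr)
#' @export
simulate_game <- function(params, initial = c(0.5, 0.5, 0.5),
                          settings = NULL, ...) {
  params <- as_game_params(params)
  s0 <- check_states(initial)
  if (nrow(s0) != 1L) abort("initial must be a single state", class = "trigame_validation_error")
  if (is.null(settings)) settings <- sim_settings(...)

  y0 <- c(x = s0$x, y = s0$y, z = s0$z)
  deriv <- function(t, state, p) list(rhs_vec(state, p))

  horizon <- settings$horizon
  extensions <- 0
  path <- NULL
  repeat {
    times <- seq(0, horizon, by = settings$save_dt)
    if (tail(times, 1) < horizon) times <- c(times, horizon)
    sol <- tryCatch(
      deSolve::ode(y = y0, times = times, func = deriv, parms = params,
                   method = "ode45", rtol = settings$rel_tol,
                   atol = settings$abs_tol),
      error = function(e) e
    )
    if (inherits(sol, "error")) {
      abort(paste0("solver failure: ", conditionMessage(sol)),
            class = "trigame_solver_error",
            last_state = if (!is.null(path)) tail(path, 1) else y0)
    }
    m <- unclass(sol)
    states <- m[, c("x", "y", "z"), drop = FALSE]
    # local error is controlled as abs_tol + rel_tol * |y|, and |y| is of
    # order 1 at the upper face, so round-off excursions scale with rel_tol
    slack <- 10 * (settings$rel_tol + settings$abs_tol)
    if (min(states) < -slack || max(states) > 1 + slack) {
      i <- which(apply(states, 1, function(r) any(r < -slack | r > 1 + slack)))[1]
      abort("state left the unit cube by more than 10 * (rel_tol + abs_tol); likely a field bug",
            class = "trigame_solver_error",
            last_state = states[max(i - 1, 1), ])
    }
    states <- pmin(pmax(states, 0), 1)
    path <- tibble::tibble(t = m[, "time"], x = states[, "x"],
                           y = states[, "y"], z = states[, "z"])
    lv <- nearest_vertex(tail(path, 1), settings$convergence_radius)
    if (!is.na(lv) || extensions >= settings$max_extension) break
    horizon <- horizon * 2
    extensions <- extensions + 1
  }

  structure(
    list(path = path, converged = !is.na(lv), limit_vertex = lv,
         params = params, settings = settings),
    class = "game_trajectory"
  )
}

nearest_vertex <- function(final, radius) {
  pp <- pure_profiles()
  d <- pmax(abs(pp$x - final$x), abs(pp$y - final$y), abs(pp$z - final$z))
  i <- which(d <= radius)
  if (length(i) == 1L) pp$label[i] else NA_character_
}

#' Which vertex (if any) a trajectory has converged to
#'
#' @param traj A `game_trajectory`, or a data frame whose last row holds the
#'   final state (columns x, y, z).
#' @param radius Max-norm convergence radius; must be < 0.5 (at 0.5 or more
#'   two vertices could qualify).
#' @return The one-row profile tibble of the limit vertex, or NULL when the
#'   final state is not within `radius` of any vertex.
#' @export
detect_convergence <- function(traj, radius = 1e-3) {
  if (radius >= 0.5) {
    abort("radius must be < 0.5 (ambiguous otherwise)",
          class = "trigame_validation_error")
  }
  if (radius <= 0) abort("radius must be > 0", class = "trigame_validation_error")
  final <- if (inherits(traj, "game_trajectory")) tail(traj$path, 1) else {
    if (!is.data.frame(traj) || nrow(traj) == 0) {
      abort("traj must be a game_trajectory or non-empty data frame",
            class = "trigame_validation_error")
    }
    tail(tibble::as_tibble(traj), 1)
  }
  lv <- nearest_vertex(final, radius)
  if (is.na(lv)) NULL else profile_coords(lv)
}

# first time the trajectory enters the convergence ball of its limit vertex,
# linearly interpolated between saved steps; Inf if never
entry_time <- function(traj, radius = traj$settings$convergence_radius) {
  if (is.na(traj$limit_vertex)) return(Inf)
  v <- profile_coords(traj$limit_vertex)
  d <- pmax(abs(traj$path$x - v$x), abs(traj$path$y - v$y),
            abs(traj$path$z - v$z))
  i <- which(d <= radius)[1]
  if (is.na(i)) return(Inf)
  if (i == 1L) return(traj$path$t[1])
  t0 <- traj$path$t[i - 1]; t1 <- traj$path$t[i]
  d0 <- d[i - 1]; d1 <- d[i]
  if (d0 == d1) t1 else t0 + (t1 - t0) * (d0 - radius) / (d0 - d1)
}

#' Multi-start integration over an interior lattice
#'
#' Integrates the replicator system from every point of a regular interior
#' lattice (offset from the faces, since each face is invariant) and tallies
#' which stable vertex each start reaches — an estimate of the basins of
#' attraction.
#'
#' @param params A [game_params()] object.
#' @param lattice_points_per_axis Lattice size per axis; 1 gives the single
#'   cube-center start (0.5, 0.5, 0.5).
#' @param settings A [sim_settings()] object.
#' @return An object of class `game_multistart`: `$trajectories` (list),
#'   `$starts` (tibble of per-start verdicts), `$summary` (counts per limit
#'   vertex, plus unconverged and errored counts).
#' @export
multi_start <- function(params, lattice_points_per_axis = 3,
                        settings = sim_settings()) {
  n <- lattice_points_per_axis
  if (n < 1) abort("lattice_points_per_axis must be >= 1", class = "trigame_validation_error")
  params <- as_game_params(params)
  g <- if (n == 1L) 0.5 else seq(1 / (n + 1), n / (n + 1), length.out = n)
  starts <- expand.grid(x = g, y = g, z = g)

  runs <- purrr::map(seq_len(nrow(starts)), function(i) {
    tryCatch(
      simulate_game(params, as.numeric(starts[i, ]), settings = settings),
      error = function(e) e
    )
  })
  verdicts <- purrr::map_dfr(seq_along(runs), function(i) {
    r <- runs[[i]]
    if (inherits(r, "error")) {
      tibble::tibble(x0 = starts$x[i], y0 = starts$y[i], z0 = starts$z[i],
                     converged = NA, limit_vertex = NA_character_,
                     error = conditionMessage(r))
    } else {
      tibble::tibble(x0 = starts$x[i], y0 = starts$y[i], z0 = starts$z[i],
                     converged = r$converged,
                     limit_vertex = if (r$converged) r$limit_vertex else NA_character_,
                     error = NA_character_)
    }
  })
  summary <- verdicts |>
    dplyr::count(.data$limit_vertex, name = "n_starts") |>
    dplyr::arrange(dplyr::desc(.data$n_starts))
  structure(list(trajectories = runs, starts = verdicts, summary = summary,
                 params = params, settings = settings),
            class = "game_multistart")
}

#' @export
print.game_trajectory <- function(x, ...) {
  cat("<game_trajectory> ", nrow(x$path), " saved states over t in [0, ",
      max(x$path$t), "]\n", sep = "")
  f <- tail(x$path, 1)
  cat(sprintf("final state: (%.6g, %.6g, %.6g); %s\n", f$x, f$y, f$z,
              if (x$converged) paste0("converged to ", x$limit_vertex)
              else "unconverged"))
  invisible(x)
}

#' @rdname simulate_game
#' @param x A `game_trajectory` object.
#' @export
tidy.game_trajectory <- function(x, ...) x$path

#' @rdname simulate_game
#' @export
glance.game_trajectory <- function(x, ...) {
  f <- tail(x$path, 1)
  tibble::tibble(
    horizon = max(x$path$t),
    x_final = f$x, y_final = f$y, z_final = f$z,
    converged = x$converged,
    limit_vertex = if (x$converged) x$limit_vertex else NA_character_,
    entry_time = entry_time(x)
  )
}

#' @export
print.game_multistart <- function(x, ...) {
  cat("<game_multistart> ", nrow(x$starts), " interior starts\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname multi_start
#' @param x A `game_multistart` object.
#' @param ... Unused.
#' @export
tidy.game_multistart <- function(x, ...) x$starts

#' @rdname multi_start
#' @export
glance.game_multistart <- function(x, ...) {
  tibble::tibble(
    n_starts = nrow(x$starts),
    n_converged = sum(x$starts$converged %in% TRUE),
    n_unconverged = sum(x$starts$converged %in% FALSE),
    n_errored = sum(!is.na(x$starts$error)),
    vertices = paste(stats::na.omit(unique(x$starts$limit_vertex)), collapse = ",")
  )
}
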