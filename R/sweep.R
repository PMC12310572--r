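#' One-parameter sensitivity sweep
#'
#' Replaces one game constant by each value in turn, integrates the replicator
#' system from a common initial state, and records the convergence outcome and
#' the first time the trajectory enters the convergence radius of its limit
#' vertex (linearly interpolated between saved steps; Inf when unconverged).
#'
#' @param params Base [game_params()] object.
#' @param name Symbol to sweep (one of [param_names()]).
#' @param values Non-empty numeric vector of nonnegative replacement values.
#' @param initial Initial state (default the cube center).
#' @param settings A [sim_settings()] object.
#' @return An object of class `game_sweep`: [tidy()] gives one row per value
#'   (`swept, value, converged, limit_vertex, entry_time, x_final, y_final,
#'   z_final`); `$trajectories` holds the underlying `game_trajectory`
#'   objects.
#' @examples
#' sc <- baseline_scenarios()
#' sweep_parameter(sc$scenario2, "Gs", c(5, 10, 15))
#' @export
sweep_parameter <- function(params, name, values,
                            initial = c(0.5, 0.5, 0.5),
                            settings = sim_settings()) {
  params <- as_game_params(params)
  if (length(name) != 1L || !name %in% param_names()) {
    abort(paste0("unknown sweep symbol: ", paste(name, collapse = ",")),
          class = "trigame_config_error")
  }
  if (length(values) == 0) {
    abort("sweep values must be non-empty", class = "trigame_config_error")
  }
  if (any(!is.finite(values) | values < 0)) {
    abort("sweep values must be nonnegative and finite",
          class = "trigame_validation_error")
  }
  runs <- purrr::map(values, function(v) {
    simulate_game(set_param(params, name, v), initial, settings = settings)
  })
  tab <- purrr::map2_dfr(values, runs, function(v, r) {
    g <- glance(r)
    tibble::tibble(swept = name, value = v, converged = g$converged,
                   limit_vertex = g$limit_vertex, entry_time = g$entry_time,
                   x_final = g$x_final, y_final = g$y_final,
                   z_final = g$z_final)
  })
  structure(list(table = tab, trajectories = runs, base_params = params,
                 initial = check_states(initial), settings = settings),
            class = "game_sweep")
}

#' Sweep a constant by relative increments
#'
#' Sweeps `name` over `base * (1 + fraction)` for each fraction — e.g. the
#' 5/10/15 percent fine-increase scenarios.
#'
#' @inheritParams sweep_parameter
#' @param fractions Numeric vector of relative increments, each > -1.
#' @return A `game_sweep` whose table carries an extra `fraction` column.
#' @export
relative_increment_scenarios <- function(params, name, fractions,
                                         initial = c(0.5, 0.5, 0.5),
                                         settings = sim_settings()) {
  if (any(fractions <= -1)) {
    abort("fractions must each be > -1", class = "trigame_validation_error")
  }
  params <- as_game_params(params)
  if (length(name) != 1L || !name %in% param_names()) {
    abort(paste0("unknown sweep symbol: ", name), class = "trigame_config_error")
  }
  base <- unclass(params)[[name]]
  sw <- sweep_parameter(params, name, base * (1 + fractions), initial, settings)
  sw$table <- dplyr::mutate(sw$table, fraction = fractions,
                            .after = "value")
  sw
}

#' The six printed sensitivity sweeps
#'
#' Runs the standard sweep battery against a base scenario (by default the
#' second printed scenario, Wt = 7, in whose regime the cooperative vertex
#' E3(0,1,0) is the unique stable profile): subsidies Gs over 5/10/15, the
#' fine level over 20/150/300, remediation cost Gg over 50/150/200, regulatory
#' cost Cr over 40/100/150, reasonable-treatment income Wt over 4/8/12 and
#' overtreatment income Wm over 15/10/5.
#'
#' The fine sweep varies `Gf` by default. Note that the fine does not enter
#' the regulator's own advantage function, so in this model fines act on
#' institutions, never on the regulator's strategy. `fine_symbol = "Pg"`
#' instead varies the credibility stake, reproducing the sweep exactly as
#' printed.
#'
#' @param base_params Base [game_params()] (default: scenario 2).
#' @param settings A [sim_settings()] object.
#' @param initial Common initial state (default cube center).
#' @param fine_symbol `"Gf"` (default) or `"Pg"` for the fine-level sweep.
#' @return A named list of `game_sweep` objects of class `game_sweep_suite`;
#'   [tidy()] binds all sweep tables.
#' @export
standard_sweep_suite <- function(base_params = baseline_scenarios()$scenario2,
                              settings = sim_settings(),
                              initial = c(0.5, 0.5, 0.5),
                              fine_symbol = c("Gf", "Pg")) {
  fine_symbol <- match.arg(fine_symbol)
  base_params <- as_game_params(base_params)
  plan <- list(
    subsidy = list(name = "Gs", values = c(5, 10, 15)),
    fine = list(name = fine_symbol, values = c(20, 150, 300)),
    remediation = list(name = "Gg", values = c(50, 150, 200)),
    regulation = list(name = "Cr", values = c(40, 100, 150)),
    reasonable_income = list(name = "Wt", values = c(4, 8, 12)),
    overtreatment_income = list(name = "Wm", values = c(15, 10, 5))
  )
  out <- purrr::map(plan, function(p) {
    sweep_parameter(base_params, p$name, p$values, initial, settings)
  })
  structure(out, class = c("game_sweep_suite", "list"),
            base_params = base_params)
}

#' @export
print.game_sweep <- function(x, ...) {
  cat("<game_sweep> symbol ", x$table$swept[1], " over ",
      length(x$trajectories), " values\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @rdname sweep_parameter
#' @param x A `game_sweep` object.
#' @param ... Unused.
#' @export
tidy.game_sweep <- function(x, ...) x$table

#' @rdname sweep_parameter
#' @export
glance.game_sweep <- function(x, ...) {
  tibble::tibble(
    swept = x$table$swept[1],
    n_values = nrow(x$table),
    n_converged = sum(x$table$converged),
    vertices = paste(stats::na.omit(unique(x$table$limit_vertex)), collapse = ",")
  )
}

#' @rdname standard_sweep_suite
#' @param x A `game_sweep_suite` object.
#' @param ... Unused.
#' @export
tidy.game_sweep_suite <- function(x, ...) {
  purrr::map_dfr(x, tidy, .id = "sweep")
}

#' @export
print.game_sweep_suite <- function(x, ...) {
  cat("<game_sweep_suite> ", length(x), " sweeps\n", sep = "")
  print(tidy(x))
  invisible(x)
}
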