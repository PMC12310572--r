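#' The two printed study scenarios
#'
#' The reference parameterizations used throughout: scenario 1 has
#' reasonable-treatment income Wt = 4 (its regime is bistable: both the
#' all-defect vertex E2(1,0,0) and the cooperative vertex E3(0,1,0) are
#' locally stable, and the cube-center start reaches E2); scenario 2 is
#' identical except Wt = 7, which destabilises E2 and leaves E3 the unique
#' attractor. The common initial state is the neutral cube center.
#'
#' @return A list with `scenario1`, `scenario2` ([game_params()] objects) and
#'   `initial` (named numeric (x, y, z) = (0.5, 0.5, 0.5)).
#' @export
baseline_scenarios <- function() {
  s1 <- game_params(Cm = 6, Ct = 2, Cp = 10, Ci = 0.5, Wm = 9, Wt = 4,
                    Gf = 6, Gs = 5, Er = 2, Oc = 1.5, Eg = 7, Cr = 1,
                    Gg = 2, Pg = 1)
  list(scenario1 = s1,
       scenario2 = set_param(s1, "Wt", 7),
       initial = c(x = 0.5, y = 0.5, z = 0.5))
}

regime_tags <- function() {
  c("E2_stable_only", "E3_stable_only", "bistable", "neither")
}

# stability-structure inequalities per regime, with strict margin
regime_ok <- function(p, regime, margin = 1e-6) {
  e2 <- p[, "Wm"] - (p[, "Er"] + p[, "Oc"] + p[, "Wt"])   # > 0 => E2 stable
  e3 <- (p[, "Gs"] + p[, "Wt"] + p[, "Er"]) - p[, "Wm"]   # > 0 => E3 stable
  switch(regime,
    E2_stable_only = e2 > margin & e3 < -margin,
    E3_stable_only = e3 > margin & e2 < -margin,
    bistable = e2 > margin & e3 > margin,
    neither = e2 < -margin & e3 < -margin
  )
}

#' Sample random parameter sets from a stability regime
#'
#' Rejection-samples parameter sets, each symbol uniform on its range, until
#' `n` sets satisfy the regime's defining inequalities with strict margin
#' 1e-6: `E2_stable_only` (overtreatment dominant: Wm > Er+Oc+Wt and
#' Wm > Gs+Wt+Er), `E3_stable_only` (cooperation dominant: Wm < Gs+Wt+Er and
#' Wm < Er+Oc+Wt), `bistable` (Er+Oc+Wt < Wm < Gs+Wt+Er, which requires
#' Oc < Gs), or `neither`. Deterministic for a fixed seed.
#'
#' @param regime One of `"E2_stable_only"`, `"E3_stable_only"`, `"bistable"`,
#'   `"neither"`.
#' @param n Number of sets to produce (>= 1).
#' @param seed Integer seed.
#' @param ranges Optional named list of c(lo, hi) sampling intervals per
#'   symbol; default every symbol uniform on \[0.5, 20\].
#' @return An object of class `scenario_set`: `$params_list` (list of
#'   [game_params()]), `$regime`, `$seed`, `$ranges`; [tidy()] gives an
#'   n x 14 tibble.
#' @examples
#' ss <- sample_parameters("bistable", n = 3, seed = 42)
#' tidy(ss)
#' @export
sample_parameters <- function(regime, n, seed,
                              ranges = NULL) {
  regime <- match.arg(regime, regime_tags())
  if (n < 1) abort("n must be >= 1", class = "trigame_validation_error")
  default <- setNames(rep(list(c(0.5, 20)), 14), param_names())
  if (!is.null(ranges)) {
    bad <- setdiff(names(ranges), param_names())
    if (length(bad)) abort(paste0("unknown symbols in ranges: ",
                                  paste(bad, collapse = ", ")),
                           class = "trigame_config_error")
    default <- modifyList(default, lapply(ranges, as.numeric))
  }
  ranges <- default
  lo <- vapply(ranges, `[`, numeric(1), 1)
  hi <- vapply(ranges, `[`, numeric(1), 2)
  if (any(hi < lo) || any(lo < 0)) {
    abort("ranges must be nonnegative intervals", class = "trigame_validation_error")
  }

  accepted <- withr::with_seed(seed, {
    acc <- NULL
    drawn <- 0L
    chunk <- max(1000L, 10L * n)
    while (is.null(acc) || nrow(acc) < n) {
      m <- matrix(runif(chunk * 14, rep(lo, each = chunk),
                        rep(hi, each = chunk)),
                  nrow = chunk, dimnames = list(NULL, param_names()))
      drawn <- drawn + chunk
      keep <- regime_ok(m, regime)
      acc <- rbind(acc, m[keep, , drop = FALSE])
      if (drawn >= 1e6 && nrow(acc) / drawn < 0.001) {
        abort(paste0("acceptance rate below 0.1% for regime '", regime,
                     "'; the region may be empty for these ranges ",
                     "(bistable needs Oc < Gs) - widen the ranges"),
              class = "trigame_config_error")
      }
    }
    acc[seq_len(n), , drop = FALSE]
  })

  params_list <- lapply(seq_len(n), function(i) {
    validate_parameters(accepted[i, ])
  })
  structure(list(params_list = params_list, regime = regime, seed = seed,
                 ranges = ranges),
            class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  cat("<scenario_set> ", length(x$params_list), " parameter sets, regime ",
      x$regime, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @rdname sample_parameters
#' @param x A `scenario_set` object.
#' @param ... Unused.
#' @export
tidy.scenario_set <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(set = seq_along(x$params_list), regime = x$regime),
    purrr::map_dfr(x$params_list, ~ tibble::as_tibble(as.list(unclass(.x))))
  )
}

#' Finite-population imitation simulator
#'
#' Simulates three finite populations under proportional imitation: each
#' generation every agent revises with probability `step_scale`, samples a
#' random peer from its own population, and imitates the peer's strategy with
#' probability proportional to the positive part of the payoff advantage
#' (payoffs evaluated against the opposing populations' current frequencies).
#' The mean-field limit of this update is exactly the replicator flow, with
#' one generation corresponding to `step_scale` time units — which makes the
#' simulator an independent stochastic check on the ODE integrator.
#'
#' @param params A [game_params()] object.
#' @param pop_size Agents per population (>= 100).
#' @param generations Number of generations (>= 1).
#' @param step_scale Revision probability per generation; the elapsed model
#'   time is `generations * step_scale`.
#' @param seed Integer seed.
#' @param initial Initial strategy frequencies (x, y, z).
#' @return A tibble with columns `t`, `x`, `y`, `z` (one row per generation,
#'   plus the initial state).
#' @export
finite_population_oracle <- function(params, pop_size = 10000,
                                     generations = 1000, step_scale = 0.01,
                                     seed = 1, initial = c(0.5, 0.5, 0.5)) {
  if (pop_size < 100) abort("pop_size must be >= 100", class = "trigame_validation_error")
  if (generations < 1) abort("generations must be >= 1", class = "trigame_validation_error")
  params <- as_game_params(params)
  s0 <- check_states(initial)

  withr::with_seed(seed, {
    k <- round(c(s0$x, s0$y, s0$z) * pop_size)  # counts playing focal action
    freq <- matrix(NA_real_, nrow = generations + 1L, ncol = 3)
    freq[1, ] <- k / pop_size
    for (g in seq_len(generations)) {
      p <- k / pop_size
      a <- adv_vec(p, params)
      up <- rbinom(3, pop_size - k, pmin(1, step_scale * p * pmax(a, 0)))
      down <- rbinom(3, k, pmin(1, step_scale * (1 - p) * pmax(-a, 0)))
      k <- k + up - down
      freq[g + 1L, ] <- k / pop_size
    }
    tibble::tibble(t = (0:generations) * step_scale,
                   x = freq[, 1], y = freq[, 2], z = freq[, 3])
  })
}
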