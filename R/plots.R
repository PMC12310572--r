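strategy_labels <- c(
  x = "patients: recognize outcomes",
  y = "institutions: reasonable treatment",
  z = "regulators: strict supervision"
)

traj_long <- function(path) {
  tidyr::pivot_longer(path, c("x", "y", "z"),
                      names_to = "component", values_to = "frequency") |>
    dplyr::mutate(component = factor(strategy_labels[.data$component],
                                     levels = unname(strategy_labels)))
}

#' Plot a trajectory's strategy frequencies over time
#'
#' @param object A `game_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.game_trajectory <- function(object, ...) {
  ggplot2::ggplot(traj_long(object$path),
                  ggplot2::aes(.data$t, .data$frequency,
                               colour = .data$component)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time", y = "strategy frequency", colour = NULL,
                  title = if (object$converged)
                    paste0("Replicator trajectory (converged to ",
                           object$limit_vertex, ")")
                  else "Replicator trajectory (unconverged)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot all trajectories of a multi-start batch
#'
#' @param object A `game_multistart`.
#' @param ... Unused.
#' @return A ggplot object (one facet per strategy component, one line per
#'   start, coloured by limit vertex).
#' @export
autoplot.game_multistart <- function(object, ...) {
  dat <- purrr::map_dfr(seq_along(object$trajectories), function(i) {
    r <- object$trajectories[[i]]
    if (inherits(r, "error")) return(NULL)
    dplyr::mutate(traj_long(r$path), start = i,
                  limit = if (r$converged) r$limit_vertex else "none")
  })
  ggplot2::ggplot(dat, ggplot2::aes(.data$t, .data$frequency,
                                    group = .data$start,
                                    colour = .data$limit)) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.4) +
    ggplot2::facet_wrap(~component, ncol = 1) +
    ggplot2::labs(x = "time", y = "strategy frequency",
                  colour = "limit vertex") +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity sweep
#'
#' @param object A `game_sweep`.
#' @param ... Unused.
#' @return A ggplot object: strategy-frequency time series, line type by
#'   component, colour by swept value.
#' @export
autoplot.game_sweep <- function(object, ...) {
  dat <- purrr::map2_dfr(object$table$value, object$trajectories,
                         function(v, r) dplyr::mutate(traj_long(r$path),
                                                      value = v))
  ggplot2::ggplot(dat, ggplot2::aes(.data$t, .data$frequency,
                                    colour = factor(.data$value))) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::facet_wrap(~component, ncol = 1) +
    ggplot2::labs(x = "time", y = "strategy frequency",
                  colour = object$table$swept[1]) +
    ggplot2::theme_minimal()
}
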