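#' Names of the 14 game constants
#'
#' The payoff and cost constants of the tripartite overtreatment game, all on
#' one arbitrary money-like scale:
#' \describe{
#'   \item{Cm}{cost of overmedicalization borne by patients}
#'   \item{Ct}{patient benefit of appropriate treatment}
#'   \item{Cp}{patient complaint cost/probability weight}
#'   \item{Ci}{patient compensation income}
#'   \item{Wm}{institution income from overtreatment}
#'   \item{Wt}{institution income from appropriate treatment}
#'   \item{Gf}{government fine on overtreating institutions}
#'   \item{Gs}{government financial subsidy to institutions}
#'   \item{Er}{institution reputation benefit of reasonable treatment}
#'   \item{Oc}{institution operating cost}
#'   \item{Eg}{government social benefit}
#'   \item{Cr}{government regulatory (supervision) cost}
#'   \item{Gg}{government remediation (rectification) cost}
#'   \item{Pg}{government credibility stake}
#' }
#'
#' @return Character vector of length 14.
#' @export
param_names <- function() {
  c("Cm", "Ct", "Cp", "Ci", "Wm", "Wt", "Gf", "Gs",
    "Er", "Oc", "Eg", "Cr", "Gg", "Pg")
}

param_descriptions <- function() {
  c(Cm = "cost of overmedicalization to patients",
    Ct = "patient benefit of appropriate treatment",
    Cp = "patient complaint cost weight",
    Ci = "patient compensation income",
    Wm = "institution income from overtreatment",
    Wt = "institution income from appropriate treatment",
    Gf = "government fine on institutions",
    Gs = "government financial subsidy",
    Er = "institution reputation benefit",
    Oc = "institution operating cost",
    Eg = "government social benefit",
    Cr = "government regulatory cost",
    Gg = "government remediation cost",
    Pg = "government credibility stake")
}

#' Construct and validate a set of game parameters
#'
#' Builds a `game_params` object from the 14 named constants of the
#' overtreatment game (see [param_names()]). All values must be supplied,
#' nonnegative and finite; extra or missing names are errors.
#'
#' @param ... Either a single named list/vector holding all 14 constants, or
#'   the constants as named arguments (`Cm = 6, Ct = 2, ...`).
#' @return A named numeric vector of class `game_params`.
#' @examples
#' game_params(Cm = 6, Ct = 2, Cp = 10, Ci = 0.5, Wm = 9, Wt = 4, Gf = 6,
#'             Gs = 5, Er = 2, Oc = 1.5, Eg = 7, Cr = 1, Gg = 2, Pg = 1)
#' @export
game_params <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) ||
      (length(dots) == 1L && (is.list(dots[[1]]) || length(dots[[1]]) > 1L))) {
    raw <- dots[[1]]
  } else {
    raw <- dots
  }
  raw <- unlist(raw)
  validate_parameters(raw)
}

#' Validate a raw named map of game constants
#'
#' @param raw Named numeric vector or list with exactly the 14 names of
#'   [param_names()].
#' @return A `game_params` object (named numeric vector, canonical order).
#' @export
validate_parameters <- function(raw) {
  raw <- unlist(raw)
  nm <- param_names()
  missing <- setdiff(nm, names(raw))
  if (length(missing) > 0) {
    abort(paste0("missing game parameter(s): ", paste(missing, collapse = ", ")),
          class = "trigame_config_error")
  }
  extra <- setdiff(names(raw), nm)
  if (length(extra) > 0) {
    abort(paste0("unknown game parameter(s): ", paste(extra, collapse = ", ")),
          class = "trigame_config_error")
  }
  vals <- as.numeric(raw[nm])
  bad <- !is.finite(vals) | vals < 0
  if (any(bad)) {
    abort(paste0("game parameters must be finite and nonnegative; offending: ",
                 paste(nm[bad], collapse = ", ")),
          class = "trigame_validation_error")
  }
  structure(setNames(vals, nm), class = "game_params")
}

#' Replace one constant in a parameter set
#'
#' @param params A `game_params` object.
#' @param name One of [param_names()].
#' @param value Nonnegative finite replacement value.
#' @return A new `game_params` object.
#' @export
set_param <- function(params, name, value) {
  params <- as_game_params(params)
  if (!name %in% param_names()) {
    abort(paste0("unknown game parameter: ", name),
          class = "trigame_config_error")
  }
  out <- unclass(params)
  out[name] <- value
  validate_parameters(out)
}

#' Coerce to game parameters
#' @param x Named list/vector of the 14 constants, or a `game_params` object.
#' @return A `game_params` object.
#' @export
as_game_params <- function(x) {
  if (inherits(x, "game_params")) return(x)
  validate_parameters(x)
}

#' @export
print.game_params <- function(x, ...) {
  cat("<game_params> 14 payoff/cost constants (common money-like scale)\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' @rdname game_params
#' @param x A `game_params` object.
#' @export
tidy.game_params <- function(x, ...) {
  tibble::tibble(
    symbol = names(x),
    value = as.numeric(x),
    description = unname(param_descriptions()[names(x)])
  )
}

# Validate an (x, y, z) state table: data frame with columns x, y, z in [0,1].
check_states <- function(states, allow_outside = FALSE) {
  if (is.numeric(states) && length(states) == 3L) {
    states <- tibble::tibble(x = states[[1]], y = states[[2]], z = states[[3]])
  }
  if (!is.data.frame(states) || !all(c("x", "y", "z") %in% names(states))) {
    abort("states must be a data frame with columns x, y, z (or a numeric length-3 vector)",
          class = "trigame_validation_error")
  }
  s <- tibble::as_tibble(states)[c("x", "y", "z")]
  if (!all(vapply(s, is.numeric, logical(1)))) {
    abort("state columns x, y, z must be numeric", class = "trigame_validation_error")
  }
  if (!allow_outside) {
    v <- unlist(s)
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
      abort("strategy frequencies must lie in [0, 1]", class = "trigame_validation_error")
    }
  }
  s
}
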