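#' Expected payoffs of the six pure actions
#'
#' For each population the expected payoff of its two actions, mixture-weighted
#' over the other two populations' current strategy frequencies. Patients
#' choose recognize/reject treatment outcomes, institutions reasonable
#' treatment/overtreatment, regulators strict/lenient supervision. Each payoff
#' is bilinear in the two opposing frequencies.
#'
#' @param states Data frame with columns `x`, `y`, `z` (strategy frequencies in
#'   \[0,1\]: patients recognizing, institutions treating reasonably,
#'   regulators supervising strictly), or a numeric length-3 vector. Vectorized
#'   over rows.
#' @param params A [game_params()] object (or coercible named vector).
#' @return A tibble with the state columns and `E_recognize`, `E_reject`,
#'   `E_reasonable`, `E_overtreat`, `E_strict`, `E_lenient`.
#' @examples
#' p <- baseline_scenarios()$scenario1
#' expected_payoffs(c(1, 1, 1), p)
#' @export
expected_payoffs <- function(states, params) {
  s <- check_states(states)
  p <- as.list(as_game_params(params))
  with(c(s, p), {
    tibble::tibble(
      x = x, y = y, z = z,
      E_recognize =
        y * z * Ct + y * (1 - z) * (Ct - Cp - Ci) +
        (1 - y) * z * (Cp + Ci - Cm) + (1 - y) * (1 - z) * Cm,
      E_reject =
        y * z * (Ct + Cp + Ci) + y * (1 - z) * (Ct - Cp) +
        (1 - y) * z * (Cp + Ci - Cm) + (1 - y) * (1 - z) * (-Cm - Cp - Ci),
      E_reasonable =
        x * z * (Wt + Gs + Er - Oc) + x * (1 - z) * (Wt + Gs + Er) +
        (1 - x) * z * (Wt + Gs + Er - Oc) +
        (1 - x) * (1 - z) * (Wt + Gs + Er - Oc),
      E_overtreat =
        x * z * (Wm - Gf - Oc) + x * (1 - z) * (Wm + Gs - Oc) +
        (1 - x) * z * (Wm - Gf - Oc) + (1 - x) * (1 - z) * (Wm - Oc),
      E_strict =
        x * y * (Eg - Cr - Gg) + x * (1 - y) * (-Cr - Gg - Pg) +
        (1 - x) * y * (Eg - Cr - Gg + Pg) + (1 - x) * (1 - y) * (Pg - Cr - Gg),
      E_lenient =
        x * y * Eg + x * (1 - y) * Pg + (1 - x) * y * (Eg + Pg) +
        (1 - x) * (1 - y) * (-Eg - Pg)
    )
  })
}

#' Payoff-advantage functions driving the replicator flow
#'
#' The payoff differential of each population's focal action over its
#' alternative, written in canonical expanded polynomial form. `Ax` is bilinear
#' in (y, z), `Ay` in (x, z), `Az` in (x, y); each equals the corresponding
#' difference of [expected_payoffs()] exactly.
#'
#' @inheritParams expected_payoffs
#' @return A tibble with the state columns and `Ax`, `Ay`, `Az`.
#' @examples
#' p <- baseline_scenarios()$scenario1
#' advantage_functions(c(0.5, 0.5, 0.5), p)  # (2.875, 4.125, -1.25)
#' @export
advantage_functions <- function(states, params) {
  s <- check_states(states)
  p <- as.list(as_game_params(params))
  with(c(s, p), {
    tibble::tibble(
      x = x, y = y, z = z,
      Ax = (Ci + 2 * Cm + Cp) - (2 * Ci + 2 * Cm + Cp) * y -
        (Ci + 2 * Cm + Cp) * z + (Ci + 2 * Cm) * y * z,
      Ay = (Er + Gs - Wm + Wt) - (Gs - Oc) * x + Gf * z + (Gs - Oc) * x * z,
      Az = (Eg - Cr - Gg + 2 * Pg) - (Eg + 4 * Pg) * x -
        (Eg + 2 * Pg) * y + (Eg + 4 * Pg) * x * y
    )
  })
}

#' Replicator vector field
#'
#' Right-hand side of the three-population replicator system: each frequency
#' grows in proportion to the payoff advantage of its action,
#' `Fx = x(1-x)Ax`, `Fy = y(1-y)Ay`, `Fz = z(1-z)Az`. The field vanishes on
#' every face of the unit cube, so each vertex is a fixed point.
#'
#' @inheritParams expected_payoffs
#' @return A tibble with the state columns and `Fx`, `Fy`, `Fz` (units 1/time).
#' @examples
#' p <- baseline_scenarios()$scenario1
#' replicator_rhs(c(0.5, 0.5, 0.5), p)  # 0.25 * (2.875, 4.125, -1.25)
#' @export
replicator_rhs <- function(states, params) {
  a <- advantage_functions(states, params)
  dplyr::transmute(a,
    x = .data$x, y = .data$y, z = .data$z,
    Fx = .data$x * (1 - .data$x) * .data$Ax,
    Fy = .data$y * (1 - .data$y) * .data$Ay,
    Fz = .data$z * (1 - .data$z) * .data$Az
  )
}

# bare-vector versions used in the integrator / root finders (no validation,
# tolerate small excursions outside the box)
adv_vec <- function(s, p) {
  x <- s[[1]]; y <- s[[2]]; z <- s[[3]]
  c((p[["Ci"]] + 2 * p[["Cm"]] + p[["Cp"]]) -
      (2 * p[["Ci"]] + 2 * p[["Cm"]] + p[["Cp"]]) * y -
      (p[["Ci"]] + 2 * p[["Cm"]] + p[["Cp"]]) * z +
      (p[["Ci"]] + 2 * p[["Cm"]]) * y * z,
    (p[["Er"]] + p[["Gs"]] - p[["Wm"]] + p[["Wt"]]) -
      (p[["Gs"]] - p[["Oc"]]) * x + p[["Gf"]] * z +
      (p[["Gs"]] - p[["Oc"]]) * x * z,
    (p[["Eg"]] - p[["Cr"]] - p[["Gg"]] + 2 * p[["Pg"]]) -
      (p[["Eg"]] + 4 * p[["Pg"]]) * x - (p[["Eg"]] + 2 * p[["Pg"]]) * y +
      (p[["Eg"]] + 4 * p[["Pg"]]) * x * y)
}

rhs_vec <- function(s, p) s * (1 - s) * adv_vec(s, p)

# Jacobian of the advantage map A(x,y,z) (constant + bilinear terms only)
adv_jac_vec <- function(s, p) {
  x <- s[[1]]; y <- s[[2]]; z <- s[[3]]
  Ci <- p[["Ci"]]; Cm <- p[["Cm"]]; Cp <- p[["Cp"]]
  GsOc <- p[["Gs"]] - p[["Oc"]]
  Eg <- p[["Eg"]]; Pg <- p[["Pg"]]
  matrix(c(
    0, -(2 * Ci + 2 * Cm + Cp) + (Ci + 2 * Cm) * z,
       -(Ci + 2 * Cm + Cp) + (Ci + 2 * Cm) * y,
    -GsOc + GsOc * z, 0, p[["Gf"]] + GsOc * x,
    -(Eg + 4 * Pg) + (Eg + 4 * Pg) * y,
    -(Eg + 2 * Pg) + (Eg + 4 * Pg) * x, 0
  ), nrow = 3, byrow = TRUE)
}
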