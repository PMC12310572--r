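#' The eight pure-strategy profiles
#'
#' Vertices of the unit cube in the conventional labelling: E1=(0,0,0),
#' E2=(1,0,0), E3=(0,1,0), E4=(0,0,1), E5=(1,1,0), E6=(1,0,1), E7=(0,1,1),
#' E8=(1,1,1).
#'
#' @return A tibble with columns `label`, `x`, `y`, `z`.
#' @export
pure_profiles <- function() {
  tibble::tibble(
    label = paste0("E", 1:8),
    x = c(0, 1, 0, 0, 1, 1, 0, 1),
    y = c(0, 0, 1, 0, 1, 0, 1, 1),
    z = c(0, 0, 0, 1, 0, 1, 1, 1)
  )
}

profile_coords <- function(label) {
  pp <- pure_profiles()
  i <- match(label, pp$label)
  if (any(is.na(i))) {
    abort(paste0("unknown pure profile label: ",
                 paste(label[is.na(i)], collapse = ", ")),
          class = "trigame_config_error")
  }
  pp[i, , drop = FALSE]
}

vertex_label <- function(x, y, z) {
  pp <- pure_profiles()
  pp$label[match(paste(x, y, z), paste(pp$x, pp$y, pp$z))]
}

#' Jacobian of the replicator system
#'
#' Analytic 3x3 Jacobian of the replicator field at a state. All off-diagonal
#' entries contain a factor \eqn{s_i(1-s_i)}, so the matrix is diagonal at
#' every vertex of the cube, with the vertex eigenvalues on the diagonal.
#'
#' @param state Numeric length-3 vector (x, y, z) or one-row data frame.
#' @param params A [game_params()] object.
#' @return A 3x3 numeric matrix (row/column order: patient, institution,
#'   regulator directions).
#' @export
game_jacobian <- function(state, params) {
  s <- check_states(state)
  if (nrow(s) != 1L) abort("state must be a single point", class = "trigame_validation_error")
  p <- as_game_params(params)
  sv <- c(s$x, s$y, s$z)
  a <- adv_vec(sv, p)
  aj <- adv_jac_vec(sv, p)
  d <- sv * (1 - sv)              # logistic factors
  j <- aj * d                      # off-diagonal: s_i(1-s_i) * dA_i/ds_j
  diag(j) <- (1 - 2 * sv) * a      # diagonal: (1-2s_i) A_i (dA_i/ds_i = 0)
  dimnames(j) <- list(c("x", "y", "z"), c("x", "y", "z"))
  j
}

#' Closed-form eigenvalues at a pure profile
#'
#' The three Jacobian eigenvalues of a vertex equilibrium in closed form
#' (patient, institution, regulator direction — the diagonal of the Jacobian
#' at that vertex):
#' \tabular{ll}{
#' E1(0,0,0) \tab (Ci+2Cm+Cp, Er+Gs-Wm+Wt, Eg-Cr-Gg+2Pg) \cr
#' E2(1,0,0) \tab (-(Ci+2Cm+Cp), Er+Oc-Wm+Wt, -(Cr+Gg+2Pg)) \cr
#' E3(0,1,0) \tab (-Ci, Wm-Gs-Er-Wt, -(Cr+Gg)) \cr
#' E4(0,0,1) \tab (0, Er+Gf+Gs-Wm+Wt, Cr-Eg+Gg-2Pg) \cr
#' E5(1,1,0) \tab (Ci, Wm-Oc-Er-Wt, -(Cr+Gg)) \cr
#' E6(1,0,1) \tab (0, Er+Gf+Gs-Wm+Wt, Cr+Gg+2Pg) \cr
#' E7(0,1,1) \tab (-(Ci+Cp), Wm-Gf-Gs-Er-Wt, Cr+Gg) \cr
#' E8(1,1,1) \tab (Ci+Cp, Wm-Gf-Gs-Er-Wt, Cr+Gg)
#' }
#'
#' @param profile Profile label ("E1".."E8") or numeric vertex (x, y, z).
#' @param params A [game_params()] object.
#' @return Named numeric vector `c(lambda1, lambda2, lambda3)`.
#' @export
vertex_eigenvalues <- function(profile, params) {
  p <- as.list(as_game_params(params))
  if (is.numeric(profile)) {
    profile <- vertex_label(profile[[1]], profile[[2]], profile[[3]])
    if (is.na(profile)) {
      abort("numeric profile must be a vertex of the unit cube",
            class = "trigame_config_error")
    }
  }
  lam <- with(p, switch(profile,
    E1 = c(Ci + 2 * Cm + Cp, Er + Gs - Wm + Wt, Eg - Cr - Gg + 2 * Pg),
    E2 = c(-(Ci + 2 * Cm + Cp), Er + Oc - Wm + Wt, -(Cr + Gg + 2 * Pg)),
    E3 = c(-Ci, Wm - Gs - Er - Wt, -(Cr + Gg)),
    E4 = c(0, Er + Gf + Gs - Wm + Wt, Cr - Eg + Gg - 2 * Pg),
    E5 = c(Ci, Wm - Oc - Er - Wt, -(Cr + Gg)),
    E6 = c(0, Er + Gf + Gs - Wm + Wt, Cr + Gg + 2 * Pg),
    E7 = c(-(Ci + Cp), Wm - Gf - Gs - Er - Wt, Cr + Gg),
    E8 = c(Ci + Cp, Wm - Gf - Gs - Er - Wt, Cr + Gg)
  ))
  if (is.null(lam)) {
    abort(paste0("unknown pure profile label: ", profile),
          class = "trigame_config_error")
  }
  setNames(lam, c("lambda1", "lambda2", "lambda3"))
}

#' Classify a pure profile by the indirect (Lyapunov) method
#'
#' A vertex is an evolutionarily stable strategy (asymptotically stable) when
#' all three eigenvalues are negative; indeterminate ("uncertainty point")
#' when any eigenvalue is within `tol` of zero, since the linearization is
#' then inconclusive along that direction and no center-manifold analysis is
#' attempted; otherwise unstable.
#'
#' @inheritParams vertex_eigenvalues
#' @param tol Numerical tolerance for treating an eigenvalue as zero
#'   (default 1e-9, must be > 0).
#' @return A one-row tibble: `label`, `x`, `y`, `z`, `lambda1..3`,
#'   `classification` (one of `"stable (ESS)"`, `"unstable"`,
#'   `"indeterminate"`).
#' @export
classify_equilibrium <- function(profile, params, tol = 1e-9) {
  if (!is.numeric(tol) || tol <= 0) {
    abort("tol must be > 0", class = "trigame_validation_error")
  }
  if (is.numeric(profile)) {
    profile <- vertex_label(profile[[1]], profile[[2]], profile[[3]])
  }
  lam <- vertex_eigenvalues(profile, params)
  cls <- if (any(abs(lam) <= tol)) {
    "indeterminate"
  } else if (all(lam < -tol)) {
    "stable (ESS)"
  } else {
    "unstable"
  }
  co <- profile_coords(profile)
  tibble::tibble(
    label = profile, x = co$x, y = co$y, z = co$z,
    lambda1 = lam[[1]], lambda2 = lam[[2]], lambda3 = lam[[3]],
    classification = cls
  )
}

#' Full stability report for the eight pure profiles
#'
#' Classifies E1..E8 by the signs of their closed-form eigenvalues and
#' evaluates the two headline stability inequalities: the all-defect vertex
#' E2(1,0,0) is stable iff `Wm > Er + Oc + Wt` (overtreatment income beats
#' reasonable income plus reputation plus operating cost), and the cooperative
#' vertex E3(0,1,0) is stable iff `Wm < Gs + Wt + Er` (overtreatment income is
#' beaten by subsidised reasonable treatment). Both can hold at once
#' (bistability) when `Oc < Gs`.
#'
#' @param params A [game_params()] object.
#' @param tol Zero tolerance for eigenvalue signs (default 1e-9).
#' @return An object of class `game_ess`: use [tidy()] for the 8-row
#'   classification table, [glance()] for a one-row summary, `$conditions`
#'   for the headline inequalities.
#' @examples
#' ess_conditions(baseline_scenarios()$scenario1)
#' @export
ess_conditions <- function(params, tol = 1e-9) {
  params <- as_game_params(params)
  tab <- purrr::map_dfr(pure_profiles()$label, classify_equilibrium,
                        params = params, tol = tol)
  p <- as.list(params)
  cond <- tibble::tibble(
    label = c("E2", "E3"),
    condition = c("Wm > Er + Oc + Wt", "Wm < Gs + Wt + Er"),
    lhs = p$Wm,
    rhs = c(p$Er + p$Oc + p$Wt, p$Gs + p$Wt + p$Er),
    satisfied = c(p$Wm > p$Er + p$Oc + p$Wt, p$Wm < p$Gs + p$Wt + p$Er)
  )
  # coherence: the headline inequality must agree with the eigenvalue signs
  # (ties within tol are left to the eigenvalue classification)
  for (i in 1:2) {
    gap <- cond$lhs[i] - cond$rhs[i]
    lam_i <- unlist(tab[tab$label == cond$label[i], c("lambda1", "lambda2", "lambda3")])
    if (abs(gap) > tol && all(abs(lam_i) > tol)) {
      eig_stable <- tab$classification[tab$label == cond$label[i]] == "stable (ESS)"
      if (eig_stable != cond$satisfied[i]) {
        abort("internal inconsistency between stability inequality and eigenvalues",
              class = "trigame_internal_error")
      }
    }
  }
  structure(
    list(table = tab, conditions = cond, params = params, tol = tol),
    class = "game_ess"
  )
}

#' @export
print.game_ess <- function(x, ...) {
  cat("<game_ess> stability of the 8 pure-strategy profiles\n")
  print(x$table)
  stable <- x$table$label[x$table$classification == "stable (ESS)"]
  cat("stable set: ", if (length(stable)) paste(stable, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' @rdname ess_conditions
#' @param x A `game_ess` object.
#' @param ... Unused.
#' @export
tidy.game_ess <- function(x, ...) x$table

#' @rdname ess_conditions
#' @export
glance.game_ess <- function(x, ...) {
  stable <- x$table$label[x$table$classification == "stable (ESS)"]
  tibble::tibble(
    n_stable = length(stable),
    stable_set = paste(stable, collapse = ","),
    bistable = all(c("E2", "E3") %in% stable),
    n_indeterminate = sum(x$table$classification == "indeterminate")
  )
}
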