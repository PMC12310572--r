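#' Pure-strategy equilibria of the replicator system
#'
#' Enumerates the candidate vertices of the unit cube and returns those where
#' the replicator field vanishes. The field carries a factor
#' \eqn{s_i(1-s_i)} in every component, so all eight vertices are equilibria
#' for any parameter set; this function verifies that numerically rather than
#' assuming it.
#'
#' @param params A [game_params()] object.
#' @param tol Residual tolerance on `max |F_i|` (default 1e-12).
#' @return A tibble with columns `label`, `x`, `y`, `z`, `residual`.
#' @export
pure_equilibria <- function(params, tol = 1e-12) {
  params <- as_game_params(params)
  pp <- pure_profiles()
  f <- replicator_rhs(pp[c("x", "y", "z")], params)
  res <- pmax(abs(f$Fx), abs(f$Fy), abs(f$Fz))
  dplyr::mutate(pp, residual = res) |>
    dplyr::filter(.data$residual <= tol)
}

#' Search the open cube for interior fixed points
#'
#' A fixed point strictly inside the cube requires all three advantage
#' functions to vanish simultaneously. The search scans a regular interior
#' grid for cells in which each advantage component changes sign among the
#' cell corners, Newton-polishes a root from each such cell (analytic Jacobian
#' of the advantage map), merges duplicates, and re-verifies every root with
#' an independent multi-start solver ([pracma::fsolve()]).
#'
#' @param params A [game_params()] object.
#' @param grid_n Grid points per axis (default 21, minimum 5).
#' @param tol Residual tolerance on `max |F_i|` for an accepted root
#'   (default 1e-10).
#' @return A tibble with columns `x`, `y`, `z`, `residual`, `interior`,
#'   `verified` (zero rows when the open cube holds no root, a valid and
#'   common outcome).
#' @export
find_interior_fixed_points <- function(params, grid_n = 21, tol = 1e-10) {
  if (grid_n < 5) abort("grid_n must be >= 5", class = "trigame_validation_error")
  if (!is.numeric(tol) || tol <= 0) abort("tol must be > 0", class = "trigame_validation_error")
  params <- as_game_params(params)

  g <- seq(0, 1, length.out = grid_n)
  grid <- expand.grid(x = g, y = g, z = g)
  av <- advantage_functions(grid, params)
  dim3 <- c(grid_n, grid_n, grid_n)
  arr <- lapply(av[c("Ax", "Ay", "Az")], array, dim = dim3)

  # cells whose 8 corners straddle zero in every component
  idx <- expand.grid(i = 1:(grid_n - 1), j = 1:(grid_n - 1), k = 1:(grid_n - 1))
  straddles <- function(a, i, j, k) {
    corners <- a[i + c(0, 1), j + c(0, 1), k + c(0, 1)]
    min(corners) <= 0 && max(corners) >= 0
  }
  keep <- vapply(seq_len(nrow(idx)), function(r) {
    i <- idx$i[r]; j <- idx$j[r]; k <- idx$k[r]
    straddles(arr$Ax, i, j, k) && straddles(arr$Ay, i, j, k) &&
      straddles(arr$Az, i, j, k)
  }, logical(1))
  idx <- idx[keep, , drop = FALSE]

  roots <- list()
  h <- 1 / (grid_n - 1)
  for (r in seq_len(nrow(idx))) {
    start <- c(g[idx$i[r]] + h / 2, g[idx$j[r]] + h / 2, g[idx$k[r]] + h / 2)
    root <- newton_advantage(start, params)
    if (!is.null(root)) roots[[length(roots) + 1L]] <- root
  }
  roots <- dedupe_points(roots, radius = 1e-6)
  # keep strictly interior roots with small replicator residual
  out <- purrr::map_dfr(roots, function(s) {
    fres <- max(abs(rhs_vec(s, params)))
    tibble::tibble(x = s[1], y = s[2], z = s[3], residual = fres,
                   interior = all(s > 0 & s < 1))
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                          residual = numeric(), interior = logical(),
                          verified = logical()))
  }
  out <- dplyr::filter(out, .data$interior, .data$residual <= tol)
  out$verified <- vapply(seq_len(nrow(out)), function(i) {
    verify_root_fsolve(c(out$x[i], out$y[i], out$z[i]), params, tol)
  }, logical(1))
  out
}

# damped Newton on the advantage map; NULL if it leaves the box or stalls
newton_advantage <- function(start, params, max_iter = 50, tol = 1e-13) {
  s <- start
  for (iter in seq_len(max_iter)) {
    a <- adv_vec(s, params)
    if (max(abs(a)) < tol) return(s)
    j <- adv_jac_vec(s, params)
    step <- tryCatch(solve(j, a), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    # damp so the iterate stays in the closed cube
    lam <- 1
    repeat {
      cand <- s - lam * step
      if (all(cand >= -1e-3 & cand <= 1 + 1e-3) || lam < 1e-6) break
      lam <- lam / 2
    }
    if (max(abs(lam * step)) < 1e-15) return(NULL)
    s <- pmin(pmax(cand, 0), 1)
  }
  a <- adv_vec(s, params)
  if (max(abs(a)) < tol) s else NULL
}

dedupe_points <- function(pts, radius) {
  out <- list()
  for (p in pts) {
    dup <- any(vapply(out, function(q) max(abs(q - p)) < radius, logical(1)))
    if (!dup) out[[length(out) + 1L]] <- p
  }
  out
}

# independent confirmation with pracma's solver from jittered starts
verify_root_fsolve <- function(root, params, tol) {
  f <- function(s) adv_vec(s, params)
  for (jit in list(c(0, 0, 0), c(0.02, -0.02, 0.01), c(-0.015, 0.01, -0.02))) {
    start <- pmin(pmax(root + jit, 1e-3), 1 - 1e-3)
    sol <- tryCatch(
      suppressWarnings(pracma::fsolve(f, start, tol = 1e-12)),
      error = function(e) NULL
    )
    if (!is.null(sol) && max(abs(sol$x - root)) < 1e-5 &&
        max(abs(rhs_vec(sol$x, params))) <= tol) {
      return(TRUE)
    }
  }
  FALSE
}
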