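# random parameter sets / states used by the property tests

random_params <- function(n = 1, lo = 0.5, hi = 20) {
  sets <- lapply(seq_len(n), function(i) {
    game_params(setNames(runif(14, lo, hi), param_names()))
  })
  if (n == 1) sets[[1]] else sets
}

random_state <- function(interior = FALSE) {
  if (interior) runif(3, 0.05, 0.95) else runif(3)
}

# explicit-Euler reference integrator (independent of deSolve)
euler_path <- function(params, initial, horizon, step = 0.01) {
  s <- as.numeric(initial)
  n <- ceiling(horizon / step)
  out <- matrix(NA_real_, nrow = n + 1, ncol = 3)
  out[1, ] <- s
  for (i in seq_len(n)) {
    a <- advantage_functions(s, params)
    s <- s + step * s * (1 - s) * c(a$Ax, a$Ay, a$Az)
    s <- pmin(pmax(s, 0), 1)
    out[i + 1, ] <- s
  }
  tibble::tibble(t = (0:n) * step, x = out[, 1], y = out[, 2], z = out[, 3])
}

expect_max_norm <- function(a, b, tol) {
  expect_lt(max(abs(as.numeric(a) - as.numeric(b))), tol)
}
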