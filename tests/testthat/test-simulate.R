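sc <- baseline_scenarios()

test_that("the two reference scenarios reach their printed limit vertices", {
  tr1 <- simulate_game(sc$scenario1, sc$initial)
  expect_true(tr1$converged)
  expect_equal(tr1$limit_vertex, "E2")
  f1 <- glance(tr1)
  expect_max_norm(c(f1$x_final, f1$y_final, f1$z_final), c(1, 0, 0), 1e-3)

  tr2 <- simulate_game(sc$scenario2, sc$initial)
  expect_equal(tr2$limit_vertex, "E3")
  f2 <- glance(tr2)
  expect_max_norm(c(f2$x_final, f2$y_final, f2$z_final), c(0, 1, 0), 1e-3)
})

test_that("a vertex initial condition stays put", {
  withr::with_seed(4, {
    for (i in 1:5) {
      p <- random_params()
      v <- pure_profiles()[sample(8, 1), ]
      tr <- simulate_game(p, c(v$x, v$y, v$z), horizon = 10)
      expect_max_norm(tr$path$x, v$x, 1e-12)
      expect_max_norm(tr$path$y, v$y, 1e-12)
      expect_max_norm(tr$path$z, v$z, 1e-12)
    }
  })
})

test_that("states stay inside the unit cube for random draws", {
  withr::with_seed(55, {
    for (i in 1:100) {
      p <- random_params()
      tr <- simulate_game(p, random_state(), horizon = 20)
      expect_gte(min(tr$path[c("x", "y", "z")]), 0)
      expect_lte(max(unlist(tr$path[c("x", "y", "z")])), 1)
    }
  })
})

test_that("halving the solver tolerances barely moves the final state", {
  for (p in list(sc$scenario1, sc$scenario2)) {
    a <- glance(simulate_game(p, sc$initial))
    b <- glance(simulate_game(p, sc$initial, rel_tol = 5e-9, abs_tol = 5e-11))
    expect_max_norm(c(a$x_final, a$y_final, a$z_final),
                    c(b$x_final, b$y_final, b$z_final), 1e-5)
  }
})

test_that("an explicit-Euler reference tracks the adaptive solution", {
  for (p in list(sc$scenario1, sc$scenario2)) {
    tr <- simulate_game(p, sc$initial)
    eu <- euler_path(p, sc$initial, horizon = 50, step = 0.01)
    fa <- tail(tr$path, 1)
    fe <- tail(eu, 1)
    expect_max_norm(c(fa$x, fa$y, fa$z), c(fe$x, fe$y, fe$z), 0.05)
  }
})

test_that("convergence detection respects the radius and rejects ambiguity", {
  near <- tibble::tibble(x = 0.9995, y = 3e-4, z = 1e-4)
  hit <- detect_convergence(near, radius = 1e-3)
  expect_equal(hit$label, "E2")
  expect_null(detect_convergence(tibble::tibble(x = 0.6, y = 0.9, z = 0.05),
                                 radius = 1e-3))
  expect_error(detect_convergence(near, radius = 0.6),
               class = "trigame_validation_error")
})

test_that("unconverged windows are reported, and extensions can recover them", {
  short <- simulate_game(sc$scenario1, sc$initial, horizon = 2)
  expect_false(short$converged)
  expect_true(is.na(short$limit_vertex))
  extended <- simulate_game(sc$scenario1, sc$initial, horizon = 2,
                            max_extension = 6)
  expect_true(extended$converged)
  expect_equal(extended$limit_vertex, "E2")
})

test_that("multi-start lattices are interior and tally basin membership", {
  ms1 <- multi_start(sc$scenario2, lattice_points_per_axis = 1,
                     settings = sim_settings())
  expect_equal(nrow(ms1$starts), 1)
  expect_equal(c(ms1$starts$x0, ms1$starts$y0, ms1$starts$z0), c(0.5, 0.5, 0.5))

  ms <- multi_start(sc$scenario2, lattice_points_per_axis = 3)
  expect_equal(nrow(ms$starts), 27)
  expect_true(all(ms$starts[c("x0", "y0", "z0")] > 0 &
                    ms$starts[c("x0", "y0", "z0")] < 1))
  expect_true(all(ms$starts$limit_vertex == "E3"))
  expect_equal(glance(ms)$n_converged, 27)

  msb <- multi_start(sc$scenario1, lattice_points_per_axis = 3)
  expect_true(all(msb$starts$limit_vertex %in% c("E2", "E3")))
})

test_that("every converged limit vertex is ESS-classified for its parameters", {
  withr::with_seed(77, {
    for (i in 1:20) {
      p <- random_params()
      tr <- simulate_game(p, random_state(interior = TRUE))
      if (tr$converged) {
        cls <- classify_equilibrium(tr$limit_vertex, p)$classification
        expect_equal(cls, "stable (ESS)")
      }
    }
  })
})

test_that("settings validation rejects degenerate windows and radii", {
  expect_error(sim_settings(horizon = 0), class = "trigame_validation_error")
  expect_error(sim_settings(rel_tol = 0), class = "trigame_validation_error")
  expect_error(sim_settings(convergence_radius = 0.5),
               class = "trigame_validation_error")
})
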