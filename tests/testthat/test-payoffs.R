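sc <- baseline_scenarios()

test_that("expected payoffs at the all-cooperate corner match hand substitution", {
  ep <- expected_payoffs(c(1, 1, 1), sc$scenario1)
  expect_equal(ep$E_recognize, 2)        # Ct
  expect_equal(ep$E_reasonable, 9.5)     # Wt + Gs + Er - Oc
  expect_equal(ep$E_strict, 4)           # Eg - Cr - Gg
  # E_strict depends on (x, y) only
  ep2 <- expected_payoffs(data.frame(x = 1, y = 1, z = runif(1)), sc$scenario1)
  expect_equal(ep2$E_strict, 4)
})

test_that("advantage functions reproduce the expanded bracket polynomials", {
  a <- advantage_functions(c(0.5, 0.5, 0.5), sc$scenario1)
  expect_equal(c(a$Ax, a$Ay, a$Az), c(2.875, 4.125, -1.25))
  # institution advantage at x = z = 0 equals the E1 institution eigenvalue
  a0 <- advantage_functions(data.frame(x = 0, y = 0.3, z = 0), sc$scenario1)
  expect_equal(a0$Ay, 2)                 # Er + Gs - Wm + Wt
  # homogeneity: all-zero parameters give a zero field
  zero <- validate_parameters(setNames(rep(0, 14), param_names()))
  az <- advantage_functions(c(0.3, 0.6, 0.9), zero)
  expect_equal(c(az$Ax, az$Ay, az$Az), c(0, 0, 0))
})

test_that("replicator field is the logistic-weighted advantage and dies on faces", {
  f <- replicator_rhs(c(0.5, 0.5, 0.5), sc$scenario1)
  expect_equal(c(f$Fx, f$Fy, f$Fz), 0.25 * c(2.875, 4.125, -1.25))
  verts <- pure_profiles()
  fv <- replicator_rhs(verts[c("x", "y", "z")], sc$scenario1)
  expect_equal(max(abs(c(fv$Fx, fv$Fy, fv$Fz))), 0)
  withr::with_seed(11, {
    for (i in 1:20) {
      s <- data.frame(x = 0, y = runif(1), z = runif(1))
      expect_equal(replicator_rhs(s, random_params())$Fx, 0)
    }
  })
})

test_that("advantages equal the payoff differences on 1000 random draws", {
  withr::with_seed(42, {
    for (i in 1:10) {
      p <- random_params()
      s <- data.frame(x = runif(100), y = runif(100), z = runif(100))
      a <- advantage_functions(s, p)
      ep <- expected_payoffs(s, p)
      expect_max_norm(a$Ax, ep$E_recognize - ep$E_reject, 1e-9)
      expect_max_norm(a$Ay, ep$E_reasonable - ep$E_overtreat, 1e-9)
      expect_max_norm(a$Az, ep$E_strict - ep$E_lenient, 1e-9)
    }
  })
})

test_that("payoff/polynomial identity holds exactly as polynomials", {
  # both sides are bilinear in the two opposing frequencies, so agreement on
  # the 3x3 grid {0, 1/2, 1}^2 (exact dyadic arithmetic) proves identity
  withr::with_seed(7, {
    for (rep in 1:5) {
      p <- game_params(setNames(sample(0:50, 14, replace = TRUE), param_names()))
      g <- expand.grid(x = c(0, 0.5, 1), y = c(0, 0.5, 1), z = c(0, 0.5, 1))
      a <- advantage_functions(g, p)
      ep <- expected_payoffs(g, p)
      expect_identical(a$Ax, ep$E_recognize - ep$E_reject)
      expect_identical(a$Ay, ep$E_reasonable - ep$E_overtreat)
      expect_identical(a$Az, ep$E_strict - ep$E_lenient)
    }
  })
})

test_that("each advantage is affine in each of its two arguments", {
  withr::with_seed(3, {
    p <- random_params()
    for (i in 1:25) {
      base <- random_state()
      for (comp in c("Ax", "Ay", "Az")) {
        args <- switch(comp, Ax = c("y", "z"), Ay = c("x", "z"), Az = c("x", "y"))
        for (v in args) {
          pts <- data.frame(x = rep(base[1], 3), y = rep(base[2], 3),
                            z = rep(base[3], 3))
          pts[[v]] <- c(0.1, 0.45, 0.8)     # equally spaced
          vals <- advantage_functions(pts, p)[[comp]]
          # second difference of an affine function vanishes
          expect_lt(abs(vals[1] - 2 * vals[2] + vals[3]), 1e-10)
        }
      }
    }
  })
})

test_that("scaling all constants by lambda scales the field by lambda", {
  withr::with_seed(8, {
    p <- random_params()
    lam <- 3.7
    p2 <- validate_parameters(unclass(p) * lam)
    s <- data.frame(x = runif(20), y = runif(20), z = runif(20))
    f1 <- replicator_rhs(s, p)
    f2 <- replicator_rhs(s, p2)
    expect_max_norm(f2$Fx, lam * f1$Fx, 1e-9)
    expect_max_norm(f2$Fy, lam * f1$Fy, 1e-9)
    expect_max_norm(f2$Fz, lam * f1$Fz, 1e-9)
  })
})
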