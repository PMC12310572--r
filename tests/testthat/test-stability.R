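sc <- baseline_scenarios()

test_that("jacobian is diagonal at vertices with the closed-form diagonal", {
  j <- game_jacobian(c(1, 0, 0), sc$scenario1)
  expect_equal(j[row(j) != col(j)], rep(0, 6))
  expect_equal(unname(diag(j)), c(-22.5, -1.5, -5))
  withr::with_seed(21, {
    for (i in 1:200) {
      p <- random_params()
      v <- pure_profiles()[sample(8, 1), ]
      jv <- game_jacobian(c(v$x, v$y, v$z), p)
      expect_equal(jv[row(jv) != col(jv)], rep(0, 6))
      expect_equal(unname(diag(jv)),
                   unname(vertex_eigenvalues(v$label, p)), tolerance = 1e-12)
    }
  })
})

test_that("analytic jacobian matches central finite differences at interior states", {
  fd_jac <- function(s, p, h = 1e-6) {
    out <- matrix(NA_real_, 3, 3)
    for (j in 1:3) {
      up <- s; up[j] <- up[j] + h
      dn <- s; dn[j] <- dn[j] - h
      fu <- replicator_rhs(up, p); fd <- replicator_rhs(dn, p)
      out[, j] <- (c(fu$Fx, fu$Fy, fu$Fz) - c(fd$Fx, fd$Fy, fd$Fz)) / (2 * h)
    }
    out
  }
  j0 <- game_jacobian(c(0.3, 0.6, 0.2), sc$scenario1)
  expect_equal(unname(j0), fd_jac(c(0.3, 0.6, 0.2), sc$scenario1),
               tolerance = 1e-6)
  withr::with_seed(31, {
    for (i in 1:20) {
      p <- random_params()
      s <- random_state(interior = TRUE)
      ja <- game_jacobian(s, p)
      jf <- fd_jac(s, p)
      expect_lt(max(abs(ja - jf)) / max(1, max(abs(ja))), 1e-5)
    }
  })
})

test_that("vertex eigenvalues reproduce the closed-form table rows", {
  expect_equal(unname(vertex_eigenvalues("E2", sc$scenario1)), c(-22.5, -1.5, -5))
  expect_equal(unname(vertex_eigenvalues("E1", sc$scenario1)), c(22.5, 2, 6))
  # patient-direction eigenvalue at E4 and E6 is identically zero
  withr::with_seed(5, {
    for (i in 1:50) {
      p <- random_params()
      expect_equal(vertex_eigenvalues("E4", p)[["lambda1"]], 0)
      expect_equal(vertex_eigenvalues("E6", p)[["lambda1"]], 0)
    }
  })
  expect_error(vertex_eigenvalues("E9", sc$scenario1), class = "trigame_config_error")
  # numeric vertex input maps to its label
  expect_equal(vertex_eigenvalues(c(0, 1, 0), sc$scenario1),
               vertex_eigenvalues("E3", sc$scenario1))
})

test_that("baseline classifications reproduce the reference sign patterns", {
  tab <- tidy(ess_conditions(sc$scenario1))
  expected <- c(E1 = "unstable", E2 = "stable (ESS)", E3 = "stable (ESS)",
                E4 = "indeterminate", E5 = "unstable", E6 = "indeterminate",
                E7 = "unstable", E8 = "unstable")
  expect_equal(setNames(tab$classification, tab$label), expected)
  expect_equal(classify_equilibrium("E2", sc$scenario1)$classification,
               "stable (ESS)")
  expect_equal(classify_equilibrium("E4", sc$scenario1)$classification,
               "indeterminate")
  expect_equal(classify_equilibrium("E1", sc$scenario1)$classification,
               "unstable")
  expect_error(classify_equilibrium("E2", sc$scenario1, tol = -1),
               class = "trigame_validation_error")
})

test_that("stable sets follow the two headline income inequalities", {
  # bistable at the reference scenario: 7.5 < Wm = 9 < 11
  expect_equal(glance(ess_conditions(sc$scenario1))$stable_set, "E2,E3")
  # Wt = 7 destabilises E2 (its institution eigenvalue becomes +1.5)
  e2 <- ess_conditions(sc$scenario2)
  expect_equal(glance(e2)$stable_set, "E3")
  expect_equal(tidy(e2)$lambda2[tidy(e2)$label == "E2"], 1.5)
  # large overtreatment income leaves only the all-defect vertex
  expect_equal(glance(ess_conditions(set_param(sc$scenario1, "Wm", 20)))$stable_set,
               "E2")
})

test_that("inequality and eigenvalue stability agree on 1000 random draws", {
  withr::with_seed(99, {
    sets <- random_params(1000)
    for (p in sets) {
      pl <- as.list(p)
      e2 <- vertex_eigenvalues("E2", p)
      e3 <- vertex_eigenvalues("E3", p)
      if (abs(pl$Wm - (pl$Er + pl$Oc + pl$Wt)) > 1e-9) {
        expect_equal(all(e2 < 0), pl$Wm > pl$Er + pl$Oc + pl$Wt)
      }
      if (abs(pl$Wm - (pl$Gs + pl$Wt + pl$Er)) > 1e-9) {
        expect_equal(all(e3 < 0), pl$Wm < pl$Gs + pl$Wt + pl$Er)
      }
    }
  })
})

test_that("only E2 and E3 can ever have an all-negative eigenvalue triple", {
  # closed form: E4/E6 carry an identically-zero eigenvalue; for strictly
  # positive parameters E1 (Ci+2Cm+Cp), E5 (Ci), E8 (Ci+Cp) have a positive
  # patient eigenvalue and E7 a positive regulator eigenvalue (Cr+Gg)
  withr::with_seed(123, {
    seen_all_neg <- setNames(rep(FALSE, 8), paste0("E", 1:8))
    for (p in random_params(300)) {
      for (lab in names(seen_all_neg)) {
        if (all(vertex_eigenvalues(lab, p) < 0)) seen_all_neg[lab] <- TRUE
      }
      expect_gt(vertex_eigenvalues("E1", p)[["lambda1"]], 0)
      expect_gt(vertex_eigenvalues("E5", p)[["lambda1"]], 0)
      expect_gt(vertex_eigenvalues("E8", p)[["lambda1"]], 0)
      expect_gt(vertex_eigenvalues("E7", p)[["lambda3"]], 0)
    }
    expect_false(any(seen_all_neg[c("E1", "E4", "E5", "E6", "E7", "E8")]))
    expect_true(all(seen_all_neg[c("E2", "E3")]))
  })
})
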