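test_that("complex-step and central-difference Jacobians agree", {
  set.seed(3)
  for (i in 1:5) {
    p <- random_params()
    s <- random_state()
    J1 <- model_jacobian(s, p, 0.2, method = "complex")
    J2 <- model_jacobian(s, p, 0.2, method = "central")
    expect_lt(max(abs(J1 - J2)) / max(abs(J1)), 1e-6)
  }
})

test_that("decoupled receptor rows of the Jacobian are pure decay", {
  p <- extended_params()
  s <- random_state()
  J <- model_jacobian(s, p, 0.1)
  expect_equal(unname(J["GPCR", ]),
               ifelse(STATE_NAMES == "GPCR", -unclass(p)[["d6"]], 0))
  expect_equal(unname(J["CRHR", ]),
               ifelse(STATE_NAMES == "CRHR", -unclass(p)[["d7"]], 0))
})

test_that("equilibria satisfy the decoupled receptor balances and residual contract", {
  p <- extended_params()
  x0 <- default_guess_pkg(p)
  eq <- find_equilibrium(p, 0.1, x0)
  expect_true(eq$converged)
  pp <- unclass(p)
  expect_equal(unname(eq$state["GPCR"]), pp[["v2"]] / pp[["d6"]],
               tolerance = 1e-7)
  expect_equal(unname(eq$state["CRHR"]), pp[["v3"]] / pp[["d7"]],
               tolerance = 1e-7)
  # residual re-evaluated through the rhs
  expect_lt(max(abs(rhs_extended(0, eq$state, p, 0.1))), 1e-10)
  expect_true(all(eq$state >= 0))
})

test_that("zero-production system has a stable equilibrium at the origin", {
  p <- extended_params(v1 = 0, v2 = 0, v3 = 0, v4 = 0,
                       v5 = 0, v6 = 0, v7 = 0, v8 = 0,
                       ks = 0, ktl1 = 0, ktl2 = 0,
                       ktrs1 = 0, ktrs2 = 0)
  eq <- find_equilibrium(p, 0, extended_state() + 0.1)
  expect_true(eq$converged)
  expect_lt(max(eq$state), 1e-6)
  expect_true(eq$stable)
  expect_error(find_equilibrium(p, 0, rep(Inf, 15)), "finite")
})
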