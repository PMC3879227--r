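test_that("limit-point abscissas are deterministic and error on non-two-fold branches", {
  q0 <- fixture_regime("hyper_switch")
  S_a <- lp_abscissas(q0)
  S_b <- lp_abscissas(q0)
  expect_identical(unclass(S_a)[1:2], unclass(S_b)[1:2])
  expect_gt(S_a["S1"], S_a["S2"])
  expect_lt(S_a["S2"], 0.1)  # irreversibility precondition of the fixture
  expect_error(lp_abscissas(extended_params()), "two-fold")
})

test_that("bordered-system fold sensitivities match finite differences of the abscissa map", {
  q0 <- fixture_regime("hyper_switch")
  S0 <- lp_abscissas(q0)
  G <- hpaxis:::.fold_sensitivities(q0, attr(S0, "branch"),
                                    free = c("ks", "d2"))
  for (nm in c("ks", "d2")) {
    h <- 1e-3 * unclass(q0)[[nm]]
    qp <- q0; qp[nm] <- qp[nm] + h
    qm <- q0; qm[nm] <- qm[nm] - h
    fd <- (lp_abscissas(qp) - lp_abscissas(qm)) / (2 * h)
    expect_equal(unname(G[, nm]), unname(fd)[1:2], tolerance = 5e-2)
  }
})

test_that("sparse correction shifts the return fold past basal stress", {
  q0 <- fixture_regime("hyper_switch")
  pr <- correction_problem(q0, basal = 0.1, S2_target = 0.15,
                           alpha = 1e-3, p = 0.9, seed = 1)
  res <- solve_correction(pr)
  expect_true(res$success)
  expect_gte(unname(res$achieved["S2"]), 0.1)
  # S1 approximately maintained
  S0 <- lp_abscissas(q0)
  expect_lt(abs(res$achieved["S1"] - S0["S1"]) / S0["S1"], 0.15)
  # post-correction classification flips to reversible
  expect_equal(res$classification$kind, "reversible_bistable")
  # accepted iterates decrease the objective monotonically
  expect_true(all(diff(res$objective_trace) <= 1e-12))
  # every reported support parameter is in the allowed subset, and the
  # reported directions match the sign of the correction
  rp <- report_intervention(res, print = FALSE)
  expect_true(all(rp$parameter %in% pr$subset))
  expect_equal(rp$direction,
               ifelse(rp$relative_change > 0, "increase", "decrease"))
})

test_that("correction problem validates its inputs", {
  q0 <- fixture_regime("hyper_switch")
  expect_error(correction_problem(q0, basal = 0.1, S2_target = 0.05),
               "exceed")
  expect_error(correction_problem(q0, subset = c("nope")), "unknown")
})
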