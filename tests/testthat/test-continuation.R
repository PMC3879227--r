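test_that("nominal parameters give a monostable branch over the stress range", {
  p <- extended_params()
  br <- continue_equilibria(p, c(0, 1))
  expect_equal(length(br$limit_points), 0)
  expect_true(all(br$stable))
  # single-valued in stress: strictly increasing stress along the branch
  expect_false(is.unsorted(br$stress))
  cs <- classify_switch(br)
  expect_equal(cs$kind, "monostable")
  expect_equal(cs$orientation, "none")
})

test_that("hypocortisolism fixture has two folds bounding a tristable window", {
  p <- fixture_regime("hypo_switch")
  br <- continue_equilibria(p, c(0, 1))
  expect_equal(length(br$limit_points), 2)
  cs <- classify_switch(br, basal_stress = 0.1)
  expect_equal(cs$kind, "irreversible_bistable")
  expect_equal(cs$orientation, "hypo")
  expect_lt(cs$S2, 0.1)
  expect_gt(cs$S1, 0.1)

  # between the fold abscissas three equilibria coexist (2 stable, 1 unstable)
  S_mid <- (cs$S1 + cs$S2) / 2
  scan <- equilibria_dense_scan(p, S_mid, n_starts = 16, seed = 2)
  expect_equal(scan$n_equilibria, 3)
  expect_equal(scan$n_stable, 2)

  # every located limit point has a near-singular Jacobian
  for (lp in br$limit_points) {
    J <- model_jacobian(lp$state, p, lp$stress)
    expect_lt(min(abs(Re(eigen(J, only.values = TRUE)$values))), 1e-6)
  }
})

test_that("stability flags flip only at located bifurcation points", {
  for (fx in c("hypo_switch", "hyper_switch")) {
    p <- fixture_regime(fx)
    br <- continue_equilibria(p, c(0, 1))
    flips <- which(diff(br$stable) != 0)
    located <- sort(c(vapply(br$limit_points, `[[`, numeric(1), "index"),
                      vapply(br$hopf_points, `[[`, numeric(1), "index")))
    # each stability flip must coincide with a located LP or Hopf interval
    expect_true(all(flips %in% located))
  }
})

test_that("continuation is invariant to halving the arclength step", {
  p <- fixture_regime("hyper_switch")
  br1 <- continue_equilibria(p, c(0, 1), ds0 = 0.05, ds_max = 0.4)
  br2 <- continue_equilibria(p, c(0, 1), ds0 = 0.025, ds_max = 0.2)
  s1 <- sort(lp_stress(br1)); s2 <- sort(lp_stress(br2))
  expect_equal(length(s1), length(s2))
  expect_lt(max(abs(s1 - s2)), 1e-4)
})

test_that("hyper fixture shows the inverted branch alignment", {
  p <- fixture_regime("hyper_switch")
  br <- continue_equilibria(p, c(0, 1))
  cs <- classify_switch(br, basal_stress = 0.1)
  expect_equal(cs$kind, "irreversible_bistable")
  expect_equal(cs$orientation, "hyper")
  # the branch reached past S1 carries more cortisol than the basal branch
  first_idx <- min(vapply(br$limit_points, `[[`, numeric(1), "index"))
  last_idx <- max(vapply(br$limit_points, `[[`, numeric(1), "index"))
  expect_gt(mean(br$states[(last_idx + 1):length(br$stress), "COR_ex"]),
            mean(br$states[1:first_idx, "COR_ex"]))
})

test_that("stress pulses move the hyper system to the elevated branch and back only after correction", {
  p <- fixture_regime("hyper_switch")
  prot <- stress_protocol(0.1, data.frame(t_start = 100, t_end = 400,
                                          level = 0.8))
  tr <- simulate_stress_response(p, prot)
  expect_lt(tr$final_residual, 1e-6)
  # trapped: post-pulse cortisol stays far above the pre-pulse level
  expect_gt(unname(tr$final_state["COR_ex"]),
            2 * tr$states[1, "COR_ex"])

  # zero-amplitude pulse keeps the system at equilibrium
  prot0 <- stress_protocol(0.1, data.frame(t_start = 100, t_end = 400,
                                           level = 0.1))
  tr0 <- simulate_stress_response(p, prot0, horizon = 1000)
  expect_lt(max(abs(tr0$states[nrow(tr0$states), ] - tr0$states[1, ])) /
              max(tr0$states[1, ]), 1e-4)
})
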