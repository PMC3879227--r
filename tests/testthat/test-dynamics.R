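test_that("oscillatory fixture sustains a limit cycle with the cascade order of maxima", {
  p <- fixture_regime("oscillatory")
  meta <- jsonlite::read_json(system.file("extdata", "regimes",
                                          "oscillatory.json",
                                          package = "hpaxis"))
  S <- meta$verification$cycle_stress
  lc <- limit_cycle(p, S)
  expect_true(lc$sustained)
  expect_gt(lc$period, 0)
  expect_equal(lc$maxima_order, c("CRH", "ACTH_ex", "COR_ex"))

  # period estimate stable under doubling of the observation horizon
  lc2 <- limit_cycle(p, S, t_observe = 8000)
  expect_lt(abs(lc2$period - lc$period) / lc$period, 0.01)
})

test_that("a damped regime reports no sustained oscillation", {
  p <- extended_params()
  lc <- limit_cycle(p, 0.3, t_transient = 2000, t_observe = 1500)
  expect_false(lc$sustained)
})

test_that("in-vitro fixture reproduces the two-protocol dose-response features", {
  p <- fixture_regime("invitro")
  init <- rest_state(p)
  tt <- seq(0.5, 60, 0.5)
  A <- run_dose_experiment(p, "A", tt, init = init)
  B <- run_dose_experiment(p, "B", tt, init = init)
  # protocol B ends below protocol A (genomic feedback becomes effective)
  expect_lt(B[tt == 60], A[tt == 60])
  # early non-genomic inhibition of release under added cortisol
  expect_lt(B[tt == 2], 0.3 * A[tt == 2])
  # delayed release-rate peak in protocol B near the quarter hour,
  # immediate peak in protocol A
  rate_A <- diff(c(0, A)); rate_B <- diff(c(0, B))
  expect_lt(tt[which.max(rate_A)], 2)
  expect_gt(tt[which.max(rate_B)], 8)
  expect_lt(tt[which.max(rate_B)], 25)
})

test_that("stress response lands on module-computed branch equilibria", {
  p <- fixture_regime("hypo_switch")
  br <- continue_equilibria(p, c(0, 1))
  cs <- classify_switch(br, 0.1)
  prot <- stress_protocol(0.1, data.frame(t_start = 100, t_end = 400,
                                          level = 0.9))
  tr <- simulate_stress_response(p, prot)
  expect_lt(tr$final_residual, 1e-6)
  # the post-pulse state is a branch equilibrium at basal stress:
  # locate the nearest branch point at stress ~ 0.1 on the far segment
  last_idx <- max(vapply(br$limit_points, `[[`, numeric(1), "index"))
  far <- seq(last_idx + 1, length(br$stress))
  j <- far[which.min(abs(br$stress[far] - 0.1))]
  expect_lt(abs(unname(tr$final_state["COR_ex"]) - br$states[j, "COR_ex"]) /
              br$states[j, "COR_ex"], 0.05)
  # hypo orientation: trapped below the pre-pulse cortisol level
  expect_lt(unname(tr$final_state["COR_ex"]), tr$states[1, "COR_ex"])
})
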