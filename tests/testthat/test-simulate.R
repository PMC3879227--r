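test_that("zero-production system stays at the origin", {
  p <- extended_params(v1 = 0, v2 = 0, v3 = 0, v4 = 0,
                       v5 = 0, v6 = 0, v7 = 0, v8 = 0,
                       ks = 0, ktl1 = 0, ktl2 = 0,
                       ktrs1 = 0, ktrs2 = 0)
  tr <- integrate_model("extended", extended_state(), stress_protocol(0),
                        seq(0, 100, 5), p)
  expect_lt(max(abs(tr$states)), 1e-12)
})

test_that("dose events are exact jumps and conserve non-dosed states", {
  p <- extended_params()
  init <- default_guess_pkg(p)
  tr <- integrate_model("extended", init, stress_protocol(0),
                        t_grid = c(0, 1, 2, 5),
                        params = p, doses = list(dose_event(0, "CRH", 10)))
  # CRH(0+) = initial + 10 exactly; other states untouched at t = 0
  expect_equal(unname(tr$states[1, "CRH"]), unname(init["CRH"]) + 10)
  others <- setdiff(STATE_NAMES, "CRH")
  expect_equal(tr$states[1, others], init[others], tolerance = 1e-12)

  # mid-trajectory dose: non-dosed states continuous across the event
  tr2 <- integrate_model("extended", init, stress_protocol(0.1),
                         t_grid = seq(0, 20, 0.5), params = p,
                         doses = list(dose_event(10, "COR_ex", 50)))
  i_pre <- which(tr2$times == 10)
  tr2b <- integrate_model("extended", init, stress_protocol(0.1),
                          t_grid = seq(0, 10, 0.5), params = p)
  expect_equal(tr2$states[i_pre, "COR_ex"],
               tr2b$states[nrow(tr2b$states), "COR_ex"] + 50,
               tolerance = 1e-6)
  expect_error(integrate_model("extended", init, stress_protocol(0),
                               c(0, 5), p,
                               doses = list(dose_event(50, "CRH", 1))),
               "within the time grid")
})

test_that("trajectories converge under tolerance and grid refinement", {
  p <- extended_params()
  init <- default_guess_pkg(p)
  prot <- stress_protocol(0.1, data.frame(t_start = 10, t_end = 30,
                                          level = 0.8))
  t1 <- seq(0, 100, 2)
  tr_a <- integrate_model("extended", init, prot, t1, p,
                          rtol = 1e-8, atol = 1e-10)
  tr_b <- integrate_model("extended", init, prot, t1, p,
                          rtol = 5e-9, atol = 5e-11)
  rel <- max(abs(tr_a$states - tr_b$states) /
               pmax(abs(tr_a$states), 1e-6))
  expect_lt(rel, 1e-5)

  # doubling output resolution leaves shared points unchanged
  t2 <- seq(0, 100, 1)
  tr_c <- integrate_model("extended", init, prot, t2, p,
                          rtol = 1e-8, atol = 1e-10)
  shared <- match(t1, t2)
  rel2 <- max(abs(tr_a$states - tr_c$states[shared, ]) /
                pmax(abs(tr_a$states), 1e-6))
  expect_lt(rel2, 1e-6)
})

test_that("compiled and reference engines agree", {
  p <- extended_params()
  init <- default_guess_pkg(p)
  t_grid <- seq(0, 60, 2)
  a <- integrate_model("extended", init, stress_protocol(0.2), t_grid, p,
                       engine = "C")
  b <- integrate_model("extended", init, stress_protocol(0.2), t_grid, p,
                       engine = "R")
  expect_equal(a$states, b$states, tolerance = 1e-8)

  pp <- parsimonious_params()
  ip <- parsimonious_state(CRH = 1, ACTH = 1, GR = 1, COR = 1)
  a2 <- integrate_model("parsimonious", ip, stress_protocol(0.3), t_grid,
                        pp, engine = "C")
  b2 <- integrate_model("parsimonious", ip, stress_protocol(0.3), t_grid,
                        pp, engine = "R")
  expect_equal(a2$states, b2$states, tolerance = 1e-8)
})

test_that("simulation from non-negative states stays non-negative", {
  set.seed(9)
  for (i in 1:5) {
    p <- random_params()
    init <- random_state()
    tr <- tryCatch(
      integrate_model("extended", init, stress_protocol(0.3),
                      seq(0, 500, 10), p),
      error = function(e) NULL)
    if (is.null(tr)) next
    expect_gt(min(tr$states), -1e-8)
  }
})

test_that("in-vitro dose experiment obeys its contract", {
  p <- extended_params()
  init <- rest_state(p)
  # readout at t -> 0 equals the (zero) initial medium ACTH
  y <- run_dose_experiment(p, "A", sample_times = c(1e-6, 30), init = init)
  expect_lt(y[1], 1e-3)
  expect_error(run_dose_experiment(p, "A", sample_times = c(10, 90)),
               "within")
})

test_that("protocol YAML files round trip into protocol objects", {
  skip_if_not_installed("yaml")
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "baseline: 0.1",
    "pulses:",
    "  - {t_start: 10, t_end: 30, level: 0.8}",
    "doses:",
    "  - {time: 0, species: CRH, amount_nM: 10}"
  ), f)
  pr <- read_protocol_yaml(f)
  expect_equal(pr$protocol$baseline, 0.1)
  expect_equal(pr$protocol$pulses$level, 0.8)
  expect_equal(stress_at(pr$protocol, c(5, 20, 40)), c(0.1, 0.8, 0.1))
  expect_equal(pr$doses[[1]]$species, "CRH")
  expect_equal(pr$doses[[1]]$amount, 10)
  unlink(f)
})
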