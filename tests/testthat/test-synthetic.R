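test_that("generator is exact at zero noise and reproducible under a seed", {
  cfg0 <- acth_generator_config(sigma_rel = 0, sigma_abs = 0, seed = 4)
  ds0 <- generate_acth_dataset(cfg0)
  clean <- attr(ds0, "truth")$noiseless
  expect_equal(ds0$acth_nM[ds0$protocol == "A"], clean$A)
  expect_equal(ds0$acth_nM[ds0$protocol == "B"], clean$B)
  expect_true(all(ds0$ci_halfwidth_nM == 0))

  cfg <- acth_generator_config(seed = 7)
  d1 <- generate_acth_dataset(cfg)
  d2 <- generate_acth_dataset(cfg)
  expect_identical(d1$acth_nM, d2$acth_nM)
})

test_that("confidence half-widths scale as one over the square root of replicates", {
  base <- acth_generator_config(n_rep = 3, seed = 1)
  ci <- lapply(c(3, 12, 48), function(n) {
    cfg <- base; cfg$n_rep <- n
    generate_acth_dataset(cfg)$ci_halfwidth_nM
  })
  expect_equal(ci[[1]] / ci[[2]], rep(2, length(ci[[1]])), tolerance = 1e-12)
  expect_equal(ci[[2]] / ci[[3]], rep(2, length(ci[[2]])), tolerance = 1e-12)
})

test_that("fitting the generator's own output attains the noise-implied residual", {
  cfg <- acth_generator_config(sigma_rel = 0.05, sigma_abs = 0.05,
                               n_rep = 4, seed = 8)
  ds <- generate_acth_dataset(cfg)
  truth <- attr(ds, "truth")$params
  # chi-square-scale bound: the weighted residual implied by the draw
  prob <- fit_problem(ds, alpha = 0, base_params = truth)
  noise_resid <- as.numeric(fit_objective(unclass(truth)[prob$free], prob))
  prob$budget <- list(n_starts = 4, n_refine = 1, maxit1 = 12, maxit2 = 3,
                      group_pass = FALSE)
  fit <- fit_two_step(prob)
  expect_lte(sum(fit$residuals), noise_resid + 1e-6)
})

test_that("dataset CSV round trip preserves the table", {
  ds <- generate_acth_dataset(acth_generator_config(seed = 2))
  f <- tempfile(fileext = ".csv")
  write_acth_csv(ds, f)
  ds2 <- read_acth_csv(f)
  for (col in names(ds))
    expect_equal(ds2[[col]], ds[[col]], tolerance = 1e-12)
  unlink(f)
})

test_that("cached fixture regimes verify against their targets", {
  fx <- make_fixture_regimes()
  expect_setequal(names(fx), c("hypo_switch", "hyper_switch", "oscillatory",
                               "invitro"))
  cs_hypo <- classify_switch(continue_equilibria(fx$hypo_switch, c(0, 1)), 0.1)
  expect_equal(cs_hypo$kind, "irreversible_bistable")
  expect_equal(cs_hypo$orientation, "hypo")
  cs_hyper <- classify_switch(continue_equilibria(fx$hyper_switch, c(0, 1)), 0.1)
  expect_equal(cs_hyper$kind, "irreversible_bistable")
  expect_equal(cs_hyper$orientation, "hyper")
})
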