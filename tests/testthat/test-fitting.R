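test_that("lp penalty values and monotonicity", {
  expect_equal(lp_penalty(numeric(3), 0.9), 0)
  expect_equal(lp_penalty(c(1, 1), 0.9), 2)
  expect_equal(lp_penalty(c(3, 4), 2), 25)
  expect_error(lp_penalty(1, 2.5), "p must lie")

  # smoothed surrogate approaches the exact penalty as eps -> 0
  # (the bias per component is bounded by eps^p)
  q <- c(0.2, 1.5, 3)
  expect_lt(abs(lp_penalty(q, 0.9, eps = 1e-8) - lp_penalty(q, 0.9)),
            1.1 * length(q) * (1e-8)^0.9)

  set.seed(5)
  for (i in 1:20) {
    q <- stats::runif(6, 0, 1)   # |q_i| <= 1
    # monotone in each component
    q2 <- q; j <- sample(6, 1); q2[j] <- q2[j] * 1.3
    expect_gte(lp_penalty(pmin(q2, 1), 0.9), lp_penalty(q, 0.9) - 1e-12)
    # for |q| <= 1 a smaller exponent penalises more
    expect_gte(lp_penalty(q, 0.7), lp_penalty(q, 1.3))
  }
})

test_that("objective vanishes at the generating point and is linear in alpha", {
  cfg <- acth_generator_config(sigma_rel = 0, sigma_abs = 0, seed = 1)
  ds <- generate_acth_dataset(cfg)
  truth <- attr(ds, "truth")$params
  prob <- fit_problem(ds, alpha = 0, weighted = FALSE, base_params = truth)
  q0 <- unclass(truth)[prob$free]
  o0 <- fit_objective(q0, prob)
  expect_lt(as.numeric(o0), 1e-5)
  expect_false(attr(o0, "failed"))

  # doubling alpha raises the objective by exactly alpha * penalty
  prob1 <- prob; prob1$alpha <- 0.3
  prob2 <- prob; prob2$alpha <- 0.6
  o1 <- as.numeric(fit_objective(q0, prob1))
  o2 <- as.numeric(fit_objective(q0, prob2))
  expect_equal(o2 - o1, 0.3 * lp_penalty(q0, prob$p), tolerance = 1e-8)

  # the generating point is a global minimum of the alpha = 0 objective
  set.seed(21)
  for (i in 1:20) {
    qp <- q0 * exp(stats::rnorm(length(q0), 0, 0.1))
    expect_gte(as.numeric(fit_objective(qp, prob)), as.numeric(o0))
  }
})

test_that("two-step fit recovers the identifiable subset on noiseless data", {
  cfg <- acth_generator_config(sigma_rel = 0, sigma_abs = 0, seed = 1)
  ds <- generate_acth_dataset(cfg)
  truth <- attr(ds, "truth")$params
  subset <- c("k1ex", "K4", "ktl1", "d5", "v5", "v6", "K7", "ktrs1",
              "d10", "d14", "kGC2", "K5")
  set.seed(42)
  base <- truth
  base[subset] <- unclass(truth)[subset] *
    exp(stats::rnorm(length(subset), 0, log(1.8)))
  base <- extended_params(base = base)

  run <- function(bud) {
    prob <- fit_problem(ds, alpha = 0, weighted = FALSE, base_params = base,
                        free = subset, spread = 8, seed = 3, budget = bud)
    fit <- fit_two_step(prob)
    list(fit = fit,
         err = abs(log(fit$q_star / unclass(truth)[subset])))
  }
  small <- run(list(n_starts = 6, n_refine = 1, maxit1 = 15, maxit2 = 5))
  large <- run(list(n_starts = 10, n_refine = 2, maxit1 = 60, maxit2 = 5))

  # residual shrinks as the optimiser budget grows
  expect_lt(sum(large$fit$residuals), sum(small$fit$residuals))
  # identifiable-subset recovery: every parameter within a factor 2.5,
  # median within a factor 1.5 at the larger budget
  expect_lt(exp(max(large$err)), 2.5)
  expect_lt(exp(stats::median(large$err)), 1.5)
  # reported objective re-evaluates to the stored value
  probs <- large$fit$problem; probs$p <- large$fit$p
  expect_equal(as.numeric(fit_objective(large$fit$q_star, probs)),
               large$fit$objective, tolerance = 1e-10)
  # determinism of the full pipeline under a fixed seed
  rerun <- run(list(n_starts = 6, n_refine = 1, maxit1 = 15, maxit2 = 5))
  expect_identical(rerun$fit$q_star, small$fit$q_star)
})
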