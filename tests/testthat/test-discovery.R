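test_that("verify_regime rejects mismatched regimes and accepts fixtures", {
  tgt_hyper <- regime_target("fold_bistable_hyper")
  # the monostable nominal set is rejected
  v0 <- verify_regime(extended_params(), tgt_hyper)
  expect_false(v0$ok)
  # the hypo fixture does not pass the hyper target
  v1 <- verify_regime(fixture_regime("hypo_switch"), tgt_hyper)
  expect_false(v1$ok)
  # fixtures pass their own targets
  expect_true(verify_regime(fixture_regime("hyper_switch"), tgt_hyper)$ok)
  expect_true(verify_regime(fixture_regime("hypo_switch"),
                            regime_target("fold_bistable_hypo"))$ok)
})

test_that("seeded discovery is deterministic and verifies its own output", {
  tgt <- regime_target("fold_bistable_hyper")
  r1 <- search_regime(tgt, n_starts = 40, seed = 1)
  r2 <- search_regime(tgt, n_starts = 40, seed = 1)
  expect_identical(unclass(r1$params), unclass(r2$params))
  expect_true(r1$verified)
  # closure: the returned parameters re-verify under a fresh continuation
  expect_true(verify_regime(r1$params, tgt)$ok)
  cs <- r1$classification
  expect_equal(cs$kind, "irreversible_bistable")
  expect_equal(cs$orientation, "hyper")
  expect_lt(cs$S2, 0.1)
})

test_that("regime targets validate their inputs", {
  expect_error(regime_target("fold_bistable_hypo", basal = 2), "basal")
  expect_error(regime_target("fold_bistable_hypo",
                             bounds = list(zzz = c(1, 2))), "unknown")
  expect_error(regime_target("fold_bistable_hypo",
                             bounds = list(ks = c(-1, 2))), "positive")
})
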