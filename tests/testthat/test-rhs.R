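test_that("membrane complex closures follow the cooperative square law", {
  p <- extended_params(kCRC = 6, kGC2 = 50)
  s <- extended_state(CRHR = 2, CRH = 3, GPCR = 1, COR_ex = 4)
  mc <- membrane_complexes(s, p)
  expect_equal(mc$CRHR_CRH, 1)           # 2*3/6
  expect_equal(mc$GPCR_COR2, 16 / 50)    # 1*4^2/50

  # zero receptor -> zero complex
  s0 <- extended_state(CRHR = 0, CRH = 123)
  expect_equal(membrane_complexes(s0, p)$CRHR_CRH, 0)

  # doubling extracellular cortisol quadruples the GPCR complex
  s2 <- s; s2["COR_ex"] <- 8
  expect_equal(membrane_complexes(s2, p)$GPCR_COR2,
               4 * membrane_complexes(s, p)$GPCR_COR2)

  expect_error(membrane_complexes(extended_state(CRH = -1), p), "negative")
})

test_that("dimer transport flux vanishes at the transport equilibrium and has one sign change", {
  p <- extended_params()
  kb <- kbar(p)
  kappa <- unclass(p)[["kGRC"]]^2 * unclass(p)[["kGRdim"]]
  C <- 1; G <- 1
  D_cyt <- C^2 * G^2 / kappa
  D_eq <- unclass(p)[["k2in"]] * D_cyt / (kb * unclass(p)[["k2ex"]])
  expect_equal(dimer_flux_F(D_eq, C, G, p), 0, tolerance = 1e-14)

  # import term vanishes when free cortisol is absent
  expect_gte(dimer_flux_F(3, 0, 5, p), 0)
  expect_equal(dimer_flux_F(3, 0, 0, p), 2 * kb * unclass(p)[["k2ex"]] * 3)

  # exactly one sign change along an increasing D_nu ray
  d_grid <- seq(0, 10 * D_eq, length.out = 400)
  fs <- vapply(d_grid, dimer_flux_F, numeric(1), COR_in = C, GR = G,
               params = p)
  expect_equal(sum(diff(sign(fs[fs != 0])) != 0), 1)

  # agrees with the independently typed closed form on random draws
  set.seed(4)
  for (i in 1:25) {
    pr <- random_params()
    d <- stats::rlnorm(1, 0, 1); c_ <- stats::rlnorm(1, 0, 1)
    g <- stats::rlnorm(1, 0, 1)
    expect_equal(dimer_flux_F(d, c_, g, pr), oracle_flux(d, c_, g, pr),
                 tolerance = 1e-12)
  }
  expect_error(dimer_flux_F(NaN, 1, 1, p), "non-finite")
})

test_that("the dimer flux enters the cortisol and GR balances as one shared value", {
  set.seed(8)
  for (i in 1:10) {
    p <- random_params()
    s <- random_state()
    d <- rhs_extended(0, s, p, 0.4)
    pp <- unclass(p)
    ff_from_cor <- unname(d["COR_in"]) -
      (pp[["kdiff1"]] * (s[["COR_ex"]] - s[["COR_in"]]) -
         pp[["d4"]] * s[["COR_in"]])
    ff_from_gr <- unname(d["GR"]) -
      (pp[["ktl2"]] * s[["mGR"]] - pp[["d8"]] * s[["GR"]])
    expect_equal(ff_from_cor, ff_from_gr, tolerance = 1e-12)
    expect_equal(ff_from_cor,
                 dimer_flux_F(s[["GRCOR2_nu"]], s[["COR_in"]], s[["GR"]], p),
                 tolerance = 1e-12)
  }
})

test_that("extended rhs matches the symbolic oracle on 100 random draws", {
  set.seed(1)
  for (i in 1:100) {
    p <- random_params()
    s <- random_state()
    stress <- stats::runif(1, 0, 2)
    got <- rhs_extended(0, s, p, stress)
    want <- oracle_rhs_extended(s, p, stress)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("linear production-degradation balances are rhs fixed points", {
  p <- extended_params()
  pp <- unclass(p)
  s <- random_state()
  s["GPCR"] <- pp[["v2"]] / pp[["d6"]]
  expect_equal(unname(rhs_extended(0, s, p, 0.5)["GPCR"]), 0)

  # all production off, zero state -> zero vector
  p0 <- extended_params(v1 = 0, v2 = 0, v3 = 0, v4 = 0,
                        v5 = 0, v6 = 0, v7 = 0, v8 = 0,
                        ks = 0, ktl1 = 0, ktl2 = 0,
                        ktrs1 = 0, ktrs2 = 0)
  z <- extended_state()
  expect_equal(max(abs(rhs_extended(0, z, p0, 0))), 0)

  expect_error(rhs_extended(0, random_state(), p, -0.1), "stress")
  expect_error(rhs_extended(0, numeric(14), p, 0), "length 15")
})

test_that("parsimonious rhs matches its oracle and stated balances", {
  p <- parsimonious_params()
  pp <- unclass(p)
  set.seed(2)
  for (i in 1:25) {
    s <- stats::setNames(stats::rlnorm(4, 0, 1), PARS_STATE_NAMES)
    stress <- stats::runif(1, 0, 2)
    expect_equal(rhs_parsimonious(0, s, p, stress),
                 oracle_rhs_parsimonious(s, p, stress), tolerance = 1e-12)
  }
  # COR = 0, stress = 0, CRH = kc/kcd is a CRH balance
  s <- parsimonious_state(CRH = pp[["kc"]] / pp[["kcd"]])
  expect_equal(unname(rhs_parsimonious(0, s, p, 0)["CRH"]), 0)
  # COR*GR = 0: GR balance at kcr/krd
  s2 <- parsimonious_state(GR = pp[["kcr"]] / pp[["krd"]])
  expect_equal(unname(rhs_parsimonious(0, s2, p, 0)["GR"]), 0)
  # production-degradation balance of cortisol
  p3 <- parsimonious_params(ko = 1, kod = 1)
  s3 <- parsimonious_state(ACTH = 1, COR = 1)
  expect_equal(unname(rhs_parsimonious(0, s3, p3, 0)["COR"]), 0)
})

test_that("knockouts remove exactly the documented terms", {
  p <- extended_params()
  s <- random_state()

  # gpcr knockout: release denominator loses the GPCR complex
  ko <- apply_knockout("gpcr_pathway")
  expect_true(ko$knockout$gpcr)
  expect_true(length(ko$removed) > 0)
  d_ko <- rhs_extended(0, s, p, 0.3, knockout = ko)
  s_nogc <- s; s_nogc["GPCR"] <- 0
  d_ref <- rhs_extended(0, s_nogc, p, 0.3)
  expect_equal(d_ko[c("ACTH_ex", "ACTH_in")], d_ref[c("ACTH_ex", "ACTH_in")])
  expect_equal(unname(d_ko["GPCR"]), 0)

  # crh feedback knockout: TFs production decoupled from the CRH complex
  ko2 <- apply_knockout("crh_genomic_feedback")
  s_a <- s; s_b <- s; s_b["CRH"] <- s_b["CRH"] * 7
  da <- rhs_extended(0, s_a, p, 0.3, knockout = ko2)
  db <- rhs_extended(0, s_b, p, 0.3, knockout = ko2)
  expect_equal(da["TFs_in"], db["TFs_in"])

  # gr loop knockout: pmGR production reduces to the basal rate
  ko3 <- apply_knockout("gr_autocatalytic_loop")
  d3 <- rhs_extended(0, s, p, 0.3, knockout = ko3)
  pp <- unclass(p)
  expect_equal(unname(d3["pmGR"]),
               pp[["v7"]] - (pp[["ktrs2"]] + pp[["d15"]]) * s[["pmGR"]])

  expect_error(apply_knockout("nonsense"), "valid knockouts")
})

test_that("parameter table reconciles the free-parameter count", {
  tab <- param_table()
  expect_equal(nrow(tab), 51)
  expect_equal(sum(tab$free), 46)
  expect_setequal(tab$name[!tab$free], c("V_in", "V_ex", "V_nu", "h", "ksb"))
  expect_equal(length(STATE_NAMES), 15)
  expect_equal(length(PARS_STATE_NAMES), 4)
})

test_that("parameter JSON round trip is exact", {
  p <- extended_params(kdiff1 = 0.123456789, v4 = 3.14159e-7)
  f <- tempfile(fileext = ".json")
  write_params_json(p, f)
  p2 <- read_params_json(f)
  expect_identical(unclass(p2), hpaxis:::as_params(p))
  unlink(f)
})
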