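# Independent symbolic-evaluation oracle for the model right-hand sides.
# The equations are retyped here as quoted R expressions and evaluated with
# base R's interpreter on a flat name environment -- a separate path from
# the package implementation.

oracle_flux_expr <- quote(
  2 * (V_nu / (2 * V_in) * k2ex * GRCOR2_nu -
         k2in * (COR_in^2 * GR^2 / (kGRC^2 * kGRdim))) /
    (1 + 4 * COR_in * GR * (COR_in + GR) / (kGRC^2 * kGRdim))
)

oracle_exprs <- local({
  CC <- quote(CRHR * CRH / kCRC)
  GC <- quote(GPCR * COR_ex^2 / kGC2)
  REL <- substitute(k1ex * CC * ACTH_in / (K4 * (1 + GC / K5) + CC),
                    list(CC = CC, GC = GC))
  FF <- oracle_flux_expr
  list(
    COR_ex = quote(V_in / V_ex * kdiff1 * (COR_in - COR_ex) +
                     v1 * ACTH_ex / (K1 + ACTH_ex) - d1 * COR_ex),
    CRH = quote(ks * (ksb + stress) / (1 + COR_ex / K3) - d2 * CRH),
    ACTH_ex = substitute(V_in / V_ex * REL - d3 * ACTH_ex, list(REL = REL)),
    COR_in = substitute(kdiff1 * (COR_ex - COR_in) - d4 * COR_in + FF,
                        list(FF = FF)),
    ACTH_in = substitute(ktl1 * mPOMC - d5 * ACTH_in - REL, list(REL = REL)),
    GPCR = quote(v2 - d6 * GPCR),
    CRHR = quote(v3 - d7 * CRHR),
    GR = substitute(ktl2 * mGR + FF - d8 * GR, list(FF = FF)),
    GRCOR2_nu = quote(k2in * (COR_in^2 * GR^2 / (kGRC^2 * kGRdim)) -
                        k2ex * GRCOR2_nu - d9 * GRCOR2_nu),
    mPOMC = quote(V_nu / V_in * ktrs1 * pmPOMC - d10 * mPOMC),
    mGR = quote(V_nu / V_in * ktrs2 * pmGR - d11 * mGR),
    TFs_in = substitute(V_nu / V_in * k3ex * TFs_nu - k3in * TFs_in -
                          d12 * TFs_in +
                          v4 * CC^h / (K6^h + CC^h), list(CC = CC)),
    TFs_nu = quote(k3in * TFs_in - k3ex * TFs_nu - d13 * TFs_nu),
    pmPOMC = quote(-ktrs1 * pmPOMC + v5 - d14 * pmPOMC +
                     v6 * TFs_nu / (K7 * (1 + GRCOR2_nu / K8) + TFs_nu)),
    pmGR = quote(-ktrs2 * pmGR + v7 + v8 * GRCOR2_nu / (K9 + GRCOR2_nu) -
                   d15 * pmGR)
  )
})

oracle_rhs_extended <- function(state, params, stress) {
  env <- as.list(c(state, hpaxis:::as_params(params), stress = stress))
  vapply(oracle_exprs, eval, numeric(1), envir = env)
}

oracle_flux <- function(D_nu, COR_in, GR, params) {
  env <- as.list(hpaxis:::as_params(params))
  env$GRCOR2_nu <- D_nu; env$COR_in <- COR_in; env$GR <- GR
  eval(oracle_flux_expr, envir = env)
}

oracle_rhs_parsimonious <- function(state, params, stress) {
  env <- as.list(c(state, unclass(params), stress = stress))
  ex <- list(
    CRH = quote((kc + stress) / (1 + COR / ki1) - kcd * CRH),
    ACTH = quote(ka * CRH / (1 + COR * GR / ki2) - kad * ACTH),
    GR = quote(kr * (COR * GR)^2 / (k + (COR * GR)^2) + kcr - krd * GR),
    COR = quote(ko * ACTH - kod * COR)
  )
  vapply(ex, eval, numeric(1), envir = env)
}

default_guess_pkg <- function(p) hpaxis:::default_guess(p)

# random positive draws for property-style tests
random_state <- function() {
  x <- stats::rlnorm(15, meanlog = 0, sdlog = 1.5)
  names(x) <- hpaxis::STATE_NAMES
  x
}

random_params <- function() {
  p <- hpaxis:::as_params(hpaxis::extended_params())
  scl <- stats::rlnorm(length(p), 0, 0.7)
  p <- p * scl
  p["h"] <- sample(c(1, 2, 3), 1)
  p[c("V_in", "V_ex", "V_nu")] <- stats::rlnorm(3, 0, 0.3)
  hpaxis::extended_params(base = p)
}
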