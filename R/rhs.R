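#' Quasi-equilibrium membrane receptor complexes
#'
#' The CRH receptor complex and the cooperatively bound GPCR-cortisol
#' complex are fast relative to the remaining kinetics and are closed
#' algebraically: `CRHR_CRH = CRHR * CRH / kCRC` and
#' `GPCR_COR2 = GPCR * COR_ex^2 / kGC2` (two cortisol ligands bind the
#' membrane receptor with positive cooperativity, hence the square law).
#'
#' @param state extended state vector (see [extended_state()]).
#' @param params parameter vector (see [extended_params()]).
#' @return list with components `CRHR_CRH` and `GPCR_COR2` (nM).
#' @export
membrane_complexes <- function(state, params) {
  s <- as_state(state)
  p <- as_params(params)
  if (any(s < 0)) stop("negative concentrations in state")
  list(
    CRHR_CRH  = unname(s["CRHR"] * s["CRH"] / p["kCRC"]),
    GPCR_COR2 = unname(s["GPCR"] * s["COR_ex"] * s["COR_ex"] / p["kGC2"])
  )
}

#' Net nuclear transport flux of the dimerised GR-cortisol complex
#'
#' Under fast cortisol-GR binding (dissociation constant `kGRC`) and fast
#' homodimerisation (`kGRdim`), the cytoplasmic dimer concentration is
#' `D_cyt = COR_in^2 GR^2 / (kGRC^2 kGRdim)`. Projecting the slow nuclear
#' import/export of the dimer onto the free cytoplasmic species gives the
#' net rate of change of free cortisol (identically, of free GR):
#'
#' `F = 2 (kbar k2ex D_nu - k2in D_cyt) / (1 + 4 COR_in GR (COR_in + GR) / (kGRC^2 kGRdim))`
#'
#' with `kbar = V_nu/(2 V_in)`. `F > 0` when nuclear export dominates and
#' `F = 0` exactly at the transport equilibrium
#' `kbar k2ex D_nu = k2in D_cyt`.
#'
#' @param D_nu nuclear dimer concentration (nM).
#' @param COR_in free cytoplasmic cortisol (nM).
#' @param GR free cytoplasmic glucocorticoid receptor (nM).
#' @param params parameter vector.
#' @return flux in nM/min (scalar).
#' @export
dimer_flux_F <- function(D_nu, COR_in, GR, params) {
  if (!all(is.finite(c(abs(D_nu), abs(COR_in), abs(GR)))))
    stop("non-finite input to dimer_flux_F")
  p <- as_params(params)
  .flux_F(D_nu, COR_in, GR, p, p["V_nu"] / (2 * p["V_in"]))
}

# arithmetic core, complex-step safe (no abs/max/branching on values)
.flux_F <- function(D_nu, C, G, p, kb) {
  kappa <- p[["kGRC"]]^2 * p[["kGRdim"]]
  D_cyt <- C * C * G * G / kappa
  unname(2 * (kb * p[["k2ex"]] * D_nu - p[["k2in"]] * D_cyt) /
           (1 + 4 * C * G * (C + G) / kappa))
}

#' Right-hand side of the extended 15-state pituitary HPA model
#'
#' Time derivatives of all 15 states (nM/min). The CRH production is
#' competitively inhibited by extracellular cortisol; ACTH release from
#' vesicles is catalysed by the CRHR-CRH complex and competitively
#' inhibited by the GPCR-cortisol complex; POMC transcription is driven by
#' nuclear transcription factors under competitive inhibition by the
#' nuclear GR-cortisol dimer; GR transcription carries the autocatalytic
#' dimer-enhanced term; TFs production responds to the CRHR-CRH complex
#' through a Hill term with coefficient `h`.
#'
#' The function is written in plain arithmetic so that it can be evaluated
#' on complex state perturbations (complex-step differentiation).
#'
#' @param t time (min); the autonomous system ignores it.
#' @param state extended state vector (numeric or complex, length 15).
#' @param params parameter vector.
#' @param stress dimensionless stress input (>= 0).
#' @param knockout optional knockout flags as produced by [apply_knockout()]
#'   (a list with logical elements `gpcr`, `crhfb`, `grloop`).
#' @return vector of 15 time derivatives, named as [STATE_NAMES].
#' @export
rhs_extended <- function(t, state, params, stress = 0,
                         knockout = NULL) {
  if (length(state) != 15L) stop("state must have length 15")
  if (any(!is.finite(abs(state)))) stop("non-finite state")
  if (is.numeric(stress) && stress < 0) stop("stress must be >= 0")
  p <- as_params(params)
  ko <- .knockout_flags(knockout)
  s <- if (is.null(names(state))) {
    stats::setNames(as.vector(state), STATE_NAMES)
  } else state[STATE_NAMES]

  COR_ex <- s[["COR_ex"]]; CRH <- s[["CRH"]]; ACTH_ex <- s[["ACTH_ex"]]
  COR_in <- s[["COR_in"]]; ACTH_in <- s[["ACTH_in"]]; GPCR <- s[["GPCR"]]
  CRHR <- s[["CRHR"]]; GR <- s[["GR"]]; D_nu <- s[["GRCOR2_nu"]]
  mPOMC <- s[["mPOMC"]]; mGR <- s[["mGR"]]; TFs_in <- s[["TFs_in"]]
  TFs_nu <- s[["TFs_nu"]]; pmPOMC <- s[["pmPOMC"]]; pmGR <- s[["pmGR"]]

  vie <- p[["V_in"]] / p[["V_ex"]]
  vni <- p[["V_nu"]] / p[["V_in"]]
  kb  <- p[["V_nu"]] / (2 * p[["V_in"]])

  CC <- CRHR * CRH / p[["kCRC"]]
  GC <- if (ko$gpcr) 0 else GPCR * COR_ex * COR_ex / p[["kGC2"]]

  kappa <- p[["kGRC"]]^2 * p[["kGRdim"]]
  D_cyt <- COR_in * COR_in * GR * GR / kappa
  FF <- .flux_F(D_nu, COR_in, GR, p, kb)

  release <- p[["k1ex"]] * CC * ACTH_in /
    (p[["K4"]] * (1 + GC / p[["K5"]]) + CC)

  tf_prod <- if (ko$crhfb) 0 else {
    p[["v4"]] * CC^p[["h"]] / (p[["K6"]]^p[["h"]] + CC^p[["h"]])
  }

  gr_auto <- if (ko$grloop) 0 else {
    p[["v8"]] * D_nu / (p[["K9"]] + D_nu)
  }

  d <- c(
    COR_ex = vie * p[["kdiff1"]] * (COR_in - COR_ex) +
      p[["v1"]] * ACTH_ex / (p[["K1"]] + ACTH_ex) - p[["d1"]] * COR_ex,
    CRH = p[["ks"]] * (p[["ksb"]] + stress) / (1 + COR_ex / p[["K3"]]) -
      p[["d2"]] * CRH,
    ACTH_ex = vie * release - p[["d3"]] * ACTH_ex,
    COR_in = p[["kdiff1"]] * (COR_ex - COR_in) - p[["d4"]] * COR_in + FF,
    ACTH_in = p[["ktl1"]] * mPOMC - p[["d5"]] * ACTH_in - release,
    GPCR = if (ko$gpcr) 0 else p[["v2"]] - p[["d6"]] * GPCR,
    CRHR = p[["v3"]] - p[["d7"]] * CRHR,
    GR = p[["ktl2"]] * mGR + FF - p[["d8"]] * GR,
    GRCOR2_nu = p[["k2in"]] * D_cyt - p[["k2ex"]] * D_nu - p[["d9"]] * D_nu,
    mPOMC = vni * p[["ktrs1"]] * pmPOMC - p[["d10"]] * mPOMC,
    mGR = vni * p[["ktrs2"]] * pmGR - p[["d11"]] * mGR,
    TFs_in = vni * p[["k3ex"]] * TFs_nu - p[["k3in"]] * TFs_in -
      p[["d12"]] * TFs_in + tf_prod,
    TFs_nu = p[["k3in"]] * TFs_in - p[["k3ex"]] * TFs_nu -
      p[["d13"]] * TFs_nu,
    pmPOMC = -p[["ktrs1"]] * pmPOMC + p[["v5"]] - p[["d14"]] * pmPOMC +
      p[["v6"]] * TFs_nu / (p[["K7"]] * (1 + D_nu / p[["K8"]]) + TFs_nu),
    pmGR = -p[["ktrs2"]] * pmGR + p[["v7"]] + gr_auto - p[["d15"]] * pmGR
  )
  d
}

#' Right-hand side of the parsimonious 4-state reference model
#'
#' The cortisol-GR complex is in fast equilibrium, `[COR-GR] = COR * GR`.
#'
#' @param t time (ignored; autonomous system).
#' @param state state vector `(CRH, ACTH, GR, COR)`.
#' @param params parameter vector from [parsimonious_params()].
#' @param stress dimensionless stress input (>= 0).
#' @return vector of 4 time derivatives, named as [PARS_STATE_NAMES].
#' @export
rhs_parsimonious <- function(t, state, params, stress = 0) {
  if (length(state) != 4L) stop("state must have length 4")
  if (any(!is.finite(abs(state)))) stop("non-finite state")
  if (is.numeric(stress) && stress < 0) stop("stress must be >= 0")
  p <- unclass(params)
  s <- if (is.null(names(state))) {
    stats::setNames(as.vector(state), PARS_STATE_NAMES)
  } else state[PARS_STATE_NAMES]
  CRH <- s[["CRH"]]; ACTH <- s[["ACTH"]]; GR <- s[["GR"]]; COR <- s[["COR"]]
  CG <- COR * GR
  c(
    CRH = (p[["kc"]] + stress) / (1 + COR / p[["ki1"]]) - p[["kcd"]] * CRH,
    ACTH = p[["ka"]] * CRH / (1 + CG / p[["ki2"]]) - p[["kad"]] * ACTH,
    GR = p[["kr"]] * CG * CG / (p[["k"]] + CG * CG) + p[["kcr"]] -
      p[["krd"]] * GR,
    COR = p[["ko"]] * ACTH - p[["kod"]] * COR
  )
}

.knockout_flags <- function(knockout) {
  if (is.null(knockout)) return(list(gpcr = FALSE, crhfb = FALSE, grloop = FALSE))
  if (inherits(knockout, "hpa_model")) return(knockout$knockout)
  stopifnot(is.list(knockout))
  list(
    gpcr = isTRUE(knockout$gpcr),
    crhfb = isTRUE(knockout$crhfb),
    grloop = isTRUE(knockout$grloop)
  )
}
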