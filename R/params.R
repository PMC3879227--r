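#' Parameter names of the extended model
#'
#' Canonical order: compartment volumes, transport/diffusion constants,
#' degradation rates, receptor/complex dissociation constants,
#' Michaelis-Menten constants, limiting/production rates, and the Hill
#' coefficient of the CRHR-driven transcription-factor production.
#'
#' @format Character vector of length 51.
#' @export
PARAM_NAMES <- c(
  "V_in", "V_ex", "V_nu",
  "kdiff1", "k1ex", "k2in", "k2ex", "k3in", "k3ex",
  paste0("d", 1:15),
  "kGRC", "kGRdim", "kCRC", "kGC2",
  "K1", "K3", "K4", "K5", "K6", "K7", "K8", "K9",
  paste0("v", 1:8), "ks", "ksb",
  "ktl1", "ktl2", "ktrs1", "ktrs2",
  "h"
)

#' Parameters held fixed during fitting and continuation
#'
#' The compartment volumes are phenomenological and fixed; the Hill
#' coefficient `h` is a structural choice (default 2); `ksb` is the basal
#' hypothalamic drive folded into the stress input description. The
#' remaining 46 entries form the free parameter vector `q`.
#' @format Character vector.
#' @export
FIXED_PARAMS <- c("V_in", "V_ex", "V_nu", "h", "ksb")

#' Names of the 46 free model parameters
#' @format Character vector of length 46.
#' @export
FREE_PARAMS <- setdiff(PARAM_NAMES, FIXED_PARAMS)

#' Construct a parameter set for the extended model
#'
#' Returns the package's nominal anterior-pituitary parameter set, with any
#' component overridden by name. Units: first-order rates and
#' transport/diffusion constants in 1/min; production/limiting rates in
#' nM/min (`v2`, `v3` receptor production; `v5`-`v8` transcription; `ks`
#' CRH production scale; `v1`, `v4` Michaelis-Menten limiting rates);
#' dissociation constants `kGRC`, `kGRdim`, `kCRC` in nM and `kGC2` in nM^2
#' (two cortisol ligands bind the GPCR cooperatively); Michaelis constants
#' `K*` in nM (`K5` in nM^2 units via the GPCR complex); volumes are
#' dimensionless relative volumes; `h` and `ksb` dimensionless.
#'
#' @param ... named overrides of entries in [PARAM_NAMES].
#' @param base optional parameter vector to start from instead of the
#'   nominal set.
#' @return Named numeric vector of class `"hpa_params"`.
#' @examples
#' p <- extended_params(kdiff1 = 0.1)
#' @export
extended_params <- function(..., base = NULL) {
  p <- if (is.null(base)) .nominal_params() else unclass(base)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), PARAM_NAMES)
    if (length(bad))
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- as.numeric(unlist(dots))
  }
  structure(p, class = "hpa_params")
}

# Nominal in-vivo anterior pituitary parameter set (package default).
# Magnitudes chosen for hormone concentrations of order 1-100 nM and the
# genomic/non-genomic time-scale separation discussed in the vignette.
.nominal_params <- function() {
  c(
    V_in = 1, V_ex = 1, V_nu = 1,
    kdiff1 = 0.2, k1ex = 1, k2in = 0.5, k2ex = 0.05, k3in = 0.2, k3ex = 0.05,
    d1 = 0.05, d2 = 0.1, d3 = 0.05, d4 = 0.05, d5 = 0.02,
    d6 = 0.01, d7 = 0.01, d8 = 0.02, d9 = 0.05, d10 = 0.05,
    d11 = 0.05, d12 = 0.05, d13 = 0.05, d14 = 0.1, d15 = 0.1,
    kGRC = 30, kGRdim = 20, kCRC = 5, kGC2 = 3000,
    K1 = 10, K3 = 20, K4 = 5, K5 = 20, K6 = 4, K7 = 10, K8 = 10, K9 = 10,
    v1 = 5, v2 = 0.1, v3 = 0.1, v4 = 1, v5 = 0.01, v6 = 1, v7 = 0.01, v8 = 0.5,
    ks = 10, ksb = 0.1,
    ktl1 = 0.5, ktl2 = 0.5, ktrs1 = 0.2, ktrs2 = 0.2,
    h = 2
  )
}

#' Validate an extended parameter set
#'
#' All entries must be strictly positive, `h >= 1`; `ksb >= 0`.
#'
#' @param params parameter vector as from [extended_params()].
#' @return `params`, invisibly; errors on violation.
#' @export
validate_params <- function(params) {
  p <- as_params(params)
  if (any(!is.finite(p))) stop("non-finite parameter value(s)")
  strict <- setdiff(PARAM_NAMES, "ksb")
  if (any(p[strict] <= 0))
    stop("parameters must be strictly positive: ",
         paste(strict[p[strict] <= 0], collapse = ", "))
  if (p["ksb"] < 0) stop("ksb must be >= 0")
  if (p["h"] < 1) stop("Hill coefficient h must be >= 1")
  invisible(params)
}

as_params <- function(params) {
  p <- unclass(params)
  if (is.list(p)) p <- unlist(p)
  if (is.null(names(p))) {
    if (length(p) != length(PARAM_NAMES))
      stop("unnamed parameter vector must have length ", length(PARAM_NAMES))
    names(p) <- PARAM_NAMES
    return(p)
  }
  missing <- setdiff(PARAM_NAMES, names(p))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  p[PARAM_NAMES]
}

#' Derived nuclear-export volume factor
#'
#' `kbar = V_nu / (2 V_in)`; derived, never stored.
#' @param params parameter vector.
#' @return scalar.
#' @export
kbar <- function(params) {
  p <- as_params(params)
  unname(p["V_nu"] / (2 * p["V_in"]))
}

#' Tabulate model parameters and reconcile the free-parameter count
#'
#' Classifies every model parameter by mechanistic role and marks the fixed
#' ones (volumes, Hill coefficient, basal-drive constant). The remaining
#' free parameters form the length-46 vector estimated during fitting.
#'
#' @return data.frame with columns `name`, `role`, `units`, `free`.
#' @examples
#' sum(param_table()$free)  # 46
#' @export
param_table <- function() {
  role <- c(
    rep("compartment volume", 3),
    rep("transport/diffusion", 6),
    rep("degradation", 15),
    rep("complex dissociation", 4),
    rep("Michaelis constant", 8),
    "adrenal cortisol limiting rate", "GPCR production", "CRHR production",
    "TFs production limiting rate", "POMC basal transcription",
    "POMC regulated transcription", "GR basal transcription",
    "GR regulated transcription",
    "CRH production scale", "basal hypothalamic drive",
    "POMC translation", "GR translation",
    "POMC mRNA nuclear export", "GR mRNA nuclear export",
    "Hill coefficient"
  )
  units <- c(
    rep("-", 3), rep("1/min", 6), rep("1/min", 15),
    "nM", "nM", "nM", "nM^2",
    "nM", "nM", "nM", "nM^2", "nM", "nM", "nM", "nM",
    rep("nM/min", 8), "nM/min", "-",
    rep("1/min", 4), "-"
  )
  data.frame(
    name = PARAM_NAMES,
    role = role,
    units = units,
    free = !(PARAM_NAMES %in% FIXED_PARAMS),
    stringsAsFactors = FALSE
  )
}

#' Parameters of the parsimonious 4-state model
#'
#' @param ... named overrides of the default rate constants.
#' @return Named numeric vector of class `"hpa_pars_params"` with the 12
#'   rate/affinity constants of the reference model.
#' @export
parsimonious_params <- function(...) {
  p <- c(
    kc = 1, ki1 = 1, kcd = 0.5, ka = 1, ki2 = 1, kad = 0.5,
    kr = 1, k = 1, kcr = 0.05, krd = 0.5, ko = 1, kod = 0.5
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad))
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- as.numeric(unlist(dots))
  }
  if (any(p <= 0)) stop("parsimonious parameters must be strictly positive")
  structure(p, class = "hpa_pars_params")
}

#' Write a parameter set to JSON
#'
#' Flat name-to-value map; decimal literals survive a read/write round trip.
#'
#' @param params parameter vector.
#' @param path output file path.
#' @export
write_params_json <- function(params, path) {
  p <- as.list(as_params(params))
  jsonlite::write_json(p, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a parameter set from JSON
#'
#' @param path JSON file written by [write_params_json()] (any flat
#'   name/value map covering [PARAM_NAMES]).
#' @return parameter vector of class `"hpa_params"`.
#' @export
read_params_json <- function(path) {
  p <- unlist(jsonlite::read_json(path))
  extended_params(base = as_params(p))
}
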