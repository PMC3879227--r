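#' State variables of the extended pituitary HPA model
#'
#' The extended model tracks 15 concentrations (all in nM): extracellular
#' cortisol (`COR_ex`), hypothalamic CRH (`CRH`), extracellular ACTH
#' (`ACTH_ex`), free cytoplasmic cortisol (`COR_in`), vesicular/intracellular
#' ACTH (`ACTH_in`), the membrane glucocorticoid receptor (`GPCR`), the CRH
#' membrane receptor (`CRHR`), free cytoplasmic glucocorticoid receptor
#' (`GR`), the nuclear dimerised GR-cortisol complex (`GRCOR2_nu`),
#' cytoplasmic POMC and GR mRNA (`mPOMC`, `mGR`), cytoplasmic and nuclear
#' CRH-induced transcription factors (`TFs_in`, `TFs_nu`) and nuclear POMC
#' and GR pre-mRNA (`pmPOMC`, `pmGR`).
#'
#' @format Character vector of length 15 giving the canonical state order.
#' @export
STATE_NAMES <- c(
  "COR_ex", "CRH", "ACTH_ex", "COR_in", "ACTH_in",
  "GPCR", "CRHR", "GR", "GRCOR2_nu", "mPOMC",
  "mGR", "TFs_in", "TFs_nu", "pmPOMC", "pmGR"
)

#' State variables of the parsimonious 4-state reference model
#'
#' @format Character vector of length 4.
#' @export
PARS_STATE_NAMES <- c("CRH", "ACTH", "GR", "COR")

#' Names of the extracellular species (dose-administrable)
#' @keywords internal
EXTRACELLULAR_STATES <- c("COR_ex", "CRH", "ACTH_ex")

#' Construct a state vector for the extended model
#'
#' Unspecified components default to 0 nM.
#'
#' @param ... named concentrations in nM, a subset of [STATE_NAMES].
#' @param .values optional full-length numeric vector (named or in canonical
#'   order) used instead of `...`.
#' @return Named numeric vector of length 15 in canonical order.
#' @examples
#' extended_state(CRH = 10, GPCR = 5)
#' @export
extended_state <- function(..., .values = NULL) {
  x <- stats::setNames(numeric(length(STATE_NAMES)), STATE_NAMES)
  if (!is.null(.values)) {
    if (length(.values) != length(STATE_NAMES))
      stop("`.values` must have length ", length(STATE_NAMES))
    if (!is.null(names(.values))) {
      check_state_names(names(.values))
      x[names(.values)] <- as.numeric(.values)
    } else {
      x[] <- as.numeric(.values)
    }
  }
  dots <- list(...)
  if (length(dots)) {
    check_state_names(names(dots))
    x[names(dots)] <- as.numeric(unlist(dots))
  }
  x
}

#' Construct a state vector for the parsimonious model
#'
#' @param ... named concentrations, a subset of [PARS_STATE_NAMES].
#' @return Named numeric vector of length 4.
#' @export
parsimonious_state <- function(...) {
  x <- stats::setNames(numeric(length(PARS_STATE_NAMES)), PARS_STATE_NAMES)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), PARS_STATE_NAMES)
    if (length(bad)) stop("unknown state name(s): ", paste(bad, collapse = ", "))
    x[names(dots)] <- as.numeric(unlist(dots))
  }
  x
}

check_state_names <- function(nm) {
  if (is.null(nm) || any(!nzchar(nm)))
    stop("all state components must be named")
  bad <- setdiff(nm, STATE_NAMES)
  if (length(bad))
    stop("unknown state name(s): ", paste(bad, collapse = ", "),
         "; valid names are: ", paste(STATE_NAMES, collapse = ", "))
  invisible(nm)
}

as_state <- function(state, names = STATE_NAMES) {
  if (length(state) != length(names))
    stop("state must have length ", length(names), ", got ", length(state))
  state <- as.numeric(state)
  names(state) <- names
  state
}
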