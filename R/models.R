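#' Model variants of the HPA network
#'
#' A model variant bundles the kind of right-hand side (extended 15-state
#' or parsimonious 4-state) with optional pathway knockouts. Variants are
#' addressable by name:
#' \describe{
#'   \item{`extended`}{full 15-state pituitary cell model}
#'   \item{`parsimonious`}{4-state reference model}
#'   \item{`extended-gpcr`}{extended model with the membrane glucocorticoid
#'     receptor pathway knocked out}
#'   \item{`extended-crhfb`}{extended model without the genomic CRH
#'     feedback (TFs production decoupled from the CRHR-CRH complex)}
#'   \item{`extended-grloop`}{extended model without the GR autocatalytic
#'     transcription loop}
#' }
#'
#' @param id one of the variant names above.
#' @return object of class `"hpa_model"`: list with elements `id`, `kind`,
#'   `knockout` (logical flags) and `removed` (documentation of removed
#'   terms).
#' @export
hpa_model <- function(id = c("extended", "parsimonious", "extended-gpcr",
                             "extended-crhfb", "extended-grloop")) {
  id <- match.arg(id)
  base <- structure(list(
    id = "extended", kind = "extended",
    knockout = list(gpcr = FALSE, crhfb = FALSE, grloop = FALSE),
    removed = character(0)
  ), class = "hpa_model")
  switch(id,
    "extended" = base,
    "parsimonious" = structure(list(
      id = "parsimonious", kind = "parsimonious",
      knockout = list(gpcr = FALSE, crhfb = FALSE, grloop = FALSE),
      removed = character(0)
    ), class = "hpa_model"),
    "extended-gpcr" = apply_knockout("gpcr_pathway"),
    "extended-crhfb" = apply_knockout("crh_genomic_feedback"),
    "extended-grloop" = apply_knockout("gr_autocatalytic_loop")
  )
}

#' Apply an in-silico pathway knockout to the extended model
#'
#' Knockouts eliminate the corresponding equations/terms rather than just
#' zeroing an initial value:
#' \describe{
#'   \item{`gpcr_pathway`}{the GPCR balance equation is removed (its
#'     derivative is frozen) and the GPCR-cortisol complex is forced to 0
#'     everywhere, so ACTH release loses its non-genomic inhibition.}
#'   \item{`crh_genomic_feedback`}{the Hill-type TFs production term driven
#'     by the CRHR-CRH complex is removed, decoupling TFs production from
#'     CRH.}
#'   \item{`gr_autocatalytic_loop`}{the dimer-enhanced GR transcription
#'     term is removed, leaving only basal GR transcription.}
#' }
#'
#' @param name knockout identifier, one of `"gpcr_pathway"`,
#'   `"crh_genomic_feedback"`, `"gr_autocatalytic_loop"`.
#' @return `"hpa_model"` variant recording the removed terms.
#' @export
apply_knockout <- function(name) {
  valid <- c("gpcr_pathway", "crh_genomic_feedback", "gr_autocatalytic_loop")
  if (!name %in% valid)
    stop("unknown knockout '", name, "'; valid knockouts: ",
         paste(valid, collapse = ", "))
  ko <- list(gpcr = FALSE, crhfb = FALSE, grloop = FALSE)
  removed <- switch(name,
    gpcr_pathway = {
      ko$gpcr <- TRUE
      c("d[GPCR]/dt balance equation",
        "GPCR_COR2 complex (forced to 0 in the ACTH release denominator)")
    },
    crh_genomic_feedback = {
      ko$crhfb <- TRUE
      "v4 Hill production of TFs_in driven by CRHR_CRH"
    },
    gr_autocatalytic_loop = {
      ko$grloop <- TRUE
      "v8 dimer-enhanced term in the pmGR transcription equation"
    }
  )
  structure(list(
    id = switch(name, gpcr_pathway = "extended-gpcr",
                crh_genomic_feedback = "extended-crhfb",
                gr_autocatalytic_loop = "extended-grloop"),
    kind = "extended",
    knockout = ko,
    removed = removed
  ), class = "hpa_model")
}

#' @export
print.hpa_model <- function(x, ...) {
  cat("<hpa_model> ", x$id, " (", x$kind, ")\n", sep = "")
  if (length(x$removed)) {
    cat("removed terms:\n")
    for (r in x$removed) cat("  - ", r, "\n", sep = "")
  }
  invisible(x)
}

#' Evaluate the right-hand side of a model variant
#'
#' @param model `"hpa_model"` object or variant name.
#' @param t time (min).
#' @param state state vector of the variant's dimension.
#' @param params parameter vector matching the variant kind.
#' @param stress dimensionless stress input.
#' @return vector of time derivatives.
#' @export
model_rhs <- function(model, t, state, params, stress = 0) {
  model <- as_model(model)
  if (model$kind == "parsimonious") {
    rhs_parsimonious(t, state, params, stress)
  } else {
    rhs_extended(t, state, params, stress, knockout = model$knockout)
  }
}

as_model <- function(model) {
  if (inherits(model, "hpa_model")) return(model)
  if (is.character(model) && length(model) == 1L) return(hpa_model(model))
  stop("`model` must be an hpa_model or a variant name")
}

model_state_names <- function(model) {
  if (as_model(model)$kind == "parsimonious") PARS_STATE_NAMES else STATE_NAMES
}
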