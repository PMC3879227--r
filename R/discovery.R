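# Centres of the default log-space search boxes, one per regime family.
# These encode the package's mechanistic prior for where each behaviour
# lives (see the methods vignette): the hypercortisolism switch needs an
# early-saturating GR autocatalytic loop with strong nuclear dimer
# consumption and an active dimer->POMC repression channel; the
# hypocortisolism switch a slower, high-capacity GR loop; the oscillatory
# regime the same collapse machinery tuned into its unstable-focus range.
.regime_centers <- list(
  fold_bistable_hyper = c(
    K9 = 0.08, v8 = 1.3, v7 = 0.0027, d9 = 0.27, k2in = 2.5, k2ex = 0.010,
    kGRC = 7.9, kGRdim = 1.7, K8 = 1.8, v6 = 3.8, K7 = 1.25, v4 = 2.4,
    K6 = 2.1, kCRC = 15, K4 = 4.7, ks = 6.4, K3 = 19, d2 = 0.28,
    v1 = 24, K1 = 69, kdiff1 = 0.63, d4 = 0.040, d8 = 0.034,
    ktl2 = 0.28, d1 = 0.14
  ),
  hopf_oscillatory = c(
    K9 = 0.087, v8 = 0.53, v7 = 0.0061, d9 = 0.68, k2in = 2.8,
    k2ex = 0.019, kGRC = 3.2, kGRdim = 3.2, K8 = 2.5, v6 = 1.1,
    K7 = 1.8, v4 = 2.2, K6 = 2.6, kCRC = 36, K4 = 4.4, ks = 3.9,
    K3 = 14, d2 = 0.15, v1 = 9.7, K1 = 49, kdiff1 = 0.70, d4 = 0.036,
    d8 = 0.076, ktl2 = 0.33, d1 = 0.028
  ),
  fold_bistable_hypo = c(
    kGRC = 5.3, kGRdim = 4.7, k2in = 0.11, d9 = 0.16, v8 = 1.0,
    K9 = 6.5, v7 = 0.0023, ktl2 = 0.19, K8 = 1.9, v4 = 1.3, K6 = 4.0,
    v6 = 0.84, K7 = 12, kCRC = 170, K4 = 6.8, ks = 6.2, K3 = 15,
    v1 = 1.9, K1 = 30, kdiff1 = 0.14, d4 = 0.031, kGC2 = 1500
  )
)

.default_bounds <- function(kind, spread = 2.5) {
  ctr <- .regime_centers[[kind]]
  stats::setNames(lapply(ctr, function(v) c(v / spread, v * spread)),
                  names(ctr))
}

.regime_base <- function(kind) {
  p <- as_params(extended_params())
  ctr <- .regime_centers[[kind]]
  p[names(ctr)] <- ctr
  structure(p, class = "hpa_params")
}

#' Define a dynamic-regime search target
#'
#' Targets describe the qualitative behaviour sought in parameter space:
#' \describe{
#'   \item{`fold_bistable_hypo`}{an irreversible bistable switch whose
#'     branch reached by increasing stress carries a *lower* cortisol level
#'     (hypocortisolism), with the return limit point below basal stress.}
#'   \item{`fold_bistable_hyper`}{the inverted alignment: the branch
#'     reached past the fold carries a *higher* cortisol level
#'     (hypercortisolism), again with the return limit point below basal.}
#'   \item{`hopf_oscillatory`}{a Hopf point on the equilibrium branch with
#'     a verified sustained limit cycle.}
#' }
#' Each target carries a log-space search box over an influential parameter
#' subset (parameters outside the box stay at the nominal set); the default
#' boxes are part of the package's search design and are documented in the
#' methods vignette.
#'
#' @param kind target kind (see above).
#' @param basal basal stress level on the fictive scale (default 0.1).
#' @param model model variant searched (default `"extended"`; knockout
#'   variants allow the in-silico negative-result experiments).
#' @param bounds named list of length-2 numeric ranges overriding the
#'   default search box.
#' @param base_params centre/complement of the search box (default nominal).
#' @return object of class `"regime_target"`.
#' @export
regime_target <- function(kind = c("fold_bistable_hypo",
                                   "fold_bistable_hyper",
                                   "hopf_oscillatory"),
                          basal = 0.1, model = "extended", bounds = NULL,
                          base_params = NULL) {
  kind <- match.arg(kind)
  if (basal < 0 || basal > 1) stop("basal must lie in [0, 1]")
  if (is.null(bounds)) bounds <- .default_bounds(kind)
  bad <- setdiff(names(bounds), PARAM_NAMES)
  if (length(bad)) stop("unknown parameter(s) in bounds: ",
                        paste(bad, collapse = ", "))
  if (any(vapply(bounds, function(b) b[1] <= 0 || b[2] < b[1], logical(1))))
    stop("bounds must be positive with lo <= hi")
  if (is.null(base_params)) base_params <- .regime_base(kind)
  structure(list(kind = kind, basal = basal, model = as_model(model),
                 bounds = bounds, base_params = base_params),
            class = "regime_target")
}

#' Verify a parameter set against a regime target
#'
#' Runs a full stress continuation (and limit-cycle detection for Hopf
#' targets) and checks the target's constraints. Pure function of its
#' inputs; returns `ok = FALSE` with diagnostics on any failure.
#'
#' @param params parameter vector.
#' @param target a [regime_target()].
#' @param stress_range continuation interval.
#' @return list with `ok`, `classification`, `branch`, and (for Hopf
#'   targets) `cycle`.
#' @export
verify_regime <- function(params, target, stress_range = c(0, 1)) {
  br <- tryCatch(
    continue_equilibria(params, stress_range, model = target$model),
    error = function(e) NULL)
  if (is.null(br))
    return(list(ok = FALSE, classification = NULL, branch = NULL,
                reason = "continuation failed"))
  cs <- classify_switch(br, basal_stress = target$basal)
  if (target$kind == "hopf_oscillatory") {
    if (!length(br$hopf_points))
      return(list(ok = FALSE, classification = cs, branch = br,
                  reason = "no Hopf point"))
    S_h <- br$hopf_points[[1]]$stress
    # probe for a sustained cycle around the located Hopf point
    probes <- unique(pmax(0, c(S_h, S_h * c(1.05, 0.95), target$basal)))
    cyc <- NULL
    for (S in probes) {
      lc <- tryCatch(limit_cycle(params, S, model = target$model),
                     error = function(e) NULL)
      if (!is.null(lc) && lc$sustained) { cyc <- lc; cyc$stress <- S; break }
    }
    return(list(ok = !is.null(cyc), classification = cs, branch = br,
                cycle = cyc,
                reason = if (is.null(cyc)) "no sustained oscillation"))
  }
  want <- if (target$kind == "fold_bistable_hypo") "hypo" else "hyper"
  ok <- cs$kind == "irreversible_bistable" && cs$orientation == want &&
    !is.na(cs$S1) && cs$S1 > target$basal && cs$S2 < target$basal
  list(ok = ok, classification = cs, branch = br,
       reason = if (!ok) paste0("classified ", cs$kind, "/", cs$orientation))
}

# graded objective used to rank and refine candidates: 0 iff verified-like
# on the probe continuation; smooth eigenvalue terms guide descent.
.regime_score <- function(params, target, probe_steps = 350) {
  br <- tryCatch(
    continue_equilibria(params, c(0, 1), model = target$model,
                        max_steps = probe_steps, ds_max = 0.3),
    error = function(e) NULL)
  if (is.null(br)) return(50)
  cs <- classify_switch(br, basal_stress = target$basal)
  min_abs_re <- vapply(br$eigenvalues, function(ev) min(abs(Re(ev))),
                       numeric(1))
  if (target$kind == "hopf_oscillatory") {
    re_pair <- br$max_re_pair
    if (all(is.na(re_pair))) return(10)
    m <- max(re_pair, na.rm = TRUE)
    # past criticality: reward margin; before: squared distance to zero
    if (m > 0) return(-min(m, 1))
    return(m^2 / max(abs(re_pair), na.rm = TRUE)^2 + 0.1)
  }
  want <- if (target$kind == "fold_bistable_hypo") "hypo" else "hyper"
  if (cs$kind == "irreversible_bistable" && cs$orientation == want &&
      cs$S1 > target$basal && cs$S2 < target$basal) {
    # verified on the probe: reward fold separation
    return(-(min(cs$S1 - target$basal, target$basal - cs$S2)))
  }
  pen <- 0
  if (length(br$limit_points) == 0) {
    # smooth drive towards a fold: squared smallest-magnitude eigenvalue
    pen <- 1 + min(min_abs_re)^2 / max(min_abs_re)^2
  } else if (cs$kind == "complex") {
    pen <- 0.8
  } else {
    if (cs$orientation != want) pen <- pen + 0.6
    if (!is.na(cs$S2) && cs$S2 >= target$basal)
      pen <- pen + 10 * (cs$S2 - target$basal + 0.01)^2
    if (!is.na(cs$S1) && cs$S1 <= target$basal)
      pen <- pen + 10 * (target$basal - cs$S1 + 0.01)^2
  }
  pen
}

#' Search parameter space for a dynamic regime
#'
#' Seeded multi-start search: a space-filling Latin hypercube sample of the
#' target's log-space box is screened with a probe continuation and scored
#' by a graded objective built from the Jacobian eigenvalues along the
#' branch (squared smallest-magnitude eigenvalue for fold targets, squared
#' real part of the least-damped complex pair for Hopf targets) plus hinge
#' penalties enforcing the limit-point position and branch-orientation
#' constraints. Candidates whose probe already satisfies the target are
#' verified with a full continuation (and limit-cycle detection); if none
#' verifies, the best starts are refined by Nelder-Mead descent on the
#' score before re-verification. Identical seed and budget reproduce the
#' identical result.
#'
#' @param target a [regime_target()].
#' @param n_starts Latin hypercube starts (default 60).
#' @param seed RNG seed.
#' @param n_refine starts refined by Nelder-Mead if screening alone fails.
#' @param refine_iters Nelder-Mead iterations per refined start.
#' @return object of class `"regime_result"`: list with `params`, `target`,
#'   `score`, `seed`, `classification`, `verified`.
#' @export
search_regime <- function(target, n_starts = 60, seed = 1, n_refine = 4,
                          refine_iters = 40) {
  set.seed(seed)
  nm <- names(target$bounds)
  lo <- log(vapply(target$bounds, `[`, numeric(1), 1))
  hi <- log(vapply(target$bounds, `[`, numeric(1), 2))
  X <- lhs::randomLHS(n_starts, length(nm))
  mk <- function(u) {
    p <- unclass(target$base_params)
    p[nm] <- exp(u)
    structure(p, class = "hpa_params")
  }
  us <- lapply(seq_len(n_starts), function(i) lo + X[i, ] * (hi - lo))
  scores <- vapply(us, function(u) .regime_score(mk(u), target), numeric(1))
  ord <- order(scores)
  trace <- data.frame(start = ord, score = scores[ord])
  # screening: verify candidates that already satisfied the probe
  for (i in ord[scores[ord] <= 0]) {
    v <- verify_regime(mk(us[[i]]), target)
    if (v$ok) {
      return(structure(list(params = mk(us[[i]]), target = target,
                            score = scores[i], seed = seed,
                            classification = v$classification,
                            cycle = v$cycle, verified = TRUE,
                            refined = FALSE, trace = trace),
                       class = "regime_result"))
    }
  }
  # refinement of the most promising starts
  for (i in ord[seq_len(min(n_refine, length(ord)))]) {
    o <- stats::optim(us[[i]], function(u) .regime_score(mk(u), target),
                      method = "Nelder-Mead",
                      control = list(maxit = refine_iters))
    v <- verify_regime(mk(o$par), target)
    if (v$ok) {
      return(structure(list(params = mk(o$par), target = target,
                            score = o$value, seed = seed,
                            classification = v$classification,
                            cycle = v$cycle, verified = TRUE,
                            refined = TRUE, trace = trace),
                       class = "regime_result"))
    }
  }
  stop("search_regime: no candidate verified the '", target$kind,
       "' target within the budget (best score ",
       format(min(scores)), ")")
}

#' @export
print.regime_result <- function(x, ...) {
  cat("<regime_result>", x$target$kind, "| seed", x$seed,
      "| score", format(x$score), if (x$refined) "(refined)", "\n")
  if (!is.null(x$classification)) print(x$classification)
  invisible(x)
}
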