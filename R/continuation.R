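#' Pseudo-arclength continuation of equilibria in the stress parameter
#'
#' Traces the equilibrium curve `f(x, S) = 0` of a model through folds with
#' a secant-predictor / Newton-corrector pseudo-arclength scheme, starting
#' from the equilibrium at the lower end of `stress_range`. At every
#' accepted point the Jacobian eigenvalues are recorded; limit points are
#' bracketed by sign changes of `det(J)` along the branch (confirmed by the
#' smallest-magnitude eigenvalue) and located by bisection to a stress
#' tolerance of 1e-6; Hopf candidates are bracketed by sign changes of the
#' largest real part over complex eigenvalue pairs.
#'
#' @param params parameter vector.
#' @param stress_range numeric length-2, continuation interval (default
#'   `c(0, 1)` on the fictive stress scale).
#' @param model model variant.
#' @param start_guess optional state guess for the first equilibrium;
#'   default: relax the default guess by integration at the starting
#'   stress.
#' @param ds0 initial arclength step (dimensionless, default 0.05).
#' @param ds_max,ds_min step bounds.
#' @param max_steps maximum number of continuation steps.
#' @param tol corrector residual tolerance.
#' @return object of class `"hpa_branch"`: list with `stress` (vector),
#'   `states` (matrix), `stable` (logical), `det_sign`, `max_re_pair`,
#'   `limit_points` (data.frame `stress` + state matrix rows),
#'   `hopf_points`, `complete` (logical: covered the range without
#'   step-size underflow).
#' @export
continue_equilibria <- function(params, stress_range = c(0, 1),
                                model = "extended", start_guess = NULL,
                                ds0 = 0.05, ds_max = 0.4, ds_min = 1e-8,
                                max_steps = 1500, tol = 1e-10) {
  model <- as_model(model)
  S_min <- stress_range[1]; S_max <- stress_range[2]
  if (is.null(start_guess)) {
    start_guess <- settle_state(params, S_min, default_guess(params),
                                model = model)
  }
  eq0 <- find_equilibrium(params, S_min, start_guess, model = model,
                          tol = 1e-9)
  if (!eq0$converged)
    stop("no equilibrium found at the start of stress_range (residual ",
         format(eq0$residual), ")")
  n <- length(eq0$state)
  f <- function(x, S) as.numeric(model_rhs(model, 0, x, params, S))
  jac <- function(x, S) model_jacobian(x, params, S, model = model)
  fS <- function(x, S) {
    h <- 1e-6 * max(1, abs(S))
    (f(x, S + h) - f(x, pmax(S - h, 0))) / (h + min(h, S))
  }

  # fixed scaling for the arclength metric
  wx <- 1 / pmax(1, abs(eq0$state))
  wS <- 2

  x <- as.numeric(eq0$state); S <- S_min

  # initial tangent from dx/dS
  J <- jac(x, S)
  dxdS <- tryCatch(-solve(J, fS(x, S)), error = function(e) rep(0, n))
  tz <- c(dxdS, 1)
  tz <- tz / sqrt(sum((c(wx * dxdS, wS))^2))
  if (tz[n + 1] < 0) tz <- -tz

  stress_v <- S
  states_m <- matrix(x, nrow = 1)
  eigs <- list(eigen(J, only.values = TRUE)$values)

  corrector <- function(x_pred, S_pred, tz, z_prev, ds) {
    xk <- x_pred; Sk <- S_pred
    for (it in 1:12) {
      g <- f(xk, Sk)
      r2 <- sum(wx^2 * tz[1:n] * (xk - z_prev[1:n])) +
        wS^2 * tz[n + 1] * (Sk - z_prev[n + 1]) - ds
      if (max(abs(g)) < tol && abs(r2) < 1e-12)
        return(list(x = xk, S = Sk, ok = TRUE))
      Jk <- jac(xk, Sk)
      A <- rbind(cbind(Jk, fS(xk, Sk)),
                 c(wx^2 * tz[1:n], wS^2 * tz[n + 1]))
      dz <- tryCatch(solve(A, -c(g, r2)), error = function(e) NULL)
      if (is.null(dz)) return(list(ok = FALSE))
      xk <- xk + dz[1:n]; Sk <- Sk + dz[n + 1]
      if (!all(is.finite(xk)) || !is.finite(Sk)) return(list(ok = FALSE))
    }
    list(ok = FALSE)
  }

  ds <- ds0
  complete <- TRUE
  for (step in seq_len(max_steps)) {
    z_prev <- c(x, S)
    repeat {
      x_pred <- x + ds * tz[1:n]
      S_pred <- S + ds * tz[n + 1]
      res <- corrector(x_pred, S_pred, tz, z_prev, ds)
      if (res$ok) break
      ds <- ds / 2
      if (ds < ds_min) break
    }
    if (!res$ok) { complete <- FALSE; break }
    x_new <- res$x; S_new <- res$S
    # secant tangent for the next step
    dz <- c(x_new - x, S_new - S)
    nr <- sqrt(sum((wx * dz[1:n])^2) + (wS * dz[n + 1])^2)
    tz <- dz / nr
    x <- x_new; S <- S_new
    stress_v <- c(stress_v, S)
    states_m <- rbind(states_m, x)
    eigs[[length(eigs) + 1]] <- eigen(jac(x, S), only.values = TRUE)$values
    ds <- min(ds * 1.4, ds_max)
    if (S > S_max + 1e-9 || S < S_min - 1e-9) break
  }

  # det(J) = prod(eigenvalues): real since complex eigenvalues pair up
  det_sign <- vapply(eigs, function(ev) sign(Re(prod(ev))), numeric(1))
  stable <- vapply(eigs, function(ev) all(Re(ev) < 0), logical(1))
  max_re_pair <- vapply(eigs, function(ev) {
    c_idx <- abs(Im(ev)) > 1e-4
    if (any(c_idx)) max(Re(ev[c_idx])) else NA_real_
  }, numeric(1))

  # bisection refinement between consecutive points along the branch
  refine <- function(i, test_fun) {
    za <- c(states_m[i, ], stress_v[i])
    zb <- c(states_m[i + 1, ], stress_v[i + 1])
    fa <- test_fun(za)
    for (iter in 1:60) {
      zm_pred <- (za + zb) / 2
      dz <- zb - za
      nr <- sqrt(sum((wx * dz[1:n])^2) + (wS * dz[n + 1])^2)
      tzl <- dz / nr
      resm <- corrector(zm_pred[1:n], zm_pred[n + 1], tzl, za, nr / 2)
      if (!resm$ok) return(NULL)
      zm <- c(resm$x, resm$S)
      fm <- test_fun(zm)
      if (sign(fm) == sign(fa)) { za <- zm; fa <- fm } else zb <- zm
      if (abs(za[n + 1] - zb[n + 1]) < 1e-8 &&
          sqrt(sum((za - zb)^2)) < 1e-6) break
    }
    (za + zb) / 2
  }

  lp_test <- function(z) {
    ev <- eigen(jac(z[1:n], z[n + 1]), only.values = TRUE)$values
    sign(Re(prod(ev))) * min(abs(Re(ev)))
  }
  hopf_test <- function(z) {
    ev <- eigen(jac(z[1:n], z[n + 1]), only.values = TRUE)$values
    c_idx <- abs(Im(ev)) > 1e-4
    if (!any(c_idx)) return(NA_real_)
    max(Re(ev[c_idx]))
  }

  limit_points <- list(); hopf_points <- list()
  for (i in seq_len(length(stress_v) - 1)) {
    if (det_sign[i] * det_sign[i + 1] < 0) {
      z <- refine(i, lp_test)
      if (!is.null(z)) {
        ev <- eigen(jac(z[1:n], z[n + 1]), only.values = TRUE)$values
        limit_points[[length(limit_points) + 1]] <-
          list(stress = z[n + 1], state = stats::setNames(z[1:n],
               model_state_names(model)), index = i,
               min_abs_re = min(abs(Re(ev))))
      }
    }
    a <- max_re_pair[i]; b <- max_re_pair[i + 1]
    if (!is.na(a) && !is.na(b) && a * b < 0 &&
        det_sign[i] * det_sign[i + 1] > 0) {
      z <- refine(i, hopf_test)
      if (!is.null(z)) {
        ev <- eigen(jac(z[1:n], z[n + 1]), only.values = TRUE)$values
        c_idx <- abs(Im(ev)) > 1e-4
        pair <- ev[c_idx][which.max(Re(ev[c_idx]))]
        hopf_points[[length(hopf_points) + 1]] <-
          list(stress = z[n + 1], state = stats::setNames(z[1:n],
               model_state_names(model)), index = i,
               omega = abs(Im(pair)), re = Re(pair))
      }
    }
  }

  colnames(states_m) <- model_state_names(model)
  structure(list(
    stress = stress_v,
    states = states_m,
    stable = stable,
    det_sign = det_sign,
    max_re_pair = max_re_pair,
    eigenvalues = eigs,
    limit_points = limit_points,
    hopf_points = hopf_points,
    stress_range = stress_range,
    complete = complete,
    model = model$id
  ), class = "hpa_branch")
}

#' @export
print.hpa_branch <- function(x, ...) {
  cat("<hpa_branch> model =", x$model, "|", length(x$stress),
      "points, stress in [", round(min(x$stress), 4), ",",
      round(max(x$stress), 4), "]\n")
  cat("limit points: ", length(x$limit_points),
      if (length(x$limit_points))
        paste0("(S = ", paste(round(lp_stress(x), 5), collapse = ", "), ")"),
      "\n")
  cat("Hopf points:  ", length(x$hopf_points), "\n")
  if (!x$complete) cat("warning: branch incomplete (step-size underflow)\n")
  invisible(x)
}

lp_stress <- function(branch) {
  vapply(branch$limit_points, `[[`, numeric(1), "stress")
}

#' Write an equilibrium branch to CSV
#'
#' Columns: `arclength` (point index), `stress`, the state names,
#' `stability`, `is_LP`, `is_Hopf` (nearest branch point flags).
#' @param branch an `"hpa_branch"`.
#' @param path output path.
#' @export
write_branch_csv <- function(branch, path) {
  is_lp <- is_hopf <- rep(FALSE, length(branch$stress))
  for (lp in branch$limit_points) is_lp[lp$index] <- TRUE
  for (hp in branch$hopf_points) is_hopf[hp$index] <- TRUE
  df <- data.frame(arclength = seq_along(branch$stress) - 1L,
                   stress = branch$stress, branch$states,
                   stability = branch$stable, is_LP = is_lp,
                   is_Hopf = is_hopf, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Classify the switch behaviour of an equilibrium branch
#'
#' A branch with no limit points is monostable; with two limit points the
#' system is bistable for stress between the fold abscissas `S2 < S1`. The
#' switch is irreversible when the return limit point `S2` lies below the
#' basal stress level. Orientation: `hyper` when the stable branch reached
#' by increasing stress past `S1` carries a higher cortisol level than the
#' basal branch (inverted alignment of the cortisol steady-state branches),
#' `hypo` otherwise.
#'
#' @param branch an `"hpa_branch"` from [continue_equilibria()].
#' @param basal_stress basal stress level (default 0.1).
#' @return object of class `"switch_classification"`: list with `kind`
#'   (`monostable`, `reversible_bistable`, `irreversible_bistable`, or
#'   `complex`), `orientation` (`none`, `hypo`, `hyper`), `S1`, `S2`,
#'   `basal_stress`.
#' @export
classify_switch <- function(branch, basal_stress = 0.1) {
  lps <- lp_stress(branch)
  out <- list(kind = "monostable", orientation = "none",
              S1 = NA_real_, S2 = NA_real_, basal_stress = basal_stress,
              lp_stress = lps)
  if (length(lps) == 0) {
    class(out) <- "switch_classification"
    return(out)
  }
  if (length(lps) != 2) {
    out$kind <- "complex"
    class(out) <- "switch_classification"
    return(out)
  }
  S1 <- max(lps); S2 <- min(lps)
  out$S1 <- S1; out$S2 <- S2
  out$kind <- if (S2 < basal_stress) "irreversible_bistable" else
    "reversible_bistable"
  # branch segments: before the first fold index (basal branch) and after
  # the second fold index (branch reached by increasing stress past S1)
  idx1 <- branch$limit_points[[which.min(abs(vapply(branch$limit_points,
            `[[`, numeric(1), "stress") - S1))]]$index
  ord <- order(vapply(branch$limit_points, `[[`, numeric(1), "index"))
  first_idx <- branch$limit_points[[ord[1]]]$index
  last_idx <- branch$limit_points[[ord[2]]]$index
  Smid <- (S1 + S2) / 2
  cor_at <- function(idx_set) {
    s <- branch$stress[idx_set]; c_ex <- branch$states[idx_set, "COR_ex"]
    ok <- is.finite(s)
    if (sum(ok) < 2) return(mean(c_ex))
    stats::approx(s[ok], c_ex[ok], xout = Smid, rule = 2)$y
  }
  near <- cor_at(seq_len(first_idx))
  far <- cor_at(seq((last_idx + 1), length(branch$stress)))
  out$orientation <- if (far > near) "hyper" else "hypo"
  class(out) <- "switch_classification"
  out
}

#' @export
print.switch_classification <- function(x, ...) {
  cat("<switch_classification>", x$kind,
      if (x$orientation != "none") paste0("(", x$orientation, ")"), "\n")
  if (!is.na(x$S1))
    cat("  LP abscissas: S1 =", round(x$S1, 5), " S2 =", round(x$S2, 5),
        " basal =", x$basal_stress, "\n")
  invisible(x)
}

#' Dense-grid multi-start equilibrium scan
#'
#' Brute-force reference for the continuation: at every stress value of a
#' grid, Newton searches from many starting points (relaxed trajectories
#' plus log-space Latin hypercube draws) are run and distinct equilibria
#' are counted. Fold abscissas can then be read off as the grid intervals
#' where the number of equilibria changes.
#'
#' @param params parameter vector.
#' @param stress_grid vector of stress values.
#' @param model model variant.
#' @param n_starts random starts per stress value (default 12).
#' @param seed RNG seed for the start draws.
#' @return data.frame with columns `stress`, `n_equilibria`, `n_stable`,
#'   plus attribute `"equilibria"` (list of state matrices).
#' @export
equilibria_dense_scan <- function(params, stress_grid, model = "extended",
                                  n_starts = 12, seed = 1) {
  model <- as_model(model)
  set.seed(seed)
  n <- length(model_state_names(model))
  res <- data.frame(stress = stress_grid, n_equilibria = 0L, n_stable = 0L)
  all_eq <- vector("list", length(stress_grid))
  # reference scales for the random starts
  x_ref <- settle_state(params, stress_grid[1], default_guess(params),
                        model = model)
  lo <- log(pmax(x_ref, 1e-3) / 100); hi <- log(pmax(x_ref, 1e-3) * 100)
  draws <- lhs::randomLHS(max(n_starts - 2, 1), n)
  prev <- NULL
  for (k in seq_along(stress_grid)) {
    S <- stress_grid[k]
    # relax towards the attractors from well-separated initial states:
    # in a multistable regime different scalings land in different basins
    starts <- lapply(c(0.05, 1, 20), function(f)
      settle_state(params, S, pmax(x_ref * f, 1e-6), model = model,
                   t_end = 4000))
    if (!is.null(prev)) starts <- c(starts, lapply(seq_len(nrow(prev)),
                                                   function(i) prev[i, ]))
    for (i in seq_len(nrow(draws)))
      starts <- c(starts, list(exp(lo + draws[i, ] * (hi - lo))))
    found <- NULL; stab <- logical(0)
    for (g in starts) {
      eq <- tryCatch(find_equilibrium(params, S, g, model = model,
                                      tol = 1e-9, max_iter = 80),
                     error = function(e) NULL)
      if (is.null(eq) || !eq$converged) next
      xs <- eq$state
      if (is.null(found)) {
        found <- matrix(xs, nrow = 1); stab <- eq$stable
      } else {
        dup <- apply(found, 1, function(r)
          max(abs(r - xs) / pmax(1, abs(r))) < 1e-5)
        if (!any(dup)) { found <- rbind(found, xs); stab <- c(stab, eq$stable) }
      }
    }
    res$n_equilibria[k] <- if (is.null(found)) 0L else nrow(found)
    res$n_stable[k] <- sum(stab)
    all_eq[[k]] <- found
    prev <- found
  }
  attr(res, "equilibria") <- all_eq
  res
}
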