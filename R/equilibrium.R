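#' Jacobian of a model right-hand side
#'
#' Complex-step differentiation of the right-hand side with respect to the
#' state: column `j` is `Im(f(x + i h e_j)) / h` with `h = 1e-20`, which is
#' exact to machine precision for the rational arithmetic of the model.
#' A central finite-difference fallback (`method = "central"`) is provided
#' for cross-checking.
#'
#' @param state state vector (non-negative).
#' @param params parameter vector.
#' @param stress dimensionless stress input.
#' @param model model variant (default extended).
#' @param method `"complex"` (default) or `"central"`.
#' @return dense Jacobian matrix (n x n) with state names on both dims.
#' @export
model_jacobian <- function(state, params, stress = 0, model = "extended",
                           method = c("complex", "central")) {
  method <- match.arg(method)
  model <- as_model(model)
  n <- length(state)
  f <- function(x) model_rhs(model, 0, x, params, stress)
  J <- matrix(NA_real_, n, n)
  if (method == "complex") {
    h <- 1e-20
    for (j in seq_len(n)) {
      x <- as.complex(state)
      x[j] <- x[j] + h * 1i
      J[, j] <- Im(f(x)) / h
    }
  } else {
    for (j in seq_len(n)) {
      hj <- max(1e-7, 1e-7 * abs(state[j]))
      xp <- as.numeric(state); xm <- as.numeric(state)
      xp[j] <- xp[j] + hj; xm[j] <- xm[j] - hj
      J[, j] <- (f(xp) - f(xm)) / (2 * hj)
    }
  }
  if (any(!is.finite(J))) stop("non-finite entries in Jacobian")
  nm <- model_state_names(model)
  dimnames(J) <- list(nm, nm)
  J
}

#' Find an equilibrium of the model at fixed stress
#'
#' Damped Newton iteration on the right-hand side, performed in
#' log-concentration space to enforce positivity (states are floored at
#' 1e-12 nM, so equilibria with vanishing components are reached to within
#' the residual tolerance). The returned point carries the Jacobian
#' eigenvalues and a stability flag.
#'
#' @param params parameter vector.
#' @param stress dimensionless stress level.
#' @param guess initial state guess (finite, length of the model state).
#' @param model model variant.
#' @param tol residual tolerance on `max(abs(rhs))` (default 1e-10).
#' @param max_iter maximum Newton iterations.
#' @return object of class `"hpa_equilibrium"`: list with `stress`, `state`,
#'   `eigenvalues`, `stable`, `residual`, `converged`.
#' @export
find_equilibrium <- function(params, stress, guess, model = "extended",
                             tol = 1e-10, max_iter = 200) {
  model <- as_model(model)
  if (any(!is.finite(guess))) stop("guess must be finite")
  floor_c <- 1e-12
  x <- pmax(as.numeric(guess), floor_c)
  u <- log(x)
  f <- function(x) as.numeric(model_rhs(model, 0, x, params, stress))
  g <- f(x)
  res <- max(abs(g))
  settles <- 0L
  for (it in seq_len(max_iter)) {
    if (res < tol) break
    Jx <- model_jacobian(x, params, stress, model = model)
    Ju <- Jx * rep(x, each = length(x))  # J_x %*% diag(x)
    du <- tryCatch(-solve(Ju, g), error = function(e) NULL)
    if (is.null(du)) {
      # regularise near-singular Jacobians (e.g. at folds)
      du <- -solve(Ju + diag(1e-8 * max(abs(Ju)), length(x)), g)
    }
    # cap the log-space step to keep the iteration tame
    mx <- max(abs(du))
    if (mx > 4) du <- du * (4 / mx)
    lambda <- 1
    improved <- FALSE
    for (k in 1:30) {
      u_new <- u + lambda * du
      x_new <- exp(u_new)
      g_new <- f(x_new)
      if (all(is.finite(g_new)) && max(abs(g_new)) < res * (1 - 1e-4 * lambda)) {
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) {
      # pseudo-transient fallback: relax along the flow, then resume Newton
      if (settles < 3L) {
        settles <- settles + 1L
        x_try <- tryCatch(
          pmax(settle_state(params, stress, x, model = model,
                            t_end = 500 * 4^settles), floor_c),
          error = function(e) NULL)
        if (!is.null(x_try)) {
          g_try <- f(x_try)
          if (all(is.finite(g_try))) {
            x <- x_try; u <- log(x); g <- g_try
            res <- max(abs(g))
            next
          }
        }
      }
      break
    }
    u <- u_new; x <- x_new; g <- g_new
    res <- max(abs(g))
  }
  converged <- res < tol
  eig <- eigen(model_jacobian(x, params, stress, model = model),
               only.values = TRUE)$values
  structure(list(
    stress = stress,
    state = stats::setNames(x, model_state_names(model)),
    eigenvalues = eig,
    stable = all(Re(eig) < 0),
    residual = res,
    converged = converged
  ), class = "hpa_equilibrium")
}

#' @export
print.hpa_equilibrium <- function(x, ...) {
  cat("<hpa_equilibrium> stress =", format(x$stress),
      if (x$stable) "(stable)" else "(unstable)",
      " residual =", format(x$residual), "\n")
  print(round(x$state, 6))
  invisible(x)
}

# relax toward an attractor by integration, then return the end state
settle_state <- function(params, stress, init, model = "extended",
                         t_end = 2000) {
  traj <- integrate_model(model, init,
                          protocol = stress_protocol(baseline = stress),
                          t_grid = c(0, t_end), params = params)
  traj$states[nrow(traj$states), ]
}

#' Default initial guess for equilibrium searches
#'
#' Uses the decoupled receptor balances (`GPCR = v2/d6`, `CRHR = v3/d7`)
#' and order-of-magnitude hormone levels.
#' @param params parameter vector.
#' @return extended state vector.
#' @keywords internal
default_guess <- function(params) {
  p <- as_params(params)
  extended_state(
    COR_ex = 10, CRH = 1, ACTH_ex = 5, COR_in = 5, ACTH_in = 10,
    GPCR = p[["v2"]] / p[["d6"]], CRHR = p[["v3"]] / p[["d7"]],
    GR = 5, GRCOR2_nu = 1, mPOMC = 1, mGR = 1,
    TFs_in = 1, TFs_nu = 1, pmPOMC = 0.5, pmGR = 0.5
  )
}
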