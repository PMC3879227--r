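#' Define a stress protocol
#'
#' A piecewise-constant stress input: a baseline level plus non-overlapping
#' rectangular pulses.
#'
#' @param baseline baseline dimensionless stress level (default 0.1, the
#'   basal level on the fictive stress scale).
#' @param pulses data.frame with columns `t_start`, `t_end`, `level`
#'   (minutes / dimensionless), or NULL.
#' @param description free-text tag.
#' @return object of class `"stress_protocol"`.
#' @export
stress_protocol <- function(baseline = 0.1, pulses = NULL, description = "") {
  if (baseline < 0) stop("baseline stress must be >= 0")
  if (is.null(pulses)) {
    pulses <- data.frame(t_start = numeric(0), t_end = numeric(0),
                         level = numeric(0))
  }
  stopifnot(all(c("t_start", "t_end", "level") %in% names(pulses)))
  if (nrow(pulses)) {
    if (any(pulses$t_start >= pulses$t_end))
      stop("pulses must have t_start < t_end")
    if (any(pulses$level < 0)) stop("pulse levels must be >= 0")
    o <- order(pulses$t_start)
    pulses <- pulses[o, , drop = FALSE]
    if (nrow(pulses) > 1 &&
        any(pulses$t_start[-1] < pulses$t_end[-nrow(pulses)]))
      stop("pulses must be non-overlapping")
  }
  structure(list(baseline = baseline, pulses = pulses,
                 description = description),
            class = "stress_protocol")
}

#' Stress level of a protocol at given times
#'
#' @param protocol a [stress_protocol()].
#' @param t vector of times (min).
#' @return numeric vector of stress levels.
#' @export
stress_at <- function(protocol, t) {
  s <- rep(protocol$baseline, length(t))
  if (nrow(protocol$pulses)) {
    for (i in seq_len(nrow(protocol$pulses))) {
      idx <- t >= protocol$pulses$t_start[i] & t < protocol$pulses$t_end[i]
      s[idx] <- protocol$pulses$level[i]
    }
  }
  s
}

#' Define a dose administration event
#'
#' Doses are modelled as instantaneous jumps of an extracellular
#' concentration (bolus administration into the medium/blood).
#'
#' @param time administration time (min).
#' @param species one of the extracellular states `"COR_ex"`, `"CRH"`,
#'   `"ACTH_ex"`.
#' @param amount amount added (nM, >= 0).
#' @return object of class `"dose_event"`.
#' @export
dose_event <- function(time, species, amount) {
  if (!species %in% EXTRACELLULAR_STATES)
    stop("dose species must be one of: ",
         paste(EXTRACELLULAR_STATES, collapse = ", "))
  if (amount < 0) stop("dose amount must be >= 0")
  structure(list(time = time, species = species, amount = amount),
            class = "dose_event")
}

#' Read a protocol definition from YAML
#'
#' Schema: `baseline`, `pulses: [{t_start, t_end, level}]`,
#' `doses: [{time, species, amount_nM}]`.
#'
#' @param path YAML file.
#' @return list with elements `protocol` ([stress_protocol()]) and `doses`
#'   (list of [dose_event()]).
#' @export
read_protocol_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read protocol files")
  y <- yaml::read_yaml(path)
  pulses <- NULL
  if (length(y$pulses))
    pulses <- do.call(rbind, lapply(y$pulses, as.data.frame))
  doses <- lapply(y$doses, function(d)
    dose_event(d$time, d$species, d$amount_nM))
  list(protocol = stress_protocol(baseline = y$baseline %||% 0,
                                  pulses = pulses),
       doses = doses)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.pack_parms_ext <- function(params, knockout, stress) {
  p <- as_params(params)
  ko <- .knockout_flags(knockout)
  c(unname(p), as.numeric(ko$gpcr), as.numeric(ko$crhfb),
    as.numeric(ko$grloop), stress)
}

# integrate one constant-stress segment
.integrate_segment <- function(model, y0, times, params, stress,
                               rtol, atol, engine, maxsteps = 20000) {
  model <- as_model(model)
  if (length(times) == 1L) {
    out <- matrix(y0, nrow = 1)
    return(cbind(times, out))
  }
  if (engine == "C") {
    if (model$kind == "extended") {
      out <- deSolve::ode(
        y = unname(y0), times = times, func = "hpa_ext_derivs",
        parms = .pack_parms_ext(params, model, stress),
        dllname = "hpaxis", initfunc = "hpa_ext_init",
        method = "lsoda", rtol = rtol, atol = atol, maxsteps = maxsteps
      )
    } else {
      out <- deSolve::ode(
        y = unname(y0), times = times, func = "hpa_pars_derivs",
        parms = c(unname(unclass(params)[names(parsimonious_params())]),
                  stress),
        dllname = "hpaxis", initfunc = "hpa_pars_init",
        method = "lsoda", rtol = rtol, atol = atol, maxsteps = maxsteps
      )
    }
  } else {
    fr <- function(t, y, parms) list(model_rhs(model, t, y, params, stress))
    out <- deSolve::ode(y = unname(y0), times = times, func = fr,
                        parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol, maxsteps = 20000)
  }
  if (attr(out, "istate")[1] < 0 || nrow(out) < length(times))
    stop("integration failed on interval [", times[1], ", ",
         times[length(times)], "] min")
  unclass(out)
}

#' Integrate a model under a stress protocol with dose events
#'
#' Solves the stiff ODE system with `lsoda`, restarting the integrator at
#' every dose event (the dosed species jumps by the administered amount)
#' and at every discontinuity of the piecewise-constant stress input, so
#' events are handled exactly.
#'
#' @param model model variant (object or name).
#' @param init initial state vector.
#' @param protocol a [stress_protocol()]; for the parsimonious model the
#'   same stress input enters its CRH equation.
#' @param t_grid strictly increasing output time grid (min).
#' @param params parameter vector matching the model kind.
#' @param doses list of [dose_event()]s, all within the time range.
#' @param rtol,atol solver tolerances (defaults 1e-8 / 1e-10).
#' @param engine `"C"` (compiled, default) or `"R"` (reference
#'   implementation); both produce the same trajectories to solver
#'   tolerance.
#' @param maxsteps cap on internal solver steps per output interval.
#' @return object of class `"hpa_trajectory"`: list with `times`, `states`
#'   (matrix time x state), `model`, `protocol`.
#' @export
integrate_model <- function(model, init, protocol = stress_protocol(0),
                            t_grid, params, doses = list(),
                            rtol = 1e-8, atol = 1e-10, engine = "C",
                            maxsteps = 20000) {
  model <- as_model(model)
  if (inherits(doses, "dose_event")) doses <- list(doses)
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing")
  t0 <- t_grid[1]; t1 <- t_grid[length(t_grid)]
  dtimes <- vapply(doses, `[[`, numeric(1), "time")
  if (length(dtimes) && (any(dtimes < t0) || any(dtimes > t1)))
    stop("dose events must lie within the time grid")
  edges <- sort(unique(c(
    t0, t1, dtimes,
    protocol$pulses$t_start, protocol$pulses$t_end
  )))
  edges <- edges[edges >= t0 & edges <= t1]

  nm <- model_state_names(model)
  y <- as_state(init, nm)
  times_out <- numeric(0)
  states_out <- NULL

  for (i in seq_len(length(edges) - 1L)) {
    a <- edges[i]; b <- edges[i + 1L]
    # apply doses scheduled at the segment start
    for (d in doses) if (d$time == a) y[d$species] <- y[d$species] + d$amount
    seg_t <- sort(unique(c(a, t_grid[t_grid > a & t_grid < b], b)))
    stress <- stress_at(protocol, (a + b) / 2)
    out <- .integrate_segment(model, y, seg_t, params, stress,
                              rtol, atol, engine, maxsteps)
    y <- as_state(out[nrow(out), -1], nm)
    keep <- which(out[, 1] %in% t_grid)
    for (k in keep) {
      j <- match(out[k, 1], times_out)
      if (is.na(j)) {
        times_out <- c(times_out, out[k, 1])
        states_out <- rbind(states_out, out[k, -1, drop = FALSE])
      } else {
        # a dose at this instant: report the post-dose (right-limit) state
        states_out[j, ] <- out[k, -1]
      }
    }
  }
  colnames(states_out) <- nm
  structure(list(
    times = times_out,
    states = states_out,
    model = model$id,
    protocol = protocol$description
  ), class = "hpa_trajectory")
}

#' @export
print.hpa_trajectory <- function(x, ...) {
  cat("<hpa_trajectory> model =", x$model, "|", length(x$times),
      "time points on [", x$times[1], ",", x$times[length(x$times)], "] min\n")
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' Columns: `time_min`, then the state names.
#' @param traj an `"hpa_trajectory"`.
#' @param path output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time_min = traj$times, traj$states, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Parameter switch for in-vitro (cell culture) simulation
#'
#' In the dish there is neither hypothalamic CRH drive nor an adrenal
#' gland, so CRH production (`ks`) and adrenal cortisol production (`v1`)
#' are disabled; extracellular ACTH degradation `d3` can optionally be
#' switched off as well.
#'
#' @param params in-vivo parameter vector.
#' @param medium_degradation keep the medium ACTH degradation `d3`
#'   (default TRUE).
#' @return modified parameter vector.
#' @export
invitro_params <- function(params, medium_degradation = TRUE) {
  p <- as_params(params)
  p["ks"] <- 1e-12   # strictly positive placeholder; drive is off
  p["v1"] <- 1e-12
  if (!medium_degradation) p["d3"] <- 1e-12
  structure(p, class = "hpa_params")
}

#' Cell rest state before an in-vitro experiment
#'
#' Steady state of the cellular species with no CRH and no cortisol in the
#' medium (cells equilibrated for many hours before the experiment).
#'
#' @param params parameter vector (in-vitro switches applied internally).
#' @param model model variant.
#' @return extended state vector with zero extracellular hormones.
#' @export
rest_state <- function(params, model = "extended") {
  p <- invitro_params(params)
  init <- default_guess(p)
  init["COR_ex"] <- 0; init["CRH"] <- 0; init["ACTH_ex"] <- 0
  x <- settle_state(p, 0, init, model = model, t_end = 8000)
  eq <- find_equilibrium(p, 0, pmax(x, 1e-12), model = model, tol = 1e-9)
  st <- eq$state
  st[c("COR_ex", "CRH", "ACTH_ex")] <- 0
  st
}

#' Simulate an in-vitro dose experiment and read out extracellular ACTH
#'
#' Protocol `A`: 10 nM CRH administered at t = 0. Protocol `B`: 10 nM CRH
#' plus 100 nM cortisol at t = 0. The readout is the extracellular ACTH
#' concentration (the model counterpart of total ACTH in the cell medium).
#'
#' @param params parameter vector (in-vivo scale; in-vitro switches are
#'   applied via [invitro_params()] unless `invitro = FALSE`).
#' @param protocol_id `"A"` or `"B"`.
#' @param sample_times sampling times in minutes, within (0, 60].
#' @param init initial cell state; default [rest_state()] of `params`.
#' @param invitro apply the in-vitro switches (default TRUE).
#' @param full return the full trajectory instead of the ACTH readout.
#' @return numeric vector of ACTH_ex (nM) at `sample_times` (or a
#'   trajectory if `full = TRUE`).
#' @export
run_dose_experiment <- function(params, protocol_id = c("A", "B"),
                                sample_times = c(1, 2, 5, 10, 15, 20, 30, 45, 60),
                                init = NULL, invitro = TRUE, full = FALSE) {
  protocol_id <- match.arg(protocol_id)
  if (any(sample_times < 0) || any(sample_times > 60))
    stop("sample times must lie within [0, 60] min")
  p <- if (invitro) invitro_params(params) else as_params(params)
  if (is.null(init)) init <- rest_state(params)
  doses <- list(dose_event(0, "CRH", 10))
  if (protocol_id == "B")
    doses <- c(doses, list(dose_event(0, "COR_ex", 100)))
  t_grid <- sort(unique(c(0, seq(0, 60, by = 0.5), sample_times)))
  traj <- integrate_model("extended", init, stress_protocol(0), t_grid,
                          p, doses = doses)
  if (full) return(traj)
  idx <- match(sample_times, traj$times)
  unname(traj$states[idx, "ACTH_ex"])
}

#' Simulate a stress-pulse response from the pre-pulse equilibrium
#'
#' Starts at the stable equilibrium for the protocol baseline, applies the
#' protocol's stress pulses, and integrates long enough past the last pulse
#' for the system to settle on a (possibly different) stable equilibrium.
#'
#' @param params parameter vector.
#' @param protocol a [stress_protocol()] whose baseline is the basal stress.
#' @param horizon total simulated time (min); default 3000 past the last
#'   pulse.
#' @param init optional starting state; default: equilibrium at baseline.
#' @param model model variant.
#' @return `"hpa_trajectory"` with an extra element `final_state` (the
#'   post-pulse asymptotic state) and `final_residual`.
#' @export
simulate_stress_response <- function(params, protocol, horizon = NULL,
                                     init = NULL, model = "extended") {
  model <- as_model(model)
  if (is.null(init)) {
    # the nominal pre-pulse state is the equilibrium continuously connected
    # to the zero-stress equilibrium (the healthy branch in a bistable
    # regime), tracked quasi-statically up to the baseline
    x <- settle_state(params, 0, default_guess(params), model = model)
    eq <- NULL
    for (S in seq(0, protocol$baseline, length.out = 5)) {
      eq <- find_equilibrium(params, S, x, model = model, tol = 1e-9)
      if (eq$converged) x <- eq$state
    }
    if (is.null(eq) || !eq$converged || !eq$stable)
      stop("no stable pre-pulse equilibrium found at baseline stress ",
           protocol$baseline, "; check the parameter regime")
    init <- eq$state
  }
  t_last <- if (nrow(protocol$pulses)) max(protocol$pulses$t_end) else 0
  if (is.null(horizon)) horizon <- t_last + 3000
  t_grid <- sort(unique(c(seq(0, horizon, length.out = 600),
                          protocol$pulses$t_start, protocol$pulses$t_end)))
  traj <- integrate_model(model, init, protocol, t_grid, params)
  fin <- traj$states[nrow(traj$states), ]
  traj$final_state <- fin
  traj$final_residual <- max(abs(model_rhs(model, 0, fin, params,
                                           protocol$baseline)))
  traj
}
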