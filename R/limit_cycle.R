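#' Detect a stable limit cycle by long integration and peak recurrence
#'
#' Integrates past a transient, then looks for sustained oscillations in
#' the observation window: recurring peaks of extracellular cortisol whose
#' amplitude does not decay. Returns the period (mean inter-peak interval),
#' per-species amplitudes over the last cycles, and the temporal order in
#' which CRH, extracellular ACTH and cortisol reach their maxima within a
#' cycle.
#'
#' @param params parameter vector.
#' @param stress constant stress level of the oscillatory regime.
#' @param init optional initial state (default: perturbed default guess).
#' @param model model variant.
#' @param t_transient transient discarded before observation (min).
#' @param t_observe observation window (min).
#' @param dt output resolution (min).
#' @param min_amp_rel minimal peak-to-trough amplitude of COR_ex relative
#'   to its mean for the oscillation to count as sustained.
#' @return list with `sustained` (logical), `period` (min), `amplitude`
#'   (named vector, half peak-to-trough), `maxima_order` (character vector
#'   of the cascade species in the order their maxima occur), `orbit`
#'   (trajectory of the last two periods), `n_peaks`.
#' @export
limit_cycle <- function(params, stress, init = NULL, model = "extended",
                        t_transient = 6000, t_observe = 4000, dt = 0.25,
                        min_amp_rel = 0.01) {
  model <- as_model(model)
  if (is.null(init)) {
    init <- default_guess(params) * 1.1
  }
  x1 <- settle_state(params, stress, init, model = model,
                     t_end = t_transient)
  t_grid <- seq(0, t_observe, by = dt)
  traj <- integrate_model(model, x1, stress_protocol(baseline = stress),
                          t_grid, params)
  cor <- traj$states[, "COR_ex"]
  pk <- .find_peaks(traj$times, cor)
  no <- list(sustained = FALSE, period = NA_real_,
             amplitude = NULL, maxima_order = NULL, orbit = traj,
             n_peaks = length(pk$t))
  amp_rel <- (max(cor) - min(cor)) / max(mean(cor), 1e-12)
  if (length(pk$t) < 4 || amp_rel < min_amp_rel) return(no)
  # sustained: amplitude in the second half at least 90% of the first half
  half <- traj$times > t_observe / 2
  a1 <- diff(range(cor[!half])); a2 <- diff(range(cor[half]))
  if (a2 < 0.9 * a1) return(no)
  ipi <- diff(pk$t)
  period <- mean(ipi[-1])
  # per-species amplitude over the last two periods
  last2 <- traj$times >= (t_observe - 2 * period)
  amp <- apply(traj$states[last2, , drop = FALSE], 2,
               function(x) diff(range(x)) / 2)
  # cascade order of maxima within one cycle: start from a CRH peak
  ord <- .maxima_order(traj$times[last2], traj$states[last2, , drop = FALSE],
                       period)
  list(sustained = TRUE, period = period, amplitude = amp,
       maxima_order = ord, orbit = list(times = traj$times[last2],
                                        states = traj$states[last2, ]),
       n_peaks = length(pk$t))
}

.find_peaks <- function(t, x, prominence = NULL) {
  n <- length(x)
  if (is.null(prominence)) prominence <- 0.02 * max(diff(range(x)), 1e-12)
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(idx)) {
    keep <- vapply(idx, function(i) {
      lo <- max(1, i - 200); hi <- min(n, i + 200)
      x[i] - min(x[lo:hi]) > prominence
    }, logical(1))
    idx <- idx[keep]
  }
  list(t = t[idx], x = x[idx], idx = idx)
}

.maxima_order <- function(t, states, period) {
  species <- c("CRH", "ACTH_ex", "COR_ex")
  if (!all(species %in% colnames(states)))
    species <- intersect(c("CRH", "ACTH", "COR"), colnames(states))
  pk_crh <- .find_peaks(t, states[, species[1]])
  if (length(pk_crh$t) < 2) return(NULL)
  t0 <- pk_crh$t[1]
  times <- c(t0)
  for (sp in species[-1]) {
    pk <- .find_peaks(t, states[, sp])
    nxt <- pk$t[pk$t >= t0]
    if (!length(nxt)) return(NULL)
    times <- c(times, nxt[1])
  }
  names(times) <- species
  species[order(times)]
}
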