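#!/usr/bin/env Rscript
# Simulate the two in-vitro dose protocols on the pituitary cell model
# (A: 10 nM CRH at t = 0; B: additionally 100 nM cortisol) and generate the
# synthetic two-protocol ACTH dataset used by the fitting analyses.
library(hpaxis)

dir.create("results", showWarnings = FALSE)

p <- fixture_regime("invitro")
init <- rest_state(p)
tt <- seq(0.5, 60, 0.5)
A <- run_dose_experiment(p, "A", tt, init = init)
B <- run_dose_experiment(p, "B", tt, init = init)
write.csv(data.frame(time_min = tt, acth_A_nM = A, acth_B_nM = B),
          "results/dose_response_curves.csv", row.names = FALSE)

rate_A <- diff(c(0, A)) / diff(c(0, tt))
rate_B <- diff(c(0, B)) / diff(c(0, tt))
message(sprintf("protocol A: 60-min ACTH %.2f nM, release-rate peak at %.1f min",
                A[length(A)], tt[which.max(rate_A)]))
message(sprintf("protocol B: 60-min ACTH %.2f nM, release-rate peak at %.1f min",
                B[length(B)], tt[which.max(rate_B)]))
message(sprintf("B/A at 60 min = %.2f: the added cortisol first blocks release",
                B[length(B)] / A[length(A)]),
        " through the membrane receptor, then the genomic feedback lowers",
        " the late ACTH level.")

ds <- generate_acth_dataset(acth_generator_config(seed = 1))
write_acth_csv(ds, "results/synthetic_acth_dataset.csv")
message("synthetic noisy dataset written to results/synthetic_acth_dataset.csv")
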