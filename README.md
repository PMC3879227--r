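# hpaxis

Kinetic modelling of the hypothalamic–pituitary–adrenal (HPA) axis with the
anterior pituitary gland cell resolved into nuclear and cytoplasmic
compartments, so that the *slow genomic* feedback through the intracellular
glucocorticoid receptor (GR), the *fast non-genomic* feedback through a
membrane glucocorticoid receptor (GPCR) and the CRH receptor (CRHR) feedback
act on their proper time scales. The package is aimed at systems biologists
and endocrine modellers who want to study how these feedback layers produce
bistable switches — including an **irreversible hypercortisolism switch** —
and how sparse inverse-bifurcation analysis can suggest minimal network
interventions that undo such a switch.

## The model

The extended model tracks 15 concentrations (nM): extracellular cortisol,
CRH and ACTH; cytoplasmic cortisol, vesicular ACTH, free GR and the
CRH-induced transcription factors TFs; the membrane receptors GPCR and CRHR;
the nuclear GR–cortisol dimer; and the nuclear pre-mRNA and cytoplasmic
mRNA pools of POMC (the ACTH precursor gene) and GR. Mass action and
Michaelis–Menten kinetics are used throughout; fast receptor–ligand binding
is closed algebraically:

- CRHR complex: `[CRHR-CRH] = CRHR · CRH / kCRC`;
- cooperative GPCR complex (two cortisol ligands):
  `[GPCR-(COR)2] = GPCR · COR_ex² / kGC2`;
- cytoplasmic GR–cortisol homodimer:
  `D_cyt = COR_in² · GR² / (kGRC² · kGRdim)`, whose nuclear transport enters
  the free cortisol and free GR balances through one shared flux `F` with
  `F = 0` at the transport equilibrium `k̄·k2ex·D_nu = k2in·D_cyt`,
  `k̄ = V_nu/(2·V_in)`.

Hypothalamic CRH production is driven by a dimensionless stress input and
competitively inhibited by cortisol: `ks·(ksb + stress)/(1 + COR_ex/K3)`.
ACTH release from vesicles is catalysed by the CRHR complex and
competitively inhibited by the GPCR complex; POMC transcription is driven
by nuclear TFs under competitive inhibition by the nuclear dimer; GR
transcription carries an autocatalytic dimer-enhanced term. 46 rate and
affinity constants are free parameters (`param_table()` documents the
classification); the 4-state parsimonious reference model
(`rhs_parsimonious()`) is included for comparison.

On top of the model the package provides

- stiff simulation of stress protocols and bolus dose experiments
  (`integrate_model()`, `run_dose_experiment()`,
  `simulate_stress_response()`),
- pseudo-arclength equilibrium continuation in the stress level with
  limit-point/Hopf detection and switch classification
  (`continue_equilibria()`, `classify_switch()`, `limit_cycle()`),
- eigenvalue-objective discovery of dynamic regimes (`search_regime()`),
- two-step Tikhonov → sparsity-enforcing `ℓ^0.9` fitting of two-protocol
  ACTH time courses with in-silico knockouts (`fit_two_step()`,
  `fit_with_model()`, `apply_knockout()`),
- sparse inverse-bifurcation correction of the irreversible
  hypercortisolism switch (`solve_correction()`), and
- a synthetic-data generator emulating the AtT-20 cell-culture dose
  experiments (`generate_acth_dataset()`).

## Worked example

Classify the shipped hypercortisolism regime and correct it:

```r
library(hpaxis)

q0 <- fixture_regime("hyper_switch")
S0 <- lp_abscissas(q0)          # limit points of the equilibrium branch
round(S0, 4)
#>     S1     S2
#> 0.2447 0.0586

classify_switch(attr(S0, "branch"), basal_stress = 0.1)
#> <switch_classification> irreversible_bistable (hyper)
#>   LP abscissas: S1 = 0.24469  S2 = 0.05862  basal = 0.1

res <- solve_correction(correction_problem(q0, basal = 0.1,
                                           S2_target = 0.15, p = 0.9))
res
#> <correction_result> success
#>   achieved S1 = 0.24923  S2 = 0.14358
#>   support size: 2
report_intervention(res)
#> network intervention (2 parameter(s) altered):
#>   d8      increase   +34.8%  other
#>   k2in    decrease   -32.5%  other
```

The return limit point `S2` starts below the basal stress level 0.1 — once
a transient stressor pushes the axis onto the elevated-cortisol branch it
stays there. The sparse correction moves `S2` to 0.144 (above basal) while
holding `S1`, turning the switch reversible by altering only two rate
constants (slower nuclear import and faster turnover of the receptor), and
a simulated stress pulse afterwards returns to baseline cortisol.

The numbered scripts under `analysis/` run the full study: regime
discovery, the two-protocol dose-response simulations, the bifurcation
diagrams and dysfunctional stress responses, the two-step fits with the
model-variant comparison and relevance ranking, and the switch correction.
Each writes its tables under `results/`.

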