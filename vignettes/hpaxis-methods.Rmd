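---
title: "Methods: compartmental glucocorticoid feedback, bistable switches and sparse inverse bifurcation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartmental glucocorticoid feedback, bistable switches and sparse inverse bifurcation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hpaxis)
```

This vignette records the scientific and numerical choices behind the
package: the model equations and their closures, the default parameters and
units, how the bifurcation, discovery, fitting and inverse-bifurcation
machinery is built, what the synthetic-data generator does and does not
emulate, and the known limitations.

## The model

The HPA axis is modelled at the level of the anterior pituitary gland cell,
embedded in a phenomenological description of the hypothalamus (CRH
production driven by a dimensionless stress input, competitively inhibited
by circulating cortisol) and the adrenal gland (Michaelis–Menten cortisol
production driven by circulating ACTH). The cell is split into cytoplasm
and nucleus so that the three feedback layers act on their own time
scales:

* **genomic GR feedback** (minutes to hours): cytoplasmic cortisol binds
  the glucocorticoid receptor, the complex homodimerises, the dimer is
  transported into the nucleus where it represses POMC transcription
  (competitive inhibition against the CRH-induced transcription factors)
  and enhances GR transcription (autocatalytic loop);
* **non-genomic GPCR feedback** (seconds to minutes): two extracellular
  cortisol molecules bind a membrane receptor with positive cooperativity
  and the complex competitively inhibits ACTH release from vesicles;
* **CRHR feedback**: the CRH–receptor complex catalyses ACTH release
  (non-genomic) and drives production of the transcription factors TFs
  through a Hill term (genomic, coefficient `h`).

Units are nM for concentrations and minutes for time; the stress input is
dimensionless on a fictive scale with basal level 0.1. All first-order
rates are 1/min. The compartment volumes `V_in`, `V_ex`, `V_nu` are
phenomenological, default 1, and fixed in every analysis (only their ratios
enter the equations).

### Quasi-equilibrium closures and the dimer transport flux

The receptor complexes and the cytoplasmic dimer are fast relative to the
remaining kinetics and are closed algebraically rather than given ODEs:
`[CRHR-CRH] = CRHR·CRH/kCRC`, `[GPCR-(COR)2] = GPCR·COR_ex²/kGC2` (the
square law expresses the two-ligand cooperative binding) and
`D_cyt = COR_in²·GR²/κ` with `κ = kGRC²·kGRdim`.

The nuclear transport of the dimer changes free cytoplasmic cortisol and
free GR. Projecting the slow transport flux onto the free species under the
fast-binding assumption gives, per unit cytoplasmic volume,

```
F = 2 (k̄ k2ex D_nu − k2in D_cyt) / (1 + 4 COR_in GR (COR_in + GR)/κ),
k̄ = V_nu / (2 V_in).
```

Derivation sketch: write the total cytoplasmic cortisol and GR pools as
`T_c = C + 2 D_cyt`, `T_g = G + 2 D_cyt` (each dimer carries two of each;
the monomeric complex pool is treated as small). Transport changes both
totals at the same rate, and differentiating the closure
`D_cyt = C²G²/κ` along the fast manifold yields the common rate of change
`F` of the free species shown above. `F` satisfies three structural
requirements: it vanishes exactly at the transport equilibrium
`k̄·k2ex·D_nu = k2in·D_cyt`, it enters the cortisol and GR balances as one
shared evaluation, and it has units nM/min with first-order transport
constants. Note that `F(D_nu, 0, 0) = 2 k̄ k2ex D_nu > 0`: exported dimers
dissociate and release free cortisol and receptor even when the free pools
are momentarily empty — export needs no free partners.

### Parameter accounting

`param_table()` classifies all 51 stored constants. Three are volumes,
`h` is a structural Hill coefficient (no literature value at the cellular
level; default 2, the smallest value giving switch-like transcription
activation), and `ksb` is the basal hypothalamic drive folded into the
stress input description (the CRH production scale appears as the products
`ks·stress` and `ks·ksb`). The remaining **46** constants form the free
vector `q` used in fitting: 6 transport/diffusion, 15 degradation, 4
complex dissociation, 8 Michaelis constants, 8 limiting/production rates,
`ks`, and 4 translation/mRNA-export rates.

### In-vitro switch

Dose experiments (`run_dose_experiment()`) emulate a cell culture: no
hypothalamus and no adrenal gland are present, so CRH production (`ks`)
**and** adrenal cortisol production (`v1`) are disabled
(`invitro_params()`); stress is held at zero and hormones enter only as
boluses. Cells start from their rest state — the steady state reached with
no CRH and no cortisol in the medium — which ties the initial conditions
to the parameters instead of adding free unknowns. Medium degradation of
ACTH (`d3`) stays active by default (flag `medium_degradation`).

## Simulation

`integrate_model()` uses `deSolve::lsoda` on compiled right-hand sides
(`src/hpa_derivs.c`; an R reference implementation is kept and tested
against it). Dose events are instantaneous jumps of an extracellular
concentration and every dose or stress-pulse edge restarts the integrator,
so events are handled exactly rather than smoothed over. Default
tolerances are `rtol = 1e-8`, `atol = 1e-10`; the fitting path uses
`rtol = 1e-6`, `atol = 1e-8` with a capped internal step budget because
optimisers routinely visit pathological parameter regions that must fail
fast (failures surface as a large finite objective value).

## Equilibria, continuation and switch classification

`find_equilibrium()` runs a damped Newton iteration in log-concentration
space (states floored at 1e-12 nM), which enforces positivity without
constraints; a pseudo-transient fallback (relax along the flow, resume
Newton) covers poor initial guesses. Jacobians are complex-step
derivatives of the right-hand side (`h = 1e-20`), exact to machine
precision for the model's rational arithmetic; a central-difference path
is kept for cross-checking.

`continue_equilibria()` is a secant-predictor/Newton-corrector
pseudo-arclength scheme with a weighted arclength metric (states scaled by
their magnitude at the branch start, stress weighted ×2 so folds are well
resolved). Step control halves on corrector failure and grows by 1.4 on
success, between 1e-8 and 0.4. Limit points are bracketed by sign changes
of `det(J)` (the product of the eigenvalues, computed anyway for stability
flags) and refined by bisection along the branch to a stress tolerance of
1e-6, confirmed by the smallest-magnitude eigenvalue; Hopf candidates are
bracketed by sign changes of the largest real part over complex pairs
(imaginary part above 1e-4) with an unchanged `det` sign, so a fold is
never misread as a Hopf point.

`classify_switch()` reports `monostable` (no folds), `reversible_bistable`
or `irreversible_bistable` (two folds; irreversible iff the return fold
abscissa `S2` lies below the basal stress level), and refuses to force
branches with more than two folds into this scheme (`complex`).
Orientation compares the cortisol level of the branch reached by
increasing stress past `S1` against the basal branch: higher cortisol
means the inverted alignment of hypercortisolism. Limit cycles are
detected by long integration past a transient with peak recurrence
(collocation/Floquet machinery is out of scope — the package's claims
about oscillations are qualitative: existence, period, amplitude and the
CRH→ACTH→cortisol order of maxima).

The brute-force counterpart `equilibria_dense_scan()` (multi-start Newton
per stress value, with relaxation from well-separated initial scalings and
warm starts chained along the grid) is used as an independent oracle for
the continuation in the tests.

## Regime discovery

`search_regime()` screens a seeded Latin hypercube sample of a log-space
box with a probe continuation and ranks candidates by a graded objective:
for fold targets the squared smallest-magnitude Jacobian eigenvalue along
the branch plus hinge penalties on the fold positions (`S2 < basal < S1`)
and the branch orientation; for Hopf targets the squared real part of the
least-damped complex pair. Candidates that already satisfy the target are
verified by a full continuation (and limit-cycle detection); otherwise the
best starts descend by Nelder–Mead on the score before re-verification.
Identical seed and budget reproduce identical results.

The default search boxes are the package's mechanistic priors, one per
regime family, derived from how each behaviour arises in this network:

* **hypercortisolism switch**: an early-saturating GR autocatalytic loop
  (`K9` small) with strong nuclear dimer consumption (`d9`, `k2in` large,
  `k2ex` small, tight binding) collapses free GR at high cortisol; because
  the nuclear dimer represses only the TFs-driven part of POMC
  transcription, the collapse disinhibits ACTH production and the elevated
  cortisol level sustains itself. This is why the genomic CRH feedback is
  essential here: without the TFs channel (knockout of the `v4` Hill term)
  there is nothing for the dimer to disinhibit, and the search finds no
  such regime within its budget — the package reproduces this as a
  bounded-budget negative result, not as a proof.
* **hypocortisolism switch**: the classical high-capacity GR loop whose
  dimer-rich branch represses POMC, trapping the axis at low cortisol.
* **oscillations**: the same nuclear machinery tuned into an
  unstable-focus range of the multi-stage negative feedback loop
  (hormones fast, mRNA/transport slow).

The shipped fixture regimes (`inst/extdata/regimes/*.json`) were produced
by `search_regime()` with the recorded seeds and carry their verification
summaries; `make_fixture_regimes(regenerate = TRUE)` re-derives them. The
`invitro` fixture is different in kind: it is a hand-tuned synthetic
ground truth (not a regeneration target and not a data reproduction)
chosen to exhibit the three qualitative dose-response features — an
immediate ACTH rise under CRH alone, a delayed release burst near the
quarter hour when cortisol is co-administered (the membrane receptor
blocks release until the medium cortisol has been cleared into the cells),
and a reduced 60-minute level once the genomic feedback catches up.

## Synthetic data generator

`generate_acth_dataset()` simulates both dose protocols at a ground-truth
parameter set and draws independent Gaussian replicates per sample with a
heteroscedastic standard deviation `max(sigma_abs, sigma_rel·value)`
(defaults 0.05 nM and 8%, around four replicates — magnitudes a
fluorescence immunoassay of nM ACTH concentrations would plausibly show);
the reported value is the replicate mean and the 95% confidence half-width
is `1.96·sd/√n`. Default sample times are 1, 2, 5, 10, 15, 20, 30, 45 and
60 minutes, spanning one minute to one hour after administration. The
generator emulates sampling noise and the two-protocol design only; it
does not model the measurement process itself, cell-to-cell variability,
well-to-well effects or non-Gaussian error tails, so passing fits here
show correctness of the estimation machinery, not that real AtT-20 data
would be fit equally well.

## Two-step regularised fitting

The objective is the CI-weighted sum of squared mismatches between the
simulated and measured extracellular ACTH over both protocols plus
`α·Σ|q_i|^p`. Initial conditions are constraints: the dosed species are
fixed exactly (10 nM CRH; 0 or 100 nM cortisol; no ACTH in fresh medium)
and the cellular species start from the parameter-dependent rest state;
selected cellular initial values can instead be estimated within bounds
(`free_rho`). CI weighting can be disabled.

Step 1 (Tikhonov, `p = 2`) screens a seeded log-space Latin hypercube and
refines the best starts by L-BFGS-B in log space, giving the dense
solution `q_tik`. Step 2 minimises the `p = 0.9` objective from `q_tik`
in the *relative linear* scale `z = q/q_tik` bounded below by zero: in
that scale the smoothed penalty gradient grows as a component shrinks,
which is what actually drives irrelevant parameters to zero (a log-space
parametrisation flattens the gradient out and cannot reach zero). The
smoothing follows an ε-continuation (1e-1, 1e-3, 1e-6) on the surrogate
`(q² + ε²)^{p/2} − ε^p`; reported penalty values are always the exact sum.
Because the dense solution typically uses every pathway (compensated
misfit), coordinate-wise descent alone can be trapped; a
group-elimination pass therefore proposes switching each regulatory arm
off entirely (GR autocatalytic loop, GPCR production, CRH-genomic drive),
lets the remaining parameters re-adjust, and keeps a proposal only if the
penalised objective improves. The componentwise ratio `q*/q_tik` is the
relevance diagnostic: components the data do not need end near zero.

`α` defaults to a small fixed value; `choose_alpha()` implements a
discrepancy-principle grid when a data-driven choice is wanted. The
optimiser budgets used in the tests and analysis scripts (6–10 starts,
15–60 quasi-Newton iterations per stage) are the package's desk-scale
choices; parameter recovery is assessed on a 12-parameter
sensitivity-selected subset, where the recovery error shrinks as the
budget grows. With all 46 parameters free, individual values are not
identifiable from 18 noisy points — only the prediction and the sparsity
structure are, which is exactly what the two-step diagnostic reports.

## Sparse inverse bifurcation

`solve_correction()` shifts the return fold `S2` of a hypercortisolism
switch to a target above the basal level (default basal + 0.05) while
keeping `S1` at its original value inside the least-squares term, and
penalises the relative parameter moves with the sparsity-enforcing
`ℓ^0.9` sum. The solver is a damped Gauss–Newton iteration: at every
iterate the two fold abscissas are recomputed by a full continuation and
their parameter sensitivities come from the bordered-system formula at the
folds, `dS/dq_i = −wᵀf_{q_i} / (wᵀf_S)` with `w` the left null vector of
the Jacobian — one continuation per iterate instead of one per parameter.
Moves are multiplicative (log-space), so the corrected parameters stay
positive; a small seeded jitter randomises the initialisation while the
rest of the solve is deterministic; iterates are accepted only if they
decrease the objective, and the trace is recorded. The support is reported
at a 1% relative-change threshold, and `report_intervention()` annotates
the moved parameters with their pathway interpretation (CRH sensitivity of
the cell, TFs regulation, GR translation, processes outside the pituitary).
Which parameters end up in the support depends on the regime
representative and on `α`; the package's claims are the qualitative ones —
reversibility is restored and the `p < 1` support is no larger than the
`p = 2` support at matched targets.

## Numerical choices and degenerate inputs

* Complex-step Jacobians require the right-hand side to be evaluable on
  complex states; the implementation uses plain rational arithmetic and
  explicit squares throughout (no `abs`/`max` branching on state values).
* Equilibria with vanishing components are handled by the 1e-12 nM floor
  of the log-space Newton; the all-zero production system converges to the
  origin within the residual tolerance.
* Zero-amplitude stress pulses, zero doses and zero noise are exact
  no-ops (tested).
* Ties in fold bracketing cannot occur at the recorded resolution because
  the fold test uses the *sign* of `det(J)`; a degenerate double fold
  inside one step would be missed — halving the continuation step is the
  documented remedy and a test asserts step-halving invariance.

## Problem sizes

The shipped analyses run at desk scale on one CPU: continuations use a few
hundred corrector steps; discovery screens 40 Latin-hypercube starts per
target; fits use 18 data points, 46 (or 12) free parameters and the
budgets above; the dense-grid oracle refines fold abscissas to 1e-4 on
zooming 17-point grids. These sizes are the package's own defaults and can
all be raised through the exported arguments.

## Limitations

* The hypothalamus and adrenal are phenomenological single equations;
  interpreting corrections that touch their parameters (`K3`, `d2`, `d3`)
  mechanistically would require resolving those glands.
* No delay differential equations, circadian forcing or ultradian pulse
  generators; oscillations are autonomous limit cycles only.
* Limit cycles are detected by simulation, not continued in parameter
  space; no two-parameter bifurcation diagrams or codimension-2 points.
* The fitting data model assumes independent Gaussian noise with known
  CIs; the real measurement error structure of immunoassays is richer.
* Negative discovery results (no hypercortisolism switch without the
  genomic CRH feedback) are bounded-budget search failures with fixed
  seeds, not nonexistence proofs.
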