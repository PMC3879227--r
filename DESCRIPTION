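Package: hpaxis
Title: Genomic and Non-Genomic Glucocorticoid Feedback Modelling of the HPA Axis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic modelling of the hypothalamic-pituitary-adrenal (HPA) axis with an
    anterior pituitary gland cell resolved into nuclear and cytoplasmic compartments, so
    that slow genomic glucocorticoid receptor (GR) feedback, fast non-genomic membrane
    receptor (GPCR) feedback and CRH receptor (CRHR) feedback act on their proper time
    scales. Provides the 15-state extended model and a 4-state parsimonious reference
    model, stiff simulation of stress protocols and dose-administration experiments,
    pseudo-arclength equilibrium continuation with limit-point and Hopf detection,
    classification of reversible and irreversible bistable switches (hypo- and
    hypercortisolism), eigenvalue-objective discovery of dynamic regimes, two-step
    Tikhonov followed by sparsity-enforcing lp-penalised fitting of ACTH time courses,
    in-silico pathway knockouts, and sparse inverse-bifurcation correction of the
    irreversible hypercortisolism switch.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
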