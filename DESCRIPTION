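Package: phosswitch
Title: Single-Molecule Phosphorylation Switches and Oscillators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic mass-action modelling of a single two-site
    phosphorylation-dephosphorylation molecule whose extreme conformations
    (fully unmodified OO, fully phosphorylated PP) autocatalyse conversion of
    the other forms towards themselves. Provides the 16-reaction catalog of
    the two-intermediate network and its named reductions (AM, TI, BP, BD1,
    CO, SO), stiff time-course integration on the conservation simplex,
    multi-start steady-state location with linear stability, limit-cycle
    detection with period and amplitude envelopes, hysteresis-aware
    bifurcation sweeps over the phosphate-donor level with bisection-refined
    regime boundaries, and a symmetry-reduced reaction-knockout scanner that
    classifies every single-path, pairwise-path and single-reaction removal
    as bistable, oscillatory, absorbing or monostable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
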