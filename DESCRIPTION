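Package: tipstalk
Title: Delta-Notch Lateral Inhibition with Intracellular Notch
    Heterogeneity and Tension-Dependent Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates and analyses an enhanced Delta-Notch lateral
    inhibition model of tip/stalk cell-fate selection on a one-dimensional
    periodic lattice of cells. Each cell carries a Delta level and
    left/right pools of activated Notch coupled by intracellular diffusion,
    and the Delta-Notch binding rate may depend on intercellular distance
    through a Dembo-type constitutive law. Provides steady-state solving
    under periodic n-cell-spacing ansaetze, finite-difference Jacobians and
    linear stability verdicts, stiff time integration, classification of
    tip/stalk/hybrid patterns, parameter-space existence maps over the
    inhibition coefficient and baseline binding rate, and closed-form
    results for the tension-only model (interface balance, the M-function
    and its critical inhibition threshold).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Config/testthat/start-first: params, model, steady-state, analytic,
    patterns, dynamics, sweeps, io, tidiers
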