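Package: vesselgr
Title: Coupled Bio-Chemo-Mechanical Growth and Remodeling of Blood Vessels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates growth and remodeling (G&R) of arteries with a
    homogenized constrained mixture model coupled to logic-gated
    intracellular signaling networks and continuum-scale reaction-diffusion
    of paracrine messengers (nitric oxide, endothelin-1). Provides a
    reduced-order axisymmetric thick-walled-cylinder mechanics solver with
    iterative elastin prestressing, normalized-Hill signaling networks with
    AND/OR/AND-NOT gates evaluated to steady state at each material point,
    quasi-steady diffusible-species profiles with endothelial flux boundary
    conditions, and a staggered chemo-mechanical time loop with scenario
    presets for pressure steps, flow steps, angiotensin II modulation, and
    stress-sensitivity stability sweeps. Results are returned as tidy
    tibbles with broom-style tidiers and ggplot2 autoplot methods.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
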