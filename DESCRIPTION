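Package: solvshell
Title: Hydration Numbers of Electrolyte Solutions from Water Reorientation
    Dynamics and Dielectric Relaxation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of ion hydration in molecular dynamics trajectories of
    aqueous electrolyte solutions, and of GHz-to-THz dielectric relaxation
    spectra of the same systems. Provides radial distribution functions under
    periodic boundary conditions, coordination numbers, geometric hydrogen-bond
    detection and statistics, ion-pair speciation, water-exchange counting, a
    multi-time-origin correlation engine for continuous hydrogen-bond survival,
    water-dipole reorientation and velocity autocorrelation functions, a
    cooperative shell-state subpopulation model with per-subpopulation
    reorientation times and retardation factors, an Empirical-Rule (3 sigma)
    classifier yielding dynamical hydration numbers, and a double-Debye
    dielectric analysis chain (probe calibration, conductivity removal,
    kinetic/static depolarization) yielding spectroscopic hydration numbers.
    Seeded synthetic generators (rotational Brownian dipole trajectories,
    Poisson hydrogen-bond event series, noisy Debye spectra) emulate the
    statistical structure of ab initio MD and network-analyzer data so the
    whole chain is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
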