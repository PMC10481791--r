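Package: coremag
Title: Boundary-Element Magnetostatics for TMS Coils with Magnetic Cores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Charge-based boundary-element solver for transcranial magnetic
    stimulation (TMS) coils with linear and nonlinear magnetic cores. Coils are
    modeled as wire grids of short straight current filaments (Biot-Savart
    primary fields, Neumann-formula self and mutual inductance, Litz-wire
    bundles). Cores are tetrahedral meshes on which a Fredholm second-kind
    surface magnetic-charge equation is solved with GMRES on all inner and
    boundary faces; field-dependent permeability from anhysteretic B-H curves
    (arctangent or Froelich models) is handled by successive substitution.
    Outputs include core magnetization, coil inductance with and without the
    core, and the induced electric field used for TMS dosimetry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    generics,
    ggplot2,
    minpack.lm,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
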