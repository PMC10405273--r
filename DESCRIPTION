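Package: mrdisp
Title: Fifth-Power-Scaling Coupled Dispersion Energy for Multiconfigurational Monomers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Second-order (coupled) dispersion energy between monomers described by
    multiconfigurational wave functions, evaluated at fifth-power cost by combining a
    pivoted Cholesky decomposition of the Coulomb integrals with a recursive
    coupling-constant expansion of the extended random phase approximation (ERPA)
    density response on an imaginary-frequency Casimir-Polder grid. Includes a compact
    Gaussian-integral/CASCI backend for desk-scale test systems, SAPT-style assembly of
    interaction-energy components (delta corrections, exchange scaling, error metrics),
    and spatial dispersion-density maps exported as cube files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    pracma,
    minpack.lm,
    MASS,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
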