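Package: pttsim
Title: Photothermal Therapy Simulation with Gold Nanoparticles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end numerical model of gold-nanoparticle photothermal
    therapy of skin tumors: discrete dipole approximation (DDA) optics for
    the nanoparticle with a Lorenz-Mie oracle, effective-medium conversion
    of particle efficiencies into tissue absorption and scattering addenda,
    voxelized Monte Carlo photon transport in layered skin, explicit
    finite-difference heat diffusion with harmonic-mean interface
    conductivities, apoptosis/thermal-hazard dosimetry, and a parametric
    sweep over nanoparticle distribution radius, injection count and laser
    power.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Rcpp, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
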