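Package: ecmwave
Title: Travelling Waves of Tumour Invasion into Extracellular Matrix
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Numerical machinery for a minimal reaction-diffusion model of
    tumour invasion with degenerate, cross-dependent diffusion, in which the
    tumour-cell diffusivity (1 - M) vanishes at maximal extracellular-matrix
    (ECM) density.  Provides a conservative method-of-lines solver for the
    nondimensional PDE system with front tracking and wave-speed estimation;
    construction of travelling-wave profiles as heteroclinic orbits of the
    desingularized phase-space system by shooting from the unstable manifold
    of the invaded state; location of critical shooting parameters by
    monotone bisection; and characterization of the minimal wave speed as a
    function of the ECM degradation rate and the far-field ECM density,
    including the threshold at which the minimal speed departs from the
    linear-spreading value 2*sqrt(1 - M).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: deSolve, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
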