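Package: epsrlite
Title: Empirical Potential Structure Refinement of Molecular Liquids
    Against X-Ray Total Scattering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reverse Monte Carlo refinement of semi-rigid molecular models
    against X-ray total structure factors, in the style of empirical
    potential structure refinement (EPSR).  Provides semi-rigid molecular
    templates for dihydropyridine drugs (nifedipine, felodipine) and
    polyvinylpyrrolidone oligomers, a Lennard-Jones plus Coulomb reference
    potential, a Metropolis engine with an iteratively refined empirical
    correction potential, Faber-Ziman partial structure factors and X-ray
    weighted totals, transforms between S(Q) and the differential pair
    distribution function D(r), first-sharp-diffraction-peak metrics,
    running coordination numbers, hydrogen-bond censuses, drug-polymer
    bonding preference analysis, CIF crystal comparators, and a synthetic
    data generator that produces pseudo-experiments with known ground
    truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
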