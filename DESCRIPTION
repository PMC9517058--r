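Package: cagekin
Title: Reconstructing Reactivity in Dynamic Host-Guest Systems on Model Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale reconstruction of reaction acceleration under
    confinement in coordination-cage host-guest systems. Provides analytic
    one-dimensional model free-energy landscapes (amide cis-trans
    isomerization, guest encapsulation/expulsion, hydroxide-attack reaction
    profiles), an overdamped-Langevin sampler with well-tempered and
    infrequent metadynamics biasing and PLUMED-dialect HILLS I/O,
    free-energy-surface estimators with basin thermodynamics, transition-rate
    reconstruction from rescaled transition-time ensembles with
    exponentiality validation, Shrake-Rupley and switching-function
    structural observables on bead models, and the probabilistic combination
    of conformer populations, encapsulation equilibria and conformer
    reactivities into a confinement reaction-acceleration index.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
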