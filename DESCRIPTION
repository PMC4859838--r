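Package: scafreg
Title: Correlative Micro-CT and Histology Registration for Bone
    Ingrowth Quantification in Porous Implants
Version: 0.1.0
Authors@R: person("scafreg", "maintainers", email = "scafreg@example.org",
    role = c("aut", "cre"))
Description: Registers a two-dimensional histology section into a
    three-dimensional micro-computed-tomography volume of a bone-implanted
    porous titanium scaffold, using the rigid (non-deforming) titanium
    lattice as a fiducial, and quantifies bone ingrowth (BI), bone-implant
    contact (BC) and histology-induced shrinkage.  Includes a fully
    ground-truthed synthetic phantom generator (lattice scaffold, implanted
    tibia, forward micro-CT simulator with metal streaks, histology
    simulator with shrinkage and interface separation), micro-CT
    preprocessing filters (histogram normalisation, Perona-Malik
    anisotropic diffusion, global thresholding, metal-artefact
    compensation), coarse-to-fine correlation-coefficient registration,
    histomorphometric metrics with orientation sampling, small-sample
    exact Mann-Whitney statistics, and a registration-accuracy validation
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
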