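Package: archgait
Title: Forward-Dynamic Simulation of Foot Arch Mechanics During the
    Stance Phase of Gait
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward-dynamic simulation of the stance phase of gait for an
    articulated foot model held fixed at the tibia while a six
    degree-of-freedom ground plane plays back the inverse motion of gait.
    Builds four foot configurations (arched foot, flatfoot with posterior
    tibialis dysfunction, flatfoot with flexor digitorum longus tendon
    transfer, and flatfoot with a force-amplifying pulley-implant tendon
    transfer), actuates nine extrinsic muscles from piecewise-linear
    activation profiles, resolves sphere-plane contact with a compliant
    normal force law and viscous friction, and extracts vertical ground
    reaction force metrics: the double-peak profile, the medial/lateral
    peak split of forefoot loading, and lateral shift and restoration
    percentages across surgical treatment scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
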