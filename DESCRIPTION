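Package: kneestance
Title: Muscle-Force-Driven Tibiofemoral Contact Simulation over the Stance Phase of Gait
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reduced-order simulation of tibiofemoral joint mechanics during
    the stance phase of walking. Muscle forces are estimated per frame by an
    EMG-bounded static optimization of Hill-type actuators balancing the
    external knee flexion-extension moment. The knee is a parametric
    condyle-on-plateau geometry with medial and lateral compartments, annular
    meniscus foundations with hoop and horn-spring load sharing, four
    cruciate/collateral ligament bundles of nonlinear (slack/toe/linear)
    spring elements with configurable pre-strain, and a grid of
    fibril-reinforced poroelastic cartilage columns advanced by implicit
    consolidation. A quasi-static five-degree-of-freedom femur equilibrium is
    solved at each frame with flexion prescribed. Includes a synthetic gait
    generator, storage-file input and output, EMG envelope processing, joint
    contact force and tissue response metrics, and a ligament pre-strain
    sensitivity sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
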