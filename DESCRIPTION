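Package: wfhankle
Title: Winding-Filament Muscle Model and Bio-Inspired Ankle Prosthesis Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a muscle-tendon unit based on the winding filament
    hypothesis, in which activation-dependent winding of the titin spring
    gives the muscle history-dependent force (residual force enhancement
    after active stretch, force depression after shortening). Two such
    virtual muscles, an anterior dorsiflexor group and a posterior
    plantarflexor group, are arranged antagonistically around a hinge ankle
    to form a torque controller for a powered ankle-foot prosthesis: given
    only the ankle angle stream and a gait-stage label, the controller
    produces a net ankle-moment command that adapts between level walking
    and stair ascent with a single unchanged parameter set. Includes a
    seeded synthetic gait generator (level walking at three speeds, stair
    ascent, level-to-stair transition bouts), stride segmentation and
    per-stride kinematic/kinetic metrics, and the parameter-fitting and
    one-at-a-time sensitivity-analysis procedures used to tune the
    controller.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
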