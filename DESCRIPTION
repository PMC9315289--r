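Package: adherenet
Title: Decisional Logic Network Modeling of Adherence Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-valued decisional logic networks for modeling longitudinal
    treatment-adherence behavior. Defines discrete logic circuits over patient,
    treatment and provider factors; runs synchronous qualitative simulations and
    enumerates persistent end-states (attractors) with basin-frequency
    estimates; fits per-edge perception thresholds and logic weights to
    discretized longitudinal trajectories by exhaustive constraint
    satisfaction; and searches for minimal intervention sets that move
    persistent non-adherent states back to sustained adherence. Includes a
    synthetic cohort generator emulating annual-assessment adherence studies
    with characteristic discontinuation subtypes, noise and missingness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
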