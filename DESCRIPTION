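Package: ewmnr
Title: Relational Movement Measures for Dyadic Animal Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts multi-animal keypoint trajectories (e.g. DeepLabCut
    output) into the simplified horizontal-plane inter-animal measures of
    Eshkol-Wachmann movement notation: partnerwise orientation sectors,
    body-surface opposition codes, and relative distance in body lengths,
    together with per-animal Front/Weight kinematic codes. On top of these
    per-frame measures it detects invariant-configuration intervals (virtual
    "joints" or attractors), quantifies how much of the animals' motion is
    mutually compensatory, attributes configurational changes to the animal
    that produced them, and scores body-target contact distributions. A
    deterministic pursuit-evasion dyad simulator provides ground-truth
    labelled trajectories for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
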