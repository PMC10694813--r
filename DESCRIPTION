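Package: tagmelt
Title: Melting-Point and Eutectic Analysis of Coarse-Grained Binary
    Triacylglyceride Crystals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for determining melting onsets and binary phase behaviour
    of coarse-grained triacylglyceride (TAG) crystals from heating
    trajectories.  Builds single-TAG supercells and seeded random binary
    mixtures, carves planar "crack" voids under an absolute composition
    tolerance, computes the near-neighbor occupancy (NNO) order parameter
    along a linear temperature ramp, detects the melting onset with a lower
    prediction-interval rule, aggregates replicate onsets with bootstrap
    confidence intervals and the plateau/mechanical-collapse rules on
    melting-vs-void-size curves, and assembles binary phase diagrams with
    eutectic minima and a Hildebrand ideal-solubility liquidus.  A synthetic
    trajectory generator with known ground truth replaces the molecular
    dynamics engine so the full pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
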