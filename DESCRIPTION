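Package: listlite
Title: Counterfactual Child-Mortality Projections from Intervention Coverage Scale-Up
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes intervention-coverage estimates from heterogeneous
    household-survey anchors (DHS-style, MICS-style, and a program baseline
    survey), constructs fixed-coverage, scale-up, and secular-trend coverage
    scenarios for a projection horizon, and translates scenario coverage
    trajectories into percent reductions in under-five mortality through a
    cause-structured residual-risk engine in the style of the Lives Saved
    Tool (LiST). Includes per-intervention decompositions (isolation and
    simultaneous scale-up), program-attributable reductions by scenario
    differencing, a seeded micro-simulation oracle for validating the
    analytic engine, and a synthetic-study generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
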