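Package: brainshift
Title: Brain-Skull Displacement Measurement and Boundary-Condition
    Calibration for Rotational Head Injury Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring relative brain-skull displacement from
    high-speed video of transected head rotation experiments and for
    calibrating the spring-connector brain-skull boundary condition of a
    reduced-order two-dimensional head-rotation simulator.  Includes a
    synthetic-experiment generator (rotation pulses, ink-dot marker
    layouts, ground-truth trajectories, rasterized grayscale frame
    stacks), dot segmentation and nearest-neighbour track linking,
    baseline-referenced relative-displacement analysis with pooled
    summaries and Wilcoxon comparisons, a plane-strain explicit-dynamics
    solver with first-order Ogden hyperelasticity, two-term Prony-series
    viscoelasticity, tension-only bridging-vein elements and penalty
    contact, and regression-through-the-origin stiffness calibration with
    confidence-interval based model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deldir,
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
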